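#' Transcriptome-based model reduction
#'
#' Starting from a (gapfilled, growth-capable) model and per-reaction
#' expression scores, solves the reduction program: activate as many
#' high-expression reactions as possible while zeroing flux through
#' low-expression reactions, then prunes the low-expression reactions that
#' carry no flux at the optimum.  The objective is
#'
#' \preformatted{  minimize  a * sum_high(E_i * delta_i) + a * sum_low(E_i * v_i)}
#'
#' over the model's own stoichiometry only (no database), with the same
#' component decomposition, slack and direction-exclusivity machinery as
#' gapfilling; slack variables exist only for high-expression reactions.
#' Unscored reactions (no GPR, gapfilled) appear in the constraints but not
#' in the objective: they are free.  Because both terms share the factor
#' `a`, `a` cancels in the arg-min; it is kept for fidelity with the
#' gapfilling objective and for per-term reporting.  The trade-off is real
#' in both directions: a high reaction stays off when activating it needs
#' more weighted low-expression flux than its own weighted slack saving,
#' and vice versa.
#'
#' Growth is enforced as a hard constraint (`v_biomass >= 0.01`) by default
#' so that every reduced model grows on its construction medium; with
#' `require_growth = FALSE` biomass instead joins the high set with
#' weight 1.
#'
#' @param model a [metabolic_model()], typically gapfilled.
#' @param scores a `pf_scores` object from [score_model()], computed against
#'   this model.
#' @param media media data.frame.
#' @param a scaling factor (default 0.1).
#' @param require_growth enforce biomass flux >= 0.01 (default `TRUE`).
#' @param cap component flux cap (default 100).
#' @param prune_inactive drop zero-flux low-expression reactions from the
#'   returned model (default `TRUE`).
#' @return object of class `pf_reduction`: `active_high`, `inactive_high`,
#'   `active_low`, `inactive_low`, `flux`, `slack`, `objective`,
#'   `reduced_model`.
#' @export
reduce_model <- function(model, scores, media, a = 0.1,
                         require_growth = TRUE, cap = 100,
                         prune_inactive = TRUE) {
  stopifnot(a > 0)
  sc <- stats::setNames(scores$score, scores$reaction_id)
  cls <- stats::setNames(scores$class, scores$reaction_id)
  ids <- model$reactions$id
  high <- ids[ids %in% names(cls) & cls[ids] == "high"]
  low <- ids[ids %in% names(cls) & cls[ids] == "low"]
  if (length(high) == 0) {
    stop("empty high-expression set: nothing to activate", call. = FALSE)
  }
  bounded <- apply_media(model, media, cap)
  slack_set <- high
  slack_w <- a * sc[high]
  if (!require_growth && !is.na(model$biomass_id) &&
      !model$biomass_id %in% slack_set) {
    slack_set <- c(slack_set, model$biomass_id)
    slack_w <- c(slack_w, a * 1)
  }
  dec_preview <- decompose(bounded, slack_set, cap)
  flux_w <- numeric(nrow(dec_preview$vars))
  lw <- dec_preview$vars$rxn %in% low
  flux_w[lw] <- a * sc[dec_preview$vars$rxn[lw]]
  fit <- pf_activation_milp(bounded, slack_set, slack_weights = slack_w,
                            flux_weights = flux_w, cap = cap,
                            require_growth = require_growth)
  res <- pf_check_status(fit$results[[1]], "reduction")
  vars <- fit$dec$vars
  x <- res$x
  v <- x[seq_len(fit$nv)]
  signed <- ifelse(vars$dir == "rev", -v, v)
  net <- tapply(signed, vars$rxn, sum)
  net <- stats::setNames(as.numeric(net), names(net))[ids]
  slack <- stats::setNames(x[fit$nv + seq_len(fit$ns)], slack_set)

  act <- function(set) set[abs(net[set]) >= 0.01 - 1e-6]
  active_high <- act(high)
  active_low <- act(low)
  sol <- structure(list(
    active_high = active_high,
    inactive_high = setdiff(high, active_high),
    active_low = active_low,
    inactive_low = setdiff(low, active_low),
    flux = net, slack = slack, objective = res$objective,
    a = a, reduced_model = NULL), class = "pf_reduction")
  if (prune_inactive) {
    sol$reduced_model <- prune_model(model, sol, media, cap = cap)
  } else {
    sol$reduced_model <- model
  }
  sol
}

#' Prune zero-flux low-expression reactions
#'
#' Removes exactly the scored low-expression reactions whose optimal net
#' flux is (numerically) zero.  High-expression reactions are retained even
#' when inactive - their genes are expressed, and a single flux state is no
#' reason to delete them - as are unscored reactions, exchanges and
#' biomass.  The reduced model is re-verified to grow on the construction
#' medium.
#'
#' @param model the parent model.
#' @param solution a `pf_reduction` (before pruning).
#' @param media media data.frame.
#' @param cap flux cap used for the growth re-check.
#' @param flux_tol net flux magnitude below which a low reaction counts as
#'   unused.
#' @return a [metabolic_model()], a subset of the parent.
#' @export
prune_model <- function(model, solution, media, cap = 100,
                        flux_tol = 1e-6) {
  low <- c(solution$active_low, solution$inactive_low)
  drop <- low[abs(solution$flux[low]) < flux_tol]
  keep <- setdiff(model$reactions$id, drop)
  reduced <- subset_model(model, keep)
  if (!is.na(reduced$biomass_id)) {
    g <- growth_rate(reduced, media, cap_internal = cap, cap_exchange = cap)
    if (g < 0.01 - 1e-7) {
      stop("pruned model no longer grows (biomass ",
           format(g, digits = 6),
           "); re-solve with require_growth = TRUE", call. = FALSE)
    }
  }
  reduced
}

#' @export
print.pf_reduction <- function(x, ...) {
  cat("pf_reduction: objective ", format(x$objective, digits = 6),
      "; high active ", length(x$active_high), "/",
      length(x$active_high) + length(x$inactive_high),
      "; low active ", length(x$active_low), "/",
      length(x$active_low) + length(x$inactive_low), sep = "")
  if (!is.null(x$reduced_model)) {
    cat("; reduced to ", nrow(x$reduced_model$reactions), " reactions",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Swap in a tissue-specific biomass equation
#'
#' Replaces the stoichiometry of the model's biomass reaction with the
#' coefficients of a biomass table (TSV columns `metabolite_id`,
#' `coefficient`; mmol/gDW, negative = consumed), matching per-tissue
#' biomass curation before reduction.
#'
#' @param model a [metabolic_model()].
#' @param biomass data.frame with `metabolite_id`, `coefficient`, or a path
#'   to such a TSV.
#' @return the model with its biomass reaction rewritten.
#' @export
set_biomass <- function(model, biomass) {
  if (is.character(biomass)) {
    biomass <- utils::read.delim(biomass, stringsAsFactors = FALSE,
                                 comment.char = "#")
  }
  if (!all(c("metabolite_id", "coefficient") %in% names(biomass))) {
    stop("biomass table needs columns 'metabolite_id' and 'coefficient'",
         call. = FALSE)
  }
  if (is.na(model$biomass_id)) stop("model has no biomass reaction",
                                    call. = FALSE)
  unknown <- setdiff(biomass$metabolite_id, model$metabolites$id)
  if (length(unknown)) {
    stop("biomass metabolite(s) not in model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  k <- rxn_index(model, model$biomass_id)
  model$reactions$stoich[[k]] <- stats::setNames(
    as.numeric(biomass$coefficient), biomass$metabolite_id)
  validate_model(model)
  model
}
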