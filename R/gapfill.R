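#' Biochemistry databases of candidate reactions
#'
#' A `biochem_db` couples candidate reactions (same layout as a model's
#' reaction table, `source = "database"`) with strictly positive gapfill
#' penalties.  Penalties default to [default_penalties()].
#'
#' @param reactions reaction data.frame (see [metabolic_model()]).
#' @param penalties named numeric, one strictly positive entry per reaction;
#'   `NULL` computes defaults.
#' @param config a [penalty_config()].
#' @return an object of class `biochem_db`.
#' @export
biochem_db <- function(reactions, penalties = NULL,
                       config = penalty_config()) {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (nrow(reactions)) reactions$source <- "database"
  db <- structure(list(reactions = NULL, penalties = NULL),
                  class = "biochem_db")
  db$reactions <- rbind_reactions(
    empty_reaction_frame(), reactions)
  if (is.null(penalties)) penalties <- default_penalties(db, config)
  miss <- setdiff(db$reactions$id, names(penalties))
  if (length(miss)) {
    stop("missing penalties for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(penalties <= 0)) {
    stop("gapfill penalties must be strictly positive", call. = FALSE)
  }
  db$penalties <- penalties[db$reactions$id]
  db
}

empty_reaction_frame <- function() {
  data.frame(id = character(0), reversible = logical(0),
             lower_bound = numeric(0), upper_bound = numeric(0),
             role = character(0), source = character(0),
             gpr = character(0), pathway = character(0),
             stoich = I(list()), gpr_dnf = I(list()),
             stringsAsFactors = FALSE)
}

#' @export
print.biochem_db <- function(x, ...) {
  cat("biochem_db: ", nrow(x$reactions), " candidate reactions, penalties ",
      num12(min(x$penalties)), "-", num12(max(x$penalties)), "\n", sep = "")
  invisible(x)
}

#' Gapfill penalty configuration and defaults
#'
#' The penalty of a candidate starts at `base` and accrues additive
#' surcharges: `transport` when the reaction spans more than one
#' compartment, `no_gene` when the candidate is flagged as having no gene
#' in any source organism (column `no_gene` in the reaction table), and
#' `reverse` when a reaction is used against its native direction (applied
#' by the optimizer to reversal candidates, not by `default_penalties()`).
#' `uniform = TRUE` makes every penalty 1.
#'
#' @param base,reverse,transport,no_gene surcharge sizes.
#' @param uniform logical; ignore surcharges.
#' @return `penalty_config()`: a named list.
#' @export
penalty_config <- function(base = 1, reverse = 2, transport = 1,
                           no_gene = 1, uniform = FALSE) {
  list(base = base, reverse = reverse, transport = transport,
       no_gene = no_gene, uniform = uniform)
}

is_transport_rxn <- function(stoich) {
  comps <- unique(sub("^.*\\[(.+)\\]$", "\\1", names(stoich)))
  length(comps) > 1L
}

#' @rdname penalty_config
#' @param database a [biochem_db()] or a reaction data.frame.
#' @param config a [penalty_config()].
#' @return `default_penalties()`: named numeric vector of forward-use
#'   penalties.
#' @export
default_penalties <- function(database, config = penalty_config()) {
  rxn <- if (inherits(database, "biochem_db")) database$reactions else
    database
  if (config$uniform) {
    return(stats::setNames(rep(1, nrow(rxn)), rxn$id))
  }
  p <- rep(config$base, nrow(rxn))
  p <- p + config$transport *
    vapply(rxn$stoich, is_transport_rxn, logical(1))
  if (!is.null(rxn$no_gene)) {
    p <- p + config$no_gene * as.numeric(isTRUE_vec(rxn$no_gene))
  }
  stats::setNames(p, rxn$id)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# ---------------------------------------------------------------------------
# Shared activation MILP: minimize  sum(slack_w * delta) + sum(flux_w * v)
# subject to   S v = 0,  0 <= v <= ub (v <= cap*z and z_f+z_r <= 1 on pairs),
#              v_f + v_r + delta >= 0.01 on the activation set,
#              delta in [0, 0.01].
# Returns solver results plus the variable bookkeeping.
pf_activation_milp <- function(model, activation, slack_weights,
                               flux_weights, cap = 100,
                               reversal_candidates = character(0),
                               require_growth = FALSE, growth_min = 0.01,
                               variants_a = NULL) {
  dec <- decompose(model, activation, cap, reversal_candidates)
  vars <- dec$vars
  nv <- nrow(vars)
  ns <- length(activation)
  np <- nrow(dec$pairs)
  nvar <- nv + ns + 2L * np
  S <- stoich_matrix(model, dec)
  Aeq <- cbind(S, Matrix::Matrix(0, nrow(S), ns + 2L * np, sparse = TRUE))

  ii <- jj <- xx <- list()
  push <- function(i, j, x) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- x
  }
  row <- 0L
  # slack rows: -(v_f + v_r) - delta <= -0.01
  for (k in seq_along(activation)) {
    row <- row + 1L
    vk <- which(vars$rxn == activation[k])
    push(rep(row, length(vk)), vk, rep(-1, length(vk)))
    push(row, nv + k, -1)
  }
  # pair rows: v - cap*z <= 0 (two rows), z_f + z_r <= 1
  zf <- nv + ns + seq_len(np)
  zr <- nv + ns + np + seq_len(np)
  for (k in seq_len(np)) {
    row <- row + 1L
    push(c(row, row), c(dec$pairs$for_idx[k], zf[k]), c(1, -cap))
    row <- row + 1L
    push(c(row, row), c(dec$pairs$rev_idx[k], zr[k]), c(1, -cap))
    row <- row + 1L
    push(c(row, row), c(zf[k], zr[k]), c(1, 1))
  }
  nub <- row
  Aub <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(nub, nvar))
  bub <- c(rep(-0.01, ns), rep(c(0, 0, 1), np))

  lb <- numeric(nvar)
  ub <- c(vars$ub, rep(0.01, ns), rep(1, 2L * np))
  if (require_growth) {
    bio <- which(vars$rxn == model$biomass_id & vars$dir == "for")
    if (length(bio) != 1L) stop("model has no biomass reaction",
                                call. = FALSE)
    lb[bio] <- growth_min
  }
  integrality <- c(rep(0, nv + ns), rep(1, 2L * np))

  cvec <- numeric(nvar)
  cvec[seq_len(nv)] <- flux_weights
  if (ns) cvec[nv + seq_len(ns)] <- slack_weights
  stage2 <- numeric(nvar)
  stage2[seq_len(nv)] <- 1
  # the second stage minimizes total component flux among (near-)optimal
  # stage-1 solutions; weight the slacks above any attainable flux saving so
  # the stage-1 tolerance cannot be spent on raising slack to shave flux
  stage2[nv + seq_len(ns)] <- nvar + 1

  prob <- list(kind = "milp", nvar = nvar,
               Aeq = pf_triplets(Aeq), beq = I(rep(0, nrow(Aeq))),
               Aub = pf_triplets(Aub), bub = I(bub),
               lb = I(lb), ub = I(ub), c = I(cvec),
               integrality = I(integrality), stage2_c = I(stage2))
  if (!is.null(variants_a)) {
    prob$variants <- lapply(variants_a, function(cv) list(c = I(cv)))
  }
  res <- pf_solve(prob)
  list(dec = dec, nv = nv, ns = ns, np = np, results = res,
       cvec = cvec, nvar = nvar)
}

#' Slack-flux pathway gapfilling
#'
#' Finds a minimum-cost set of database reactions to add (and, optionally,
#' model reactions to run against their native direction) so that as many
#' gene-associated model reactions as possible can carry flux on the given
#' medium.  The mixed-integer program works on forward/backward component
#' fluxes capped at `cap` with binary direction exclusivity, mass balance
#' over the model-plus-database stoichiometry, media-gated exchange bounds,
#' and a slack variable `delta in [0, 0.01]` per activation-set reaction
#' forced to 0.01 exactly when the reaction is inactive
#' (`v_for + v_rev + delta >= 0.01`).  The objective is
#'
#' \preformatted{  minimize  a * sum(gamma_activate * delta) + sum(gamma_gapfill * v)}
#'
#' where the second sum runs over database reactions and reversal
#' candidates.  Degenerate alternate optima are canonicalized by a
#' lexicographic second stage minimizing total component flux.  A reaction
#' is called *active* when its net flux is at least 0.01 (the slack
#' tolerance), robust to solver noise.
#'
#' @param model a [metabolic_model()].
#' @param database a [biochem_db()] (may be empty).
#' @param media media data.frame.
#' @param a scaling factor weighting inactivity against additions
#'   (paper-explored range 0.01-0.25; default 0.1).
#' @param activation_set reaction ids to activate; default all
#'   gene-associated reactions plus biomass.
#' @param gamma_activate named per-reaction activation weights (default 1).
#' @param reversals logical: offer reverse-direction candidates for
#'   irreversible internal model reactions.
#' @param require_growth logical: enforce biomass flux >= 0.01 as a hard
#'   constraint instead of only keeping biomass in the activation set.
#' @param cap component flux cap (default 100).
#' @param config [penalty_config()] for reversal-candidate pricing.
#' @return object of class `pf_gapfill`: `added`, `reversed`, `active`,
#'   `inactive`, `objective`, `flux` (net fluxes), `slack`, `penalties`.
#' @export
gapfill <- function(model, database, media, a = 0.1,
                    activation_set = NULL, gamma_activate = NULL,
                    reversals = TRUE, require_growth = FALSE, cap = 100,
                    config = penalty_config()) {
  stopifnot(a > 0)
  db <- database
  if (is.null(db)) db <- biochem_db(empty_reaction_frame(),
                                    penalties = stats::setNames(
                                      numeric(0), character(0)))
  db <- drop_unconnectable(model, db)
  super <- if (nrow(db$reactions)) add_reactions(model, db$reactions) else
    model
  super <- apply_media(super, media, cap)
  if (is.null(activation_set)) {
    activation_set <- union(gene_associated(model),
                            stats::na.omit(model$biomass_id))
  }
  if (is.null(gamma_activate)) {
    gamma_activate <- stats::setNames(rep(1, length(activation_set)),
                                      activation_set)
  }
  rev_cand <- character(0)
  if (reversals) {
    r <- super$reactions
    rev_cand <- r$id[r$role == "internal" & !r$reversible &
                       r$source == "model"]
  }
  fit <- pf_activation_milp(
    super, activation_set,
    slack_weights = a * gamma_activate[activation_set],
    flux_weights = gapfill_flux_weights(super, db, rev_cand, config,
                                        decompose(super, activation_set, cap,
                                                  rev_cand)$vars),
    cap = cap, reversal_candidates = rev_cand,
    require_growth = require_growth)
  res <- pf_check_status(fit$results[[1]], "gapfilling")
  classify_gapfill(model, db, fit, res, activation_set, a)
}

# penalty per decomposed variable: database reactions pay their penalty in
# both directions (+reverse surcharge on the rev component of natively
# irreversible db reactions); reversal candidates pay base+reverse
# (+transport) on the reverse component only.
gapfill_flux_weights <- function(super, db, rev_cand, config, vars) {
  w <- numeric(nrow(vars))
  pen <- db$penalties
  for (k in seq_len(nrow(vars))) {
    rid <- vars$rxn[k]
    ridx <- match(rid, super$reactions$id)
    src <- super$reactions$source[ridx]
    if (src == "database") {
      p <- pen[[rid]]
      if (vars$dir[k] == "rev" && !super$reactions$reversible[ridx] &&
          !config$uniform) {
        p <- p + config$reverse
      }
      w[k] <- p
    } else if (vars$dir[k] == "rev" && rid %in% rev_cand) {
      w[k] <- if (config$uniform) 1 else {
        config$base + config$reverse + config$transport *
          is_transport_rxn(super$reactions$stoich[[ridx]])
      }
    }
  }
  w
}

drop_unconnectable <- function(model, db) {
  if (!nrow(db$reactions)) return(db)
  known <- model$metabolites$id
  db_mets <- lapply(db$reactions$stoich, names)
  all_db <- table(unlist(db_mets))
  keep <- vapply(db_mets, function(m) {
    new <- setdiff(m, known)
    # a metabolite seen nowhere else (not in the model, unique to this
    # reaction) makes the reaction a dead end
    all(all_db[new] > 1L) || length(new) == 0L
  }, logical(1))
  if (any(!keep)) {
    warning("dropping ", sum(!keep),
            " database reaction(s) with unconnectable metabolites: ",
            paste(db$reactions$id[!keep], collapse = ", "), call. = FALSE)
    db$reactions <- db$reactions[keep, , drop = FALSE]
    db$penalties <- db$penalties[db$reactions$id]
  }
  db
}

classify_gapfill <- function(model, db, fit, res, activation_set, a,
                             act_tol = 0.01, flux_tol = 1e-6) {
  # activity tolerance: solver feasibility noise can leave net flux at
  # 0.01 - O(1e-8); classify with a 1e-6 margin
  vars <- fit$dec$vars
  x <- res$x
  v <- x[seq_len(fit$nv)]
  slack <- stats::setNames(x[fit$nv + seq_len(fit$ns)], activation_set)
  signed <- ifelse(vars$dir == "rev", -v, v)
  net <- tapply(signed, vars$rxn, sum)
  net <- stats::setNames(as.numeric(net), names(net))

  db_ids <- db$reactions$id
  added <- db_ids[abs(net[db_ids]) >= flux_tol]
  rev_use <- vars$dir == "rev" & vars$rxn %in% model$reactions$id &
    !model$reactions$reversible[match(vars$rxn, model$reactions$id)] &
    model$reactions$role[match(vars$rxn, model$reactions$id)] == "internal"
  reversed <- unique(vars$rxn[rev_use & v >= flux_tol])
  active <- activation_set[abs(net[activation_set]) >= act_tol - 1e-6]
  inactive <- setdiff(activation_set, active)
  structure(list(
    added = added[!is.na(added)], reversed = reversed,
    active = active, inactive = inactive,
    objective = res$objective, flux = net, slack = slack,
    a = a, activation_set = activation_set,
    n_variables = fit$nvar, n_binaries = 2L * fit$np),
    class = "pf_gapfill")
}

#' @export
print.pf_gapfill <- function(x, ...) {
  cat("pf_gapfill: objective ", format(x$objective, digits = 6), "; added ",
      length(x$added), ", reversed ", length(x$reversed), "; active ",
      length(x$active), "/", length(x$activation_set), "\n", sep = "")
  invisible(x)
}

#' Integrate a gapfill solution into a model
#'
#' Appends the added database reactions (as `source = "gapfilled"`, without
#' gene associations) and makes reversed reactions reversible, then checks
#' that the result grows on the gapfilling medium whenever the solution
#' activated biomass.
#'
#' @param model the model that was gapfilled.
#' @param solution a `pf_gapfill` from [gapfill()].
#' @param database the [biochem_db()] used.
#' @param media the gapfilling media.
#' @param cap the gapfilling flux cap.
#' @return a [metabolic_model()].
#' @export
integrate_gapfill <- function(model, solution, database, media, cap = 100) {
  out <- model
  if (length(solution$added)) {
    addrxn <- database$reactions[match(solution$added,
                                       database$reactions$id), ,
                                 drop = FALSE]
    addrxn$source <- "gapfilled"
    addrxn$gpr <- NA_character_
    addrxn$gpr_dnf <- I(vector("list", nrow(addrxn)))
    out <- add_reactions(out, addrxn)
  }
  if (length(solution$reversed)) {
    k <- rxn_index(out, solution$reversed)
    out$reactions$reversible[k] <- TRUE
    out$reactions$lower_bound[k] <- -abs(out$reactions$upper_bound[k])
  }
  if (!is.na(out$biomass_id) && out$biomass_id %in% solution$active) {
    g <- growth_rate(out, media, cap_internal = cap, cap_exchange = cap)
    if (g < 0.01 - 1e-7) {
      stop("internal consistency error: integrated model does not grow (",
           format(g, digits = 6), ")", call. = FALSE)
    }
  }
  out
}
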