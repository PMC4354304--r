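#' Flux balance analysis over net (undecomposed) fluxes
#'
#' Bounds follow the standard FBA box: irreversible reactions in
#' `[0, cap_internal]`, reversible in `[-cap_internal, cap_internal]`, and
#' exchange reactions in `[-cap_exchange, min(limit, cap_exchange) * gamma]`
#' where `gamma` is 1 for media metabolites (positive exchange flux =
#' uptake).  Defaults are the flux-fitting caps (1000 internal, 50
#' exchange); gapfilling growth checks pass `cap_exchange = 100`.
#'
#' @param model a [metabolic_model()].
#' @param media media data.frame or `NULL` (closed).
#' @param objective reaction id to maximize (default: biomass).
#' @param cap_internal,cap_exchange flux caps.
#' @return `fba()`: list with `objective` (optimal value) and `flux` (named
#'   net flux vector).
#' @export
fba <- function(model, media, objective = model$biomass_id,
                cap_internal = 1000, cap_exchange = 50) {
  lpdat <- fba_lp_data(model, media, cap_internal, cap_exchange)
  k <- rxn_index(model, objective)
  cvec <- numeric(lpdat$nvar)
  cvec[k] <- -1  # maximize
  prob <- c(lpdat$base, list(kind = "milp", c = I(cvec)))
  res <- pf_check_status(pf_solve(prob)[[1]], "FBA")
  list(objective = -res$objective,
       flux = stats::setNames(res$x, model$reactions$id))
}

fba_lp_data <- function(model, media, cap_internal = 1000,
                        cap_exchange = 50) {
  rxn <- model$reactions
  n <- nrow(rxn)
  lb <- ifelse(rxn$reversible, -cap_internal, 0)
  ub <- rep(cap_internal, n)
  ex <- which(rxn$role == "exchange")
  if (length(ex)) {
    ex_met <- vapply(rxn$stoich[ex], function(s) names(s)[1], character(1))
    limits <- if (!is.null(media) && nrow(media)) {
      stats::setNames(media$max_uptake, media$metabolite_id)
    } else stats::setNames(numeric(0), character(0))
    lb[ex] <- -cap_exchange
    ub[ex] <- ifelse(ex_met %in% names(limits),
                     pmin(limits[ex_met], cap_exchange), 0)
  }
  S <- stoich_matrix(model)
  list(nvar = n,
       base = list(nvar = n, Aeq = pf_triplets(S),
                   beq = I(rep(0, nrow(S))), lb = I(lb), ub = I(ub)))
}

#' Flux variability analysis
#'
#' @rdname fba
#' @param reaction_ids reactions to scan (default: all).
#' @return `fva()`: data.frame with `id`, `min`, `max` net flux.
#' @export
fva <- function(model, media, reaction_ids = model$reactions$id,
                cap_internal = 1000, cap_exchange = 50) {
  lpdat <- fba_lp_data(model, media, cap_internal, cap_exchange)
  idx <- rxn_index(model, reaction_ids)
  variants <- vector("list", 2L * length(idx))
  for (k in seq_along(idx)) {
    cmin <- numeric(lpdat$nvar); cmin[idx[k]] <- 1
    cmax <- numeric(lpdat$nvar); cmax[idx[k]] <- -1
    variants[[2L * k - 1L]] <- list(c = I(cmin))
    variants[[2L * k]] <- list(c = I(cmax))
  }
  prob <- c(lpdat$base, list(kind = "milp", c = I(numeric(lpdat$nvar)),
                             variants = variants))
  res <- pf_solve(prob)
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    r1 <- pf_check_status(res[[2L * k - 1L]], "FVA")
    r2 <- pf_check_status(res[[2L * k]], "FVA")
    vmin[k] <- r1$objective
    vmax[k] <- -r2$objective
  }
  data.frame(id = reaction_ids, min = vmin, max = vmax,
             stringsAsFactors = FALSE)
}

#' Percentage of blocked reactions
#'
#' A reaction is blocked when its feasible flux range under the FBA
#' constraints is `[0, 0]`.  The percentage over all reactions is reported
#' to one decimal place.
#'
#' @rdname fba
#' @param tol absolute flux below which a bound is considered zero.
#' @export
blocked_fraction <- function(model, media, cap_internal = 1000,
                             cap_exchange = 50, tol = 1e-6) {
  rng <- fva(model, media, cap_internal = cap_internal,
             cap_exchange = cap_exchange)
  blocked <- abs(rng$min) < tol & abs(rng$max) < tol
  round(100 * sum(blocked) / nrow(rng), 1)
}

#' Maximum growth rate on a medium
#'
#' Convenience wrapper: FBA maximizing the biomass reaction.
#' @rdname fba
#' @export
growth_rate <- function(model, media, cap_internal = 1000,
                        cap_exchange = 50) {
  if (is.na(model$biomass_id)) stop("model has no biomass reaction",
                                    call. = FALSE)
  fba(model, media, model$biomass_id, cap_internal, cap_exchange)$objective
}
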