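#' Fit model fluxes to measured fluxomics by quadratic programming
#'
#' Minimizes the squared deviation between predicted and measured fluxes,
#' `sum_measured (v_exp - v)^2`, over the standard FBA constraints: mass
#' balance `N v = 0`, `v in [0 or -cap_internal, cap_internal]` (reversible
#' reactions are *not* decomposed here), and media-gated exchange bounds
#' `-cap_exchange <= v_ex <= cap_exchange * gamma`.  Convexity makes the
#' projection onto the measured coordinates unique; the full vector is
#' canonicalized by a tiny ridge (`ridge`) on all coordinates, i.e. a
#' minimum-Euclidean-norm secondary objective over the unmeasured fluxes.
#' The fit is evaluated by the Spearman rank correlation between measured
#' and fitted values ([spearman_correlation()]).
#'
#' @param model a [metabolic_model()].
#' @param measured named numeric vector of measured fluxes keyed by model
#'   reaction ids (see [read_fluxes()] for id mapping); at least 2 matched
#'   reactions are required.
#' @param media media data.frame.
#' @param cap_internal internal flux cap (default 1000; reversible lower
#'   bound -1000).
#' @param cap_exchange exchange cap (default 50).
#' @param min_growth hard lower bound on biomass flux (default 0.01: the
#'   fit is computed with the model growing; set 0 to disable).
#' @param ridge regularization weight for the canonical full vector.
#' @return object of class `pf_fluxfit`: `fitted` (full named flux vector),
#'   `distance` (squared distance on measured coordinates), `spearman_rho`,
#'   `spearman_p`, `n_matched`, `kkt` (stationarity residual), `measured`.
#' @export
fit_fluxes <- function(model, measured, media, cap_internal = 1000,
                       cap_exchange = 50, min_growth = 0.01,
                       ridge = 1e-8) {
  ids <- model$reactions$id
  unknown <- setdiff(names(measured), ids)
  if (length(unknown)) {
    stop("measured reaction(s) not in model (map ids first): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(names(measured), ids)
  if (length(idx) < 2) {
    stop("need at least 2 matched reactions for fitting/correlation",
         call. = FALSE)
  }
  lpdat <- fba_lp_data(model, media, cap_internal, cap_exchange)
  base <- lpdat$base
  if (min_growth > 0) {
    if (is.na(model$biomass_id)) stop("model has no biomass reaction",
                                      call. = FALSE)
    bio <- rxn_index(model, model$biomass_id)
    lb <- as.numeric(base$lb)
    lb[bio] <- max(lb[bio], min_growth)
    base$lb <- I(lb)
  }
  qdiag <- rep(2 * ridge, lpdat$nvar)
  qdiag[idx] <- qdiag[idx] + 2
  cvec <- numeric(lpdat$nvar)
  cvec[idx] <- -2 * measured
  prob <- c(base, list(kind = "qp", qdiag = I(qdiag), c = I(cvec)))
  res <- pf_check_status(pf_solve(prob)[[1]], "flux fitting")
  fitted <- stats::setNames(res$x, ids)
  fm <- fitted[names(measured)]
  sp <- spearman_correlation(fm, measured)
  structure(list(
    fitted = fitted, distance = sum((measured - fm)^2),
    spearman_rho = sp$rho, spearman_p = sp$p,
    n_matched = length(measured), kkt = res$kkt,
    measured = measured), class = "pf_fluxfit")
}

#' @export
print.pf_fluxfit <- function(x, ...) {
  cat("pf_fluxfit: n = ", x$n_matched, ", squared distance ",
      format(x$distance, digits = 6), ", Spearman rho ",
      format(x$spearman_rho, digits = 4), " (p = ",
      format(x$spearman_p, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation with midrank ties
#'
#' Computes rho as the Pearson correlation of midranks.  The two-sided
#' p-value uses the full permutation distribution of rho when `n < exact_n`
#' (exact even under ties) and the t-distribution approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y numeric vectors of equal length, `n >= 2`.
#' @param exact_n exact-permutation cutoff (default 10, i.e. exact for
#'   `n <= 9`).
#' @return list with `rho`, `p`, `n`; `rho` is `NA` (with a warning) when
#'   either vector has zero rank variance.
#' @export
spearman_correlation <- function(x, y, exact_n = 10) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need n >= 2 for a correlation", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: Spearman rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rx, ry)
  if (n < exact_n) {
    P <- permutations_of(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2)) * stats::sd(ry) * sqrt(n - 1)
    ryc <- ry - mean(ry)
    rhos <- as.numeric(matrix(ryc[P], nrow(P), n) %*% rxc) / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

# all permutations of 1..n as a (n!) x n integer matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    block <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-k]
    out[block, 1L] <- k
    out[block, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}
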