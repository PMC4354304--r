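#' Decompose reversible reactions into forward and backward components
#'
#' All optimization modules work on non-negative component fluxes: each
#' reaction contributes a forward variable and, if it can run backwards
#' (natively reversible, an exchange reaction, or a requested reversal
#' candidate), a backward variable; the net flux is `v_for - v_rev`.
#' Reactions in the *activation set* additionally get a slack variable
#' `delta` in `[0, 0.01]` tied to the constraint
#' `v_for + v_rev + delta >= 0.01`, so `delta` is forced to 0.01 exactly
#' when the reaction carries no flux.  Direction exclusivity
#' (`z_for + z_rev <= 1` on binary use variables with `v <= cap * z`) is the
#' sole integer part of the formulations and is emitted only for reactions
#' that actually have both components.
#'
#' Component upper bounds are `cap`, clipped by the model's own bounds in
#' the respective direction (so a media-gated exchange keeps its uptake
#' bound).
#'
#' @param model a [metabolic_model()] (apply media first).
#' @param activation_set reaction ids that receive slack variables.
#' @param cap flux cap for the components (paper default 100).
#' @param reversal_candidates ids of irreversible reactions that also get a
#'   backward component (the "make reversible" gapfilling option).
#' @return an object of class `pf_decomposed`: list with `vars` (data.frame
#'   `var`, `rxn`, `dir`, `ub`), `pairs` (data.frame `for_idx`, `rev_idx`
#'   into `vars`), `slack_rxns`, `cap` and the model.
#' @export
decompose <- function(model, activation_set = character(0), cap = 100,
                      reversal_candidates = character(0)) {
  rxn <- model$reactions
  bad <- setdiff(activation_set, rxn$id)
  if (length(bad)) {
    stop("activation set contains unknown reactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vars <- list()
  for (k in seq_len(nrow(rxn))) {
    id <- rxn$id[k]
    fwd_ub <- max(0, min(cap, rxn$upper_bound[k]))
    vars[[length(vars) + 1L]] <- data.frame(
      var = paste0(id, "..f"), rxn = id, dir = "for", ub = fwd_ub,
      stringsAsFactors = FALSE)
    has_rev <- rxn$reversible[k] || rxn$role[k] == "exchange" ||
      id %in% reversal_candidates
    if (has_rev) {
      rev_ub <- if (rxn$lower_bound[k] < 0) {
        max(0, min(cap, -rxn$lower_bound[k]))
      } else cap  # reversal candidate: native bounds forbid it, cap applies
      vars[[length(vars) + 1L]] <- data.frame(
        var = paste0(id, "..r"), rxn = id, dir = "rev", ub = rev_ub,
        stringsAsFactors = FALSE)
    }
  }
  vars <- do.call(rbind, vars)
  rownames(vars) <- NULL
  two <- names(which(table(vars$rxn) == 2L))
  pairs <- data.frame(
    rxn = two,
    for_idx = match(paste0(two, "..f"), vars$var),
    rev_idx = match(paste0(two, "..r"), vars$var),
    stringsAsFactors = FALSE)
  structure(list(vars = vars, pairs = pairs,
                 slack_rxns = activation_set, cap = cap, model = model),
            class = "pf_decomposed")
}

#' Recompose net fluxes from component fluxes
#'
#' @param decomposed a [decompose()] result.
#' @param x numeric vector of component fluxes in `decomposed$vars` order.
#' @return named numeric vector of net fluxes, one per model reaction.
#' @export
recompose <- function(decomposed, x) {
  vars <- decomposed$vars
  signed <- ifelse(vars$dir == "rev", -x, x)
  net <- tapply(signed, vars$rxn, sum)
  ids <- decomposed$model$reactions$id
  stats::setNames(as.numeric(net[ids]), ids)
}

#' @export
print.pf_decomposed <- function(x, ...) {
  cat("pf_decomposed: ", nrow(x$vars), " flux components (",
      nrow(x$pairs), " for/rev pairs), ", length(x$slack_rxns),
      " slack variables, cap ", x$cap, "\n", sep = "")
  invisible(x)
}
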