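#' Apply a growth medium to a model's exchange reactions
#'
#' Sets, for every exchange reaction, the uptake (upper) bound to
#' `min(max_uptake, cap)` when the exchanged metabolite is in the medium and
#' to 0 otherwise, and the secretion (lower) bound to `-cap`.  This encodes
#' the asymmetric bound `-cap <= v_ex <= cap * gamma` with `gamma = 1` for
#' media metabolites and 0 otherwise; positive exchange flux is uptake.
#'
#' @param model a [metabolic_model()].
#' @param media media data.frame (see [read_media()]), or `NULL` for a
#'   closed medium (secretion only).
#' @param cap default uptake/secretion cap; 100 for gapfilling, 50 for the
#'   quadratic flux fit.
#' @return the model with exchange bounds updated.
#' @export
apply_media <- function(model, media, cap = 100) {
  rxn <- model$reactions
  ex <- which(rxn$role == "exchange")
  ex_met <- vapply(rxn$stoich[ex], function(s) names(s)[1], character(1))
  limits <- stats::setNames(numeric(0), character(0))
  if (!is.null(media) && nrow(media)) {
    limits <- stats::setNames(media$max_uptake, media$metabolite_id)
    missing <- setdiff(names(limits), ex_met)
    if (length(missing)) {
      stop("media metabolite(s) with no exchange reaction: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  for (k in seq_along(ex)) {
    m <- ex_met[k]
    up <- if (m %in% names(limits)) min(limits[[m]], cap) else 0
    rxn$upper_bound[ex[k]] <- up
    rxn$lower_bound[ex[k]] <- -cap
    rxn$reversible[ex[k]] <- TRUE
  }
  model$reactions <- rxn
  model
}

exchange_metabolites <- function(model) {
  ex <- model$reactions$role == "exchange"
  vapply(model$reactions$stoich[ex], function(s) names(s)[1], character(1))
}
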