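#' Median-normalize one condition of an expression matrix
#'
#' The gene expression score is the raw value in the queried condition
#' divided by the median of that gene across *all* columns of the supplied
#' matrix.  Genes whose median is zero are unscorable and are excluded from
#' the result (no pseudocount by default: a pseudocount would manufacture
#' scores the data cannot support).
#'
#' @param mat non-negative numeric matrix, genes x conditions (dimnames
#'   required); see [read_expression()].
#' @param condition column label to normalize.
#' @param pseudocount optional non-negative value added to every entry
#'   before normalization (default 0 = off).
#' @return named numeric vector of normalized scores for scorable genes.
#' @export
normalize_expression <- function(mat, condition, pseudocount = 0) {
  validate_expression(mat)
  if (!condition %in% colnames(mat)) {
    stop("unknown condition label: ", condition, call. = FALSE)
  }
  m <- mat + pseudocount
  med <- apply(m, 1, stats::median)
  ok <- med > 0
  stats::setNames(m[ok, condition] / med[ok], rownames(m)[ok])
}

#' Score a reaction's expression from its GPR rule
#'
#' Implements the max/min/max cascade over the canonical GPR form: the
#' reaction score is the maximum over complexes of the minimum over
#' subunits of the maximum over each subunit's genes of the normalized gene
#' scores.  A subunit with no scorable gene makes its complex unscorable; a
#' reaction with no scorable complex (or no GPR) is unscored (`NA`).
#'
#' @param gpr a [parse_gpr()] object or `NULL`.
#' @param gene_scores named non-negative numeric vector (missing genes are
#'   unscorable).
#' @return a single non-negative score, or `NA_real_` if unscored.
#' @export
score_reaction <- function(gpr, gene_scores) {
  if (is.null(gpr)) return(NA_real_)
  cx_scores <- vapply(gpr, function(complex) {
    su <- vapply(complex, function(subunit) {
      hit <- gene_scores[names(gene_scores) %in% subunit]
      if (length(hit) == 0) NA_real_ else max(hit)
    }, numeric(1))
    if (anyNA(su)) NA_real_ else min(su)
  }, numeric(1))
  if (all(is.na(cx_scores))) NA_real_ else max(cx_scores, na.rm = TRUE)
}

#' Per-reaction expression scores and high/low classification
#'
#' `score_model()` normalizes the chosen condition and scores every
#' reaction; `classify_scores()` applies the threshold rule: a reaction is
#' *low* expression iff its score falls strictly below the threshold
#' (a score exactly at the threshold is high), *unscored* if it has no GPR
#' or no scorable gene.
#'
#' @param model a [metabolic_model()].
#' @param mat expression matrix.
#' @param condition condition label.
#' @param threshold classification threshold (default 0.2: genes expressed
#'   below 20% of their cross-condition median call a reaction low).
#' @param pseudocount see [normalize_expression()].
#' @return an object of class `pf_scores`: data.frame `reaction_id`,
#'   `score`, `class` with the threshold as attribute.
#' @export
score_model <- function(model, mat, condition, threshold = 0.2,
                        pseudocount = 0) {
  g <- normalize_expression(mat, condition, pseudocount)
  scores <- vapply(model$reactions$gpr_dnf, score_reaction, numeric(1),
                   gene_scores = g)
  classify_scores(model$reactions$id, scores, threshold)
}

#' @rdname score_model
#' @param reaction_ids,scores parallel vectors (scores `NA` = unscored).
#' @export
classify_scores <- function(reaction_ids, scores, threshold = 0.2) {
  stopifnot(threshold > 0)
  cls <- ifelse(is.na(scores), "unscored",
                ifelse(scores < threshold, "low", "high"))
  structure(data.frame(reaction_id = reaction_ids, score = scores,
                       class = cls, stringsAsFactors = FALSE),
            threshold = threshold, class = c("pf_scores", "data.frame"))
}

#' Fraction of active reactions across thresholds
#'
#' For each condition and each threshold, the fraction of gene-associated
#' reactions whose expression score is at or above the threshold.  The
#' denominator is the number of gene-associated reactions (unscored
#' gene-associated reactions count in the denominator but can never pass a
#' positive threshold); rows are non-increasing in the threshold.
#'
#' @param model a [metabolic_model()].
#' @param mat expression matrix.
#' @param conditions condition labels (default: all columns).
#' @param thresholds strictly increasing positive thresholds.
#' @return numeric matrix, conditions x thresholds.
#' @export
threshold_scan <- function(model, mat, conditions = colnames(mat),
                           thresholds = c(0.01, 0.05, 0.1, 0.2, 0.5,
                                          1, 2, 4, 8, 16)) {
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  ga <- gene_associated(model)
  gidx <- match(ga, model$reactions$id)
  out <- matrix(NA_real_, length(conditions), length(thresholds),
                dimnames = list(conditions, format(thresholds)))
  for (ci in seq_along(conditions)) {
    g <- normalize_expression(mat, conditions[ci])
    sc <- vapply(model$reactions$gpr_dnf[gidx], score_reaction, numeric(1),
                 gene_scores = g)
    for (ti in seq_along(thresholds)) {
      out[ci, ti] <- sum(!is.na(sc) & sc >= thresholds[ti]) / length(ga)
    }
  }
  out
}

#' Score distributions per pathway category
#'
#' @param scores a `pf_scores` object.
#' @param category_map named character vector mapping reaction id to at most
#'   one category.
#' @return data.frame with one row per category: `category`, `n`, `min`,
#'   `q1`, `median`, `q3`, `max`, `n_zero` (categories with no scored
#'   reaction report `n = 0` and `NA` statistics).
#' @export
category_summary <- function(scores, category_map) {
  cats <- sort(unique(category_map))
  if (length(cats) == 0) {
    return(data.frame(category = character(0), n = integer(0),
                      min = numeric(0), q1 = numeric(0),
                      median = numeric(0), q3 = numeric(0),
                      max = numeric(0), n_zero = integer(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(cats, function(cc) {
    ids <- names(category_map)[category_map == cc]
    sc <- scores$score[scores$reaction_id %in% ids]
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0) {
      return(data.frame(category = cc, n = 0L, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_,
                        n_zero = 0L, stringsAsFactors = FALSE))
    }
    q <- stats::quantile(sc, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(category = cc, n = length(sc), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               n_zero = sum(sc == 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write reaction scores to TSV
#'
#' Columns: `reaction_id`, `score` (6 significant digits, empty if
#' unscored), `class`.
#' @param scores a `pf_scores` object.
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  tab <- data.frame(
    reaction_id = scores$reaction_id,
    score = ifelse(is.na(scores$score), "",
                   formatC(scores$score, digits = 6, format = "g")),
    class = scores$class, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
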