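#' Read and write metabolic models
#'
#' `read_model()`/`write_model()` dispatch on `format`: `"sbml"` (Level 3
#' with the FBC package, see [read_model_sbml()]) or `"tsv"`, a flat dialect
#' with one reaction per row and the columns
#' `id`, `equation`, `gpr`, `role` (plus optional `lower_bound`,
#' `upper_bound`, `source`, `pathway`).  Equations look like
#' `"(1) A[c] + (2) B[c] <=> (1) C[c]"`: coefficients in parentheses,
#' compartment tags in square brackets, `<=>` reversible and `=>`
#' irreversible; an empty side denotes a boundary (exchange) reaction.
#' `format = "auto"` keys on the file extension (`.xml`/`.sbml` vs anything
#' else).
#'
#' @param path file path.
#' @param format `"auto"`, `"sbml"` or `"tsv"`.
#' @return `read_model()` returns a validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "tsv"
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(format,
         sbml = read_model_sbml(path),
         tsv = read_model_tsv(path))
}

#' @rdname read_model
#' @param model a `metabolic_model`.
#' @return `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "tsv"
  }
  switch(format,
         sbml = write_model_sbml(model, path),
         tsv = write_model_tsv(model, path))
  invisible(path)
}

parse_equation <- function(eq, id = "?") {
  arrow <- regmatches(eq, regexpr("<=>|=>|<=", eq))
  if (length(arrow) == 0) {
    stop("reaction '", id, "': equation has no arrow: ", eq, call. = FALSE)
  }
  sides <- strsplit(eq, "<=>|=>|<=")[[1]]
  lhs <- if (length(sides) >= 1) trimws(sides[1]) else ""
  rhs <- if (length(sides) >= 2) trimws(sides[2]) else ""
  if (arrow == "<=") { tmp <- lhs; lhs <- rhs; rhs <- tmp; arrow <- "=>" }
  parse_side <- function(side, sign) {
    if (!nzchar(side)) return(numeric(0))
    terms <- strsplit(side, "\\s+\\+\\s+")[[1]]
    out <- numeric(0)
    for (tm in terms) {
      tm <- trimws(tm)
      mt <- regmatches(tm, regexec("^\\(([-0-9.eE+]+)\\)\\s*(.+)$", tm))[[1]]
      if (length(mt) == 3) {
        coef <- suppressWarnings(as.numeric(mt[2]))
        met <- trimws(mt[3])
      } else if (startsWith(tm, "(")) {
        stop("reaction '", id, "': malformed stoichiometry term '", tm, "'",
             call. = FALSE)
      } else {
        coef <- 1
        met <- tm
      }
      if (is.na(coef) || !nzchar(met)) {
        stop("reaction '", id, "': malformed stoichiometry term '", tm, "'",
             call. = FALSE)
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
    }
    out
  }
  lh <- parse_side(lhs, -1)
  rh <- parse_side(rhs, +1)
  s <- c(lh, rh)
  # merge duplicates across sides
  s <- tapply(s, names(s), sum)
  s <- s[s != 0]
  if (length(s) == 0) {
    stop("reaction '", id, "': equation cancels to nothing: ", eq,
         call. = FALSE)
  }
  list(stoich = stats::setNames(as.numeric(s), names(s)),
       reversible = arrow == "<=>")
}

format_equation <- function(stoich, reversible) {
  fmt <- function(ids) {
    paste(sprintf("(%s) %s", vapply(abs(stoich[ids]), num12, character(1)),
                  ids), collapse = " + ")
  }
  lhs <- names(stoich)[stoich < 0]
  rhs <- names(stoich)[stoich > 0]
  arrow <- if (reversible) "<=>" else "=>"
  trimws(paste(fmt(lhs), arrow, fmt(rhs)))
}

# numbers to 12 significant digits, no scientific notation surprises
num12 <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

read_model_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  need <- c("id", "equation")
  if (!all(need %in% names(tab))) {
    stop("model TSV must have columns 'id' and 'equation'", call. = FALSE)
  }
  parsed <- lapply(seq_len(nrow(tab)), function(k) {
    parse_equation(tab$equation[k], tab$id[k])
  })
  stoich <- lapply(parsed, `[[`, "stoich")
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  role <- if (!is.null(tab$role)) tab$role else "internal"
  role[is.na(role) | !nzchar(role)] <- "internal"
  lb <- if (!is.null(tab$lower_bound)) as.numeric(tab$lower_bound) else {
    ifelse(reversible, -1000, 0)
  }
  ub <- if (!is.null(tab$upper_bound)) as.numeric(tab$upper_bound) else 1000
  rxn <- data.frame(id = tab$id, reversible = reversible,
                    lower_bound = lb, upper_bound = ub, role = role,
                    source = if (!is.null(tab$source)) tab$source else "model",
                    gpr = if (!is.null(tab$gpr)) tab$gpr else NA_character_,
                    pathway = if (!is.null(tab$pathway)) tab$pathway else
                      NA_character_,
                    stringsAsFactors = FALSE)
  rxn$gpr[!is.na(rxn$gpr) & !nzchar(rxn$gpr)] <- NA_character_
  rxn$stoich <- I(stoich)
  met_ids <- unique(unlist(lapply(stoich, names)))
  comp <- ifelse(grepl("\\[.+\\]$", met_ids),
                 sub("^.*\\[(.+)\\]$", "\\1", met_ids), "c")
  met <- data.frame(id = met_ids, name = met_ids, compartment = comp,
                    formula = NA_character_, is_exchangeable = FALSE,
                    stringsAsFactors = FALSE)
  ex_mets <- unlist(lapply(which(role == "exchange"), function(k) {
    names(stoich[[k]])
  }))
  met$is_exchangeable <- met$id %in% ex_mets
  metabolic_model(met, rxn)
}

write_model_tsv <- function(model, path) {
  rxn <- model$reactions
  tab <- data.frame(
    id = rxn$id,
    equation = vapply(seq_len(nrow(rxn)), function(k) {
      format_equation(rxn$stoich[[k]], rxn$reversible[k])
    }, character(1)),
    gpr = ifelse(is.na(rxn$gpr), "", rxn$gpr),
    role = rxn$role,
    lower_bound = vapply(rxn$lower_bound, num12, character(1)),
    upper_bound = vapply(rxn$upper_bound, num12, character(1)),
    source = rxn$source,
    pathway = ifelse(is.na(rxn$pathway), "", rxn$pathway),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a growth-media table
#'
#' Media TSVs have two columns, `metabolite_id` and `max_uptake`
#' (non-negative, in the model's flux units).  Metabolites present in the
#' media may be taken up; everything else may only be secreted.
#'
#' @param path file path.
#' @return a data.frame with columns `metabolite_id`, `max_uptake`.
#' @export
read_media <- function(path) {
  if (!file.exists(path)) stop("media file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("metabolite_id", "max_uptake") %in% names(tab))) {
    stop("media TSV must have columns 'metabolite_id' and 'max_uptake'",
         call. = FALSE)
  }
  tab$max_uptake <- as.numeric(tab$max_uptake)
  if (any(tab$max_uptake < 0)) {
    stop("media uptake limits must be non-negative", call. = FALSE)
  }
  tab[, c("metabolite_id", "max_uptake")]
}

#' @rdname read_media
#' @param media a media data.frame.
#' @export
write_media <- function(media, path) {
  utils::write.table(media, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a gene-expression matrix
#'
#' First column = gene id, remaining columns = one per condition, header row
#' required; values non-negative.
#'
#' @param path file path.
#' @return a numeric matrix, genes in rows (rownames), conditions in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  validate_expression(mat)
  mat
}

validate_expression <- function(mat) {
  if (any(is.na(mat)) || any(mat < 0)) {
    stop("expression matrix must be non-negative with no missing values",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate condition labels in expression matrix", call. = FALSE)
  }
  invisible(mat)
}

#' @rdname read_expression
#' @param mat numeric matrix (genes x conditions) with dimnames.
#' @export
write_expression <- function(mat, path) {
  tab <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a measured-flux table
#'
#' Two columns: `reaction_id`, `flux`.  An optional two-column id-mapping
#' table (`from`, `to`) translates assay reaction names to model ids; no
#' fuzzy matching is attempted.
#'
#' @param path file path.
#' @param map optional path to an id-mapping TSV with columns `from`, `to`.
#' @return named numeric vector of measured fluxes keyed by model ids.
#' @export
read_fluxes <- function(path, map = NULL) {
  if (!file.exists(path)) stop("flux file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("reaction_id", "flux") %in% names(tab))) {
    stop("flux TSV must have columns 'reaction_id' and 'flux'",
         call. = FALSE)
  }
  v <- stats::setNames(as.numeric(tab$flux), tab$reaction_id)
  if (any(!is.finite(v))) stop("measured fluxes must be finite",
                               call. = FALSE)
  if (!is.null(map)) {
    mp <- utils::read.delim(map, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(mp))) {
      stop("id map TSV must have columns 'from' and 'to'", call. = FALSE)
    }
    idx <- match(names(v), mp$from)
    names(v)[!is.na(idx)] <- mp$to[idx[!is.na(idx)]]
  }
  v
}
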