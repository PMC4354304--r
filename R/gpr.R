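#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers in which `or`
#' joins alternative catalysts (isozymes, paralogs) and `and` joins the
#' subunits of a protein complex.  pathflux stores every rule in a canonical
#' two-level normal form mirroring the biology:
#'
#' \preformatted{  reaction = OR over complexes ( AND over subunits ( OR over genes ) )}
#'
#' i.e. a list of *complexes*, each complex a list of *subunits*, each
#' subunit a character vector of interchangeable genes.  `(g1 and g2) or g3`
#' becomes two complexes (`g1`+`g2` subunits; `g3`), while
#' `g1 and (g2 or g3)` becomes one complex with two subunits, the second
#' holding both genes.  Arbitrary nesting is resolved at parse time by
#' distribution; because (max, min) form a distributive lattice, the normal
#' form evaluates identically to the original expression under both boolean
#' and expression-score semantics.
#'
#' @param rule a GPR string, e.g. `"(g1 and g2) or g3"`.  `and`/`or` are
#'   case-insensitive; parentheses group.
#' @return `parse_gpr()` returns an object of class `"pf_gpr"`: a list of
#'   complexes as described above, or `NULL` for an empty/blank rule.
#' @examples
#' g <- parse_gpr("(g1 and g2) or g3")
#' length(g)            # 2 complexes
#' gpr_genes(g)
#' eval_gpr(g, c("g3"))  # TRUE: g3 alone suffices
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) ||
      !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule near '", st$toks[st$pos], "': ", rule,
         call. = FALSE)
  }
  structure(gpr_normalize(ast), class = "pf_gpr")
}

gpr_tokenize <- function(rule) {
  s <- gsub("\\(", " ( ", rule)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# recursive descent: expr := term ('or' term)* ; term := atom ('and' atom)* ;
# atom := gene | '(' expr ')'
gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (st$pos <= length(st$toks) &&
         tolower(st$toks[st$pos]) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (st$pos <= length(st$toks) &&
         tolower(st$toks[st$pos]) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  if (st$pos > length(st$toks)) stop("malformed GPR rule: unexpected end",
                                     call. = FALSE)
  tok <- st$toks[st$pos]
  if (tok == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (st$pos > length(st$toks) || st$toks[st$pos] != ")") {
      stop("malformed GPR rule: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed GPR rule: unexpected token '", tok, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  list(op = "gene", id = tok)
}

# Normalize an AST to the two-level complex/subunit form.
# Returns a list of complexes; a complex is a list of character vectors.
gpr_normalize <- function(node) {
  if (node$op == "gene") return(list(list(node$id)))
  if (node$op == "or") {
    return(do.call(c, lapply(node$args, gpr_normalize)))
  }
  # and: fold children into the accumulated complex list
  acc <- list(list())  # one empty complex
  for (child in node$args) {
    cx <- gpr_normalize(child)
    if (all(lengths(cx) == 1L)) {
      # every alternative is a single subunit: merge into one OR-subunit
      subunit <- unique(unlist(cx))
      acc <- lapply(acc, function(a) c(a, list(subunit)))
    } else {
      # distribute: cartesian product of complexes
      acc <- unlist(lapply(acc, function(a) {
        lapply(cx, function(b) c(a, b))
      }), recursive = FALSE)
    }
  }
  acc
}

#' @rdname parse_gpr
#' @param gpr a `"pf_gpr"` object (or `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  unique(unlist(gpr))
}

#' Evaluate a GPR rule against a set of present genes
#'
#' @inheritParams gpr_genes
#' @param present character vector of gene ids considered present.
#' @return logical; `NA` if `gpr` is `NULL`.
#' @export
eval_gpr <- function(gpr, present) {
  if (is.null(gpr)) return(NA)
  any(vapply(gpr, function(complex) {
    all(vapply(complex, function(subunit) any(subunit %in% present),
               logical(1)))
  }, logical(1)))
}

#' Render a GPR back to a rule string
#'
#' Produces `(a and b) or (c and (d or e))`-style strings from the canonical
#' form; `parse_gpr(gpr_to_string(g))` is equivalent to `g`.
#' @inheritParams gpr_genes
#' @return a string, or `""` for `NULL`.
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  fmt_sub <- function(su) {
    if (length(su) == 1L) su else paste0("(", paste(su, collapse = " or "), ")")
  }
  fmt_cx <- function(cx) {
    parts <- vapply(cx, fmt_sub, character(1))
    s <- paste(parts, collapse = " and ")
    if (length(cx) > 1L) paste0("(", s, ")") else s
  }
  paste(vapply(gpr, fmt_cx, character(1)), collapse = " or ")
}
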