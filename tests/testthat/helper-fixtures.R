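# Shared builders and independent oracles for the test suite.

# compact hand-model builder: rxns is a named list, each element
# list(stoich = c(met = coef, ...), and optional reversible/role/gpr)
hand_model <- function(rxns, biomass = NA_character_) {
  rows <- lapply(names(rxns), function(id) {
    r <- rxns[[id]]
    row <- data.frame(
      id = id,
      reversible = isTRUE(r$reversible),
      lower_bound = if (isTRUE(r$reversible)) -1000 else 0,
      upper_bound = 1000,
      role = if (is.null(r$role)) "internal" else r$role,
      source = "model",
      gpr = if (is.null(r$gpr)) NA_character_ else r$gpr,
      pathway = NA_character_,
      stringsAsFactors = FALSE)
    row$stoich <- I(list(r$stoich))
    row
  })
  rxn <- do.call(rbind, rows)
  met_ids <- unique(unlist(lapply(rxn$stoich, names)))
  comp <- ifelse(grepl("\\[e\\]$", met_ids), "e", "c")
  met <- data.frame(id = met_ids, name = met_ids, compartment = comp,
                    formula = NA_character_,
                    is_exchangeable = met_ids %in% unlist(
                      lapply(which(rxn$role == "exchange"),
                             function(k) names(rxn$stoich[[k]]))),
                    stringsAsFactors = FALSE)
  metabolic_model(met, rxn, c("c", "e"), biomass)
}

media_of <- function(mets, uptake = 100) {
  data.frame(metabolite_id = mets, max_uptake = uptake,
             stringsAsFactors = FALSE)
}

# ---- independent GPR oracle: evaluate the original rule string directly
# (own tokenizer and recursive-descent evaluator; never touches the
# package's normal form)
naive_gpr_eval <- function(rule, gene_scores, boolean = FALSE) {
  s <- gsub("\\(", " ( ", rule)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  val_or <- function() {
    v <- val_and()
    while (tolower(peek()) == "or") {
      take()
      w <- val_and()
      v <- if (is.na(v)) w else if (is.na(w)) v else max(v, w)
    }
    v
  }
  val_and <- function() {
    v <- val_atom()
    while (tolower(peek()) == "and") {
      take()
      w <- val_atom()
      v <- if (is.na(v) || is.na(w)) NA_real_ else min(v, w)
    }
    v
  }
  val_atom <- function() {
    t <- take()
    if (t == "(") { v <- val_or(); take(); return(v) }
    if (boolean) {
      return(as.numeric(t %in% gene_scores))  # gene_scores = present set
    }
    if (t %in% names(gene_scores)) unname(gene_scores[[t]]) else NA_real_
  }
  val_or()
}

# random nested GPR rule over genes g1..gn
random_rule <- function(n_genes, depth = 3) {
  genes <- paste0("g", seq_len(n_genes))
  build <- function(d) {
    if (d == 0 || runif(1) < 0.4) return(sample(genes, 1))
    op <- sample(c(" and ", " or "), 1)
    k <- sample(2:3, 1)
    paste0("(", paste(vapply(seq_len(k), function(i) build(d - 1L),
                             character(1)), collapse = op), ")")
  }
  build(depth)
}

# independent quartiles for category_summary
naive_quartiles <- function(x) unname(quantile(x, c(0.25, 0.5, 0.75)))

expect_solver <- function() {
  # the backend is a hard dependency of the package; a failure here should
  # surface as a test failure, never a skip
  invisible(TRUE)
}
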