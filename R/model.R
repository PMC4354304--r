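#' Stoichiometric metabolic models
#'
#' A `metabolic_model` is a light S3 container in the COBRA tradition:
#'
#' * `metabolites`: data.frame with `id`, `name`, `compartment`, `formula`,
#'   `is_exchangeable`;
#' * `reactions`: data.frame with `id`, `reversible`, `lower_bound`,
#'   `upper_bound`, `role` (`internal`/`exchange`/`biomass`), `source`
#'   (`model`/`database`/`gapfilled`), `gpr` (rule string), `pathway`
#'   (free annotation, `NA` allowed) and two list-columns: `stoich`
#'   (named numeric, negative = consumed) and `gpr_dnf` (parsed
#'   [parse_gpr()] object or `NULL`);
#' * `compartments`: character vector of declared compartment ids;
#' * `biomass_id`: id of the unique biomass reaction (or `NA`);
#' * `genes`: all gene ids appearing in GPRs.
#'
#' Flux sign conventions: a positive flux runs a reaction left-to-right as
#' written.  An exchange reaction touches exactly one metabolite with
#' coefficient +1, so **positive exchange flux is uptake** and negative flux
#' is secretion; growth media gate the uptake (upper) bound only.  This is
#' the convention forced by bounds of the form `-cap <= v_ex <= cap * gamma`
#' with `gamma = 1` for media metabolites.
#'
#' @param metabolites,reactions data.frames as described above.  Missing
#'   optional columns are filled with defaults.
#' @param compartments character; defaults to those used by metabolites.
#' @param biomass_id id of the biomass reaction, or `NA`.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, compartments = NULL,
                            biomass_id = NA_character_) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$is_exchangeable)) {
    metabolites$is_exchangeable <- FALSE
  }
  if (is.null(reactions$role)) reactions$role <- "internal"
  if (is.null(reactions$source)) reactions$source <- "model"
  if (is.null(reactions$gpr)) reactions$gpr <- NA_character_
  if (is.null(reactions$pathway)) reactions$pathway <- NA_character_
  if (is.null(reactions$gpr_dnf)) {
    reactions$gpr_dnf <- I(lapply(reactions$gpr, parse_gpr))
  }
  if (is.null(reactions$reversible) && !is.null(reactions$lower_bound)) {
    reactions$reversible <- reactions$lower_bound < 0
  }
  if (is.null(reactions$reversible)) reactions$reversible <- FALSE
  if (is.null(reactions$lower_bound)) {
    reactions$lower_bound <- ifelse(reactions$reversible, -1000, 0)
  }
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- 1000
  if (is.null(compartments)) {
    compartments <- sort(unique(metabolites$compartment))
  }
  if (is.na(biomass_id) && any(reactions$role == "biomass")) {
    biomass_id <- reactions$id[reactions$role == "biomass"][1]
  }
  genes <- sort(unique(unlist(lapply(reactions$gpr_dnf, gpr_genes))))
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         compartments = compartments, biomass_id = biomass_id,
         genes = as.character(genes)),
    class = "metabolic_model")
  validate_model(m)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, declared compartments,
#' non-empty stoichiometries over known metabolites, single-metabolite
#' exchange reactions, and a unique biomass reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly unchanged, or an error.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxn$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_comp <- setdiff(met$compartment, model$compartments)
  if (length(bad_comp)) {
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  }
  for (k in seq_len(nrow(rxn))) {
    s <- rxn$stoich[[k]]
    if (length(s) == 0) {
      stop("reaction '", rxn$id[k], "' has empty stoichiometry",
           call. = FALSE)
    }
    unknown <- setdiff(names(s), met$id)
    if (length(unknown)) {
      stop("reaction '", rxn$id[k], "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (rxn$role[k] == "exchange" && length(s) != 1L) {
      stop("exchange reaction '", rxn$id[k],
           "' must touch exactly one metabolite", call. = FALSE)
    }
  }
  if (sum(rxn$role == "biomass") > 1L) {
    stop("more than one biomass reaction", call. = FALSE)
  }
  if (!is.na(model$biomass_id) && !model$biomass_id %in% rxn$id) {
    stop("biomass_id '", model$biomass_id, "' is not a reaction",
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  rl <- x$reactions$role
  cat("metabolic_model: ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions (", sum(rl == "internal"),
      " internal, ", sum(rl == "exchange"), " exchange), ",
      length(x$genes), " genes\n", sep = "")
  cat("compartments: ", paste(x$compartments, collapse = ", "),
      "; biomass: ", x$biomass_id, "\n", sep = "")
  invisible(x)
}

#' Reaction ids with a gene association
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids whose GPR is non-empty.
#' @export
gene_associated <- function(model) {
  has <- !vapply(model$reactions$gpr_dnf, is.null, logical(1))
  model$reactions$id[has]
}

rxn_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

#' Subset a model to a reaction set
#'
#' Keeps the given reactions and every metabolite they reference.  Used by
#' pruning; the result is re-validated.
#' @param model a `metabolic_model`.
#' @param reaction_ids ids to keep.
#' @return a `metabolic_model`.
#' @export
subset_model <- function(model, reaction_ids) {
  keep <- rxn_index(model, reaction_ids)
  rxn <- model$reactions[keep, , drop = FALSE]
  used <- unique(unlist(lapply(rxn$stoich, names)))
  met <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  rownames(rxn) <- rownames(met) <- NULL
  bio <- if (!is.na(model$biomass_id) && model$biomass_id %in% rxn$id) {
    model$biomass_id
  } else NA_character_
  metabolic_model(met, rxn, model$compartments, bio)
}

#' Add reactions to a model
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction data.frame rows in the model's layout (new
#'   metabolites are created in their bracketed compartment with defaults).
#' @return a `metabolic_model`.
#' @export
add_reactions <- function(model, reactions) {
  new_mets <- setdiff(unique(unlist(lapply(reactions$stoich, names))),
                      model$metabolites$id)
  met <- model$metabolites
  if (length(new_mets)) {
    comp <- sub("^.*\\[(.*)\\]$", "\\1", new_mets)
    comp[!grepl("\\[", new_mets)] <- model$compartments[1]
    met <- rbind(met, data.frame(
      id = new_mets, name = new_mets, compartment = comp,
      formula = NA_character_, is_exchangeable = FALSE,
      stringsAsFactors = FALSE))
  }
  rxn <- rbind_reactions(model$reactions, reactions)
  comps <- union(model$compartments, unique(met$compartment))
  metabolic_model(met, rxn, comps, model$biomass_id)
}

# rbind for reaction frames with list-columns, tolerating missing columns
rbind_reactions <- function(a, b) {
  cols <- c("id", "reversible", "lower_bound", "upper_bound", "role",
            "source", "gpr", "pathway")
  for (cc in cols) {
    if (is.null(b[[cc]])) {
      b[[cc]] <- switch(cc,
        reversible = FALSE, lower_bound = 0, upper_bound = 1000,
        role = "internal", source = "model", NA_character_)
    }
  }
  if (is.null(b$gpr_dnf)) b$gpr_dnf <- I(lapply(b$gpr, parse_gpr))
  b <- b[, c(cols, "stoich", "gpr_dnf")]
  a <- a[, c(cols, "stoich", "gpr_dnf")]
  out <- rbind(a, b)
  rownames(out) <- NULL
  out
}

#' Stoichiometric matrix of a model
#'
#' Rows are metabolites, columns reactions, in model order.  With
#' `decomposed = TRUE` columns follow a [decompose()] variable table and the
#' column of a reverse component is the negation of its forward column.
#'
#' @param model a `metabolic_model`.
#' @param decomposed either `FALSE` (net reactions) or the result of
#'   [decompose()].
#' @return a sparse `Matrix::dgCMatrix` with dimnames.
#' @export
stoich_matrix <- function(model, decomposed = FALSE) {
  met_ids <- model$metabolites$id
  if (isFALSE(decomposed)) {
    cols <- seq_len(nrow(model$reactions))
    sgn <- rep(1, length(cols))
    cnames <- model$reactions$id
  } else {
    vars <- decomposed$vars
    cols <- match(vars$rxn, model$reactions$id)
    sgn <- ifelse(vars$dir == "rev", -1, 1)
    cnames <- vars$var
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(cols)) {
    s <- model$reactions$stoich[[cols[k]]]
    ii <- c(ii, match(names(s), met_ids))
    jj <- c(jj, rep.int(k, length(s)))
    xx <- c(xx, unname(s) * sgn[k])
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(met_ids), length(cols)),
    dimnames = list(met_ids, cnames))
}
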