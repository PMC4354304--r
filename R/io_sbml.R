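#' SBML Level 3 (FBC) input and output
#'
#' `read_model_sbml()` and `write_model_sbml()` handle the subset of SBML
#' Level 3 Version 1 + FBC version 2 needed for constraint-based modeling:
#' compartments, species, reactions with stoichiometry and flux bounds
#' (parameter-backed `fbc:lowerFluxBound`/`fbc:upperFluxBound`), gene-product
#' associations (`fbc:and`/`fbc:or`/`fbc:geneProductRef`), and the active
#' objective (which marks the biomass reaction).  Original pathflux ids may
#' contain characters that are not legal SBML SIds (e.g. `A[c]`); they are
#' sanitized deterministically for the `id` attribute and preserved verbatim
#' in `name`, so round-trips are id-exact.  The `role`, `source` and
#' `pathway` annotations ride in an XHTML notes body.
#'
#' @param path file path.
#' @return a validated [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  attr_of <- function(node, a) xml2::xml_attr(node, a, ns = ns)

  comp_nodes <- xml2::xml_find_all(doc, ".//s:listOfCompartments/s:compartment",
                                   ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_sid <- xml2::xml_attr(sp_nodes, "id")
  sp_name <- xml2::xml_attr(sp_nodes, "name")
  sp_id <- ifelse(is.na(sp_name) | !nzchar(sp_name), sp_sid, sp_name)
  met <- data.frame(id = sp_id, name = sp_id,
                    compartment = xml2::xml_attr(sp_nodes, "compartment"),
                    formula = xml2::xml_attr(sp_nodes, "fbc:chemicalFormula",
                                             ns = ns),
                    is_exchangeable = FALSE, stringsAsFactors = FALSE)

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                                 ns)
  gp_label <- stats::setNames(xml2::xml_attr(gp_nodes, "label"),
                              xml2::xml_attr(gp_nodes, "id"))

  obj_targets <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//fbc:fluxObjective", ns), "reaction")

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rx_nodes)
  rxn <- data.frame(id = character(n), reversible = logical(n),
                    lower_bound = numeric(n), upper_bound = numeric(n),
                    role = "internal", source = "model",
                    gpr = NA_character_, pathway = NA_character_,
                    stringsAsFactors = FALSE)
  stoich <- vector("list", n)
  biomass_id <- NA_character_
  for (k in seq_len(n)) {
    nd <- rx_nodes[[k]]
    sid <- attr_of(nd, "id")
    nm <- attr_of(nd, "name")
    rid <- if (is.na(nm) || !nzchar(nm)) sid else nm
    rxn$id[k] <- rid
    rxn$reversible[k] <- identical(attr_of(nd, "reversible"), "true")
    lbp <- attr_of(nd, "fbc:lowerFluxBound")
    ubp <- attr_of(nd, "fbc:upperFluxBound")
    rxn$lower_bound[k] <- if (!is.na(lbp) && lbp %in% names(par_val)) {
      par_val[[lbp]]
    } else if (rxn$reversible[k]) -1000 else 0
    rxn$upper_bound[k] <- if (!is.na(ubp) && ubp %in% names(par_val)) {
      par_val[[ubp]]
    } else 1000
    s <- numeric(0)
    for (rf in xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference",
                                  ns)) {
      mid <- sp_id[match(attr_of(rf, "species"), sp_sid)]
      s[mid] <- -as.numeric(attr_of(rf, "stoichiometry"))
    }
    for (rf in xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference",
                                  ns)) {
      mid <- sp_id[match(attr_of(rf, "species"), sp_sid)]
      s[mid] <- as.numeric(attr_of(rf, "stoichiometry"))
    }
    stoich[[k]] <- s
    ga <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(ga, "xml_missing")) {
      rxn$gpr[k] <- sbml_gpr_string(ga, gp_label, ns)
    }
    notes <- xml2::xml_find_all(nd, ".//s:notes//*", ns)
    for (p in notes) {
      txt <- xml2::xml_text(p)
      mt <- regmatches(txt, regexec("^pathflux:([a-z]+)=(.*)$", txt))[[1]]
      if (length(mt) == 3 && mt[2] %in% c("role", "source", "pathway")) {
        rxn[[mt[2]]][k] <- if (nzchar(mt[3])) mt[3] else NA_character_
      }
    }
    if (sid %in% obj_targets) {
      rxn$role[k] <- "biomass"
      biomass_id <- rid
    }
  }
  rxn$stoich <- I(stoich)
  met$is_exchangeable <- met$id %in% names(unlist(
    lapply(which(rxn$role == "exchange"), function(k) stoich[[k]])))
  if (length(compartments) == 0) compartments <- unique(met$compartment)
  metabolic_model(met, rxn, compartments, biomass_id)
}

# render an fbc association subtree to a GPR rule string
sbml_gpr_string <- function(node, gp_label, ns) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gid <- xml2::xml_attr(node, "fbc:geneProduct",
                          ns = c(fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"))
    lab <- gp_label[[gid]]
    return(if (is.null(lab) || is.na(lab)) gid else lab)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpr_string, character(1), gp_label = gp_label,
                  ns = ns)
  op <- if (name == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

sanitize_sid <- function(x, prefix) {
  out <- paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))
  # deterministic de-duplication
  while (anyDuplicated(out)) {
    d <- duplicated(out)
    out[d] <- paste0(out[d], "_x")
  }
  out
}

#' @rdname read_model_sbml
#' @param model a `metabolic_model`.
#' @export
write_model_sbml <- function(model, path) {
  met <- model$metabolites
  rxn <- model$reactions
  msid <- stats::setNames(sanitize_sid(met$id, "M_"), met$id)
  rsid <- stats::setNames(sanitize_sid(rxn$id, "R_"), rxn$id)
  genes <- model$genes
  gsid <- stats::setNames(sanitize_sid(genes, "G_"), genes)

  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "pathflux_model",
                             "fbc:strict" = "false")

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cc in model$compartments) {
    xml2::xml_add_child(loc, "compartment", id = cc, constant = "true")
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(
      los, "species", id = msid[[met$id[k]]], name = met$id[k],
      compartment = met$compartment[k], hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.na(met$formula[k])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula[k])
    }
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_len(nrow(rxn))) {
    sid <- rsid[[rxn$id[k]]]
    xml2::xml_add_child(lop, "parameter", id = paste0("pf_lb_", sid),
                        value = num12(rxn$lower_bound[k]), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("pf_ub_", sid),
                        value = num12(rxn$upper_bound[k]), constant = "true")
  }

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(rxn))) {
    sid <- rsid[[rxn$id[k]]]
    rx <- xml2::xml_add_child(
      lor, "reaction", id = sid, name = rxn$id[k],
      reversible = tolower(as.character(rxn$reversible[k])), fast = "false",
      "fbc:lowerFluxBound" = paste0("pf_lb_", sid),
      "fbc:upperFluxBound" = paste0("pf_ub_", sid))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    for (field in c("role", "source", "pathway")) {
      val <- rxn[[field]][k]
      if (!is.na(val)) {
        p <- xml2::xml_add_child(body, "p")
        xml2::xml_set_text(p, paste0("pathflux:", field, "=", val))
      }
    }
    s <- rxn$stoich[[k]]
    react <- s[s < 0]; prod <- s[s > 0]
    if (length(react)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(react)) {
        xml2::xml_add_child(lr, "speciesReference", species = msid[[m]],
                            stoichiometry = num12(-react[[m]]),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lp, "speciesReference", species = msid[[m]],
                            stoichiometry = num12(prod[[m]]),
                            constant = "true")
      }
    }
    g <- rxn$gpr_dnf[[k]]
    if (!is.null(g)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      sbml_write_assoc(gpa, g, gsid)
    }
  }

  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
  if (!is.na(model$biomass_id)) {
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = rsid[[model$biomass_id]],
                        "fbc:coefficient" = "1")
  }
  if (length(genes)) {
    logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = gsid[[g]],
                          "fbc:label" = g)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# write the canonical OR(AND(OR)) association under `parent`
sbml_write_assoc <- function(parent, gpr, gsid) {
  add_ref <- function(node, g) {
    xml2::xml_add_child(node, "fbc:geneProductRef",
                        "fbc:geneProduct" = gsid[[g]])
  }
  add_subunit <- function(node, subunit) {
    if (length(subunit) == 1L) {
      add_ref(node, subunit)
    } else {
      orn <- xml2::xml_add_child(node, "fbc:or")
      for (g in subunit) add_ref(orn, g)
    }
  }
  add_complex <- function(node, complex) {
    if (length(complex) == 1L) {
      add_subunit(node, complex[[1]])
    } else {
      andn <- xml2::xml_add_child(node, "fbc:and")
      for (su in complex) add_subunit(andn, su)
    }
  }
  if (length(gpr) == 1L) {
    add_complex(parent, gpr[[1]])
  } else {
    orn <- xml2::xml_add_child(parent, "fbc:or")
    for (cx in gpr) add_complex(orn, cx)
  }
  invisible(parent)
}
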