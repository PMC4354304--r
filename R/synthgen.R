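#' Fixture specifications for the synthetic generators
#'
#' Every generator is a pure function of its spec: the same spec (and in
#' particular the same `seed`) reproduces the same artifact bit for bit.
#' The generated world is deliberately simple - linear and 2-way-branched
#' pathways from exchange metabolites to a biomass drain - which is enough
#' to create bypass and essentiality structure while keeping exhaustive
#' oracles tractable.
#'
#' @param seed integer RNG seed.
#' @param n_reactions number of internal reactions (exchanges and biomass
#'   are extra).
#' @param n_pathways number of linear pathways; the first `n_core` feed the
#'   biomass reaction (essential), the rest end in a secretable terminal
#'   (optional "peripheral" pathways).
#' @param n_core number of biomass-feeding pathways.
#' @param reversible_fraction fraction of internal reactions made
#'   reversible.  The gapfilling fixtures keep this at 0 so that the
#'   exhaustive subset-enumeration oracle is a pure LP per subset (the
#'   direction binaries are validated separately on hand-built toys).
#' @param gpr_complexity `"single"` (one gene per reaction), `"complex"`
#'   (two-subunit AND), or `"mixed"` (random single / OR pair / AND pair /
#'   nested rules).
#' @param planted_removals number of essential reactions moved to the
#'   database in [make_gapfill_case()].
#' @param n_decoys number of distractor database reactions.
#' @param noise_sigma lognormal (expression) or Gaussian (flux) noise sd.
#' @param n_conditions number of expression conditions (>= 3 so the median
#'   is meaningful).
#' @return a list of class `pf_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_reactions = 20L, n_pathways = 4L,
                         n_core = 2L, reversible_fraction = 0,
                         gpr_complexity = c("mixed", "single", "complex"),
                         planted_removals = 1L, n_decoys = 4L,
                         noise_sigma = 0, n_conditions = 5L) {
  gpr_complexity <- match.arg(gpr_complexity)
  stopifnot(n_reactions >= 2L * n_pathways, n_core >= 1L,
            n_core <= n_pathways, planted_removals >= 0L,
            reversible_fraction >= 0, reversible_fraction <= 1,
            noise_sigma >= 0, n_conditions >= 3L)
  structure(list(seed = as.integer(seed), n_reactions = as.integer(n_reactions),
                 n_pathways = as.integer(n_pathways),
                 n_core = as.integer(n_core),
                 reversible_fraction = reversible_fraction,
                 gpr_complexity = gpr_complexity,
                 planted_removals = as.integer(planted_removals),
                 n_decoys = as.integer(n_decoys),
                 noise_sigma = noise_sigma,
                 n_conditions = as.integer(n_conditions)),
            class = "pf_fixture_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

random_gpr <- function(rid, complexity) {
  g <- function(i) paste0("g_", rid, "_", i)
  switch(complexity,
         single = g(1),
         complex = paste0(g(1), " and ", g(2)),
         mixed = switch(sample.int(4, 1),
                        g(1),
                        paste0(g(1), " or ", g(2)),
                        paste0(g(1), " and ", g(2)),
                        paste0(g(1), " and (", g(2), " or ", g(3), ")")))
}

#' Generate a growth-feasible toy model
#'
#' Builds `n_pathways` linear pathways, each from an exchangeable root
#' metabolite through a gene-associated transport step and chain reactions
#' to a terminal; the first `n_core` terminals are consumed by the biomass
#' drain, the remaining pathways end in a secretion exchange.  Every
#' internal reaction carries a GPR drawn per `gpr_complexity` and a
#' `pathway` annotation.  The generated medium (all root metabolites at
#' uptake 100) is attached as `$media`, the pathway membership as
#' `$pathways`; the model is verified to grow at generation time.
#'
#' @param spec a [fixture_spec()].
#' @return a [metabolic_model()] with extra fields `media` (data.frame) and
#'   `pathways` (named list of internal reaction ids).
#' @export
make_model <- function(spec) {
  with_seed(spec$seed, make_model_impl(spec))
}

make_model_impl <- function(spec) {
  P <- spec$n_pathways
  lens <- rep(spec$n_reactions %/% P, P)
  extra <- spec$n_reactions %% P
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  rxns <- list()
  mets <- list()
  pathways <- list()
  add_met <- function(id, comp, exch = FALSE) {
    mets[[id]] <<- data.frame(id = id, name = id, compartment = comp,
                              formula = NA_character_,
                              is_exchangeable = exch,
                              stringsAsFactors = FALSE)
  }
  add_rxn <- function(id, stoich, role = "internal", gpr = NA_character_,
                      pathway = NA_character_, reversible = FALSE) {
    rxns[[id]] <<- data.frame(id = id, reversible = reversible,
                              lower_bound = if (reversible) -1000 else 0,
                              upper_bound = 1000, role = role,
                              source = "model", gpr = gpr, pathway = pathway,
                              stringsAsFactors = FALSE)
    rxns[[id]]$stoich <<- I(list(stoich))
  }
  terminals <- character(P)
  for (p in seq_len(P)) {
    pw <- paste0("pwy", p)
    root <- paste0("M", p, "_0[e]")
    add_met(root, "e", exch = TRUE)
    add_rxn(paste0("EX_M", p, "_0"), stats::setNames(1, root),
            role = "exchange")
    chain_ids <- character(0)
    prev <- root
    for (j in seq_len(lens[p])) {
      mid <- paste0("M", p, "_", j, "[c]")
      add_met(mid, "c")
      rid <- if (j == 1) paste0("T", p) else paste0("R", p, "_", j - 1L)
      rev <- stats::runif(1) < spec$reversible_fraction
      # continuous product coefficients keep steady-state fluxes distinct
      # along a chain (ties would make rank correlations degenerate)
      coef <- stats::runif(1, 0.7, 1.4)
      add_rxn(rid, stats::setNames(c(-1, coef), c(prev, mid)),
              gpr = random_gpr(rid, spec$gpr_complexity), pathway = pw,
              reversible = rev)
      chain_ids <- c(chain_ids, rid)
      prev <- mid
    }
    terminals[p] <- prev
    pathways[[pw]] <- chain_ids
    if (p > spec$n_core) {
      # peripheral pathway: terminal is secretable, never in the medium
      add_rxn(paste0("EX_", sub("\\[.*$", "", prev)),
              stats::setNames(1, prev), role = "exchange")
      mets[[prev]]$is_exchangeable <- TRUE
    }
  }
  # biomass demands 10 units of each core terminal: at the minimum-growth
  # state (v_bio = 0.01) every core-chain reaction then carries at least
  # 0.1 / 1.4^6 > 0.01 flux, i.e. growth alone activates the whole core
  add_rxn("bio1",
          stats::setNames(rep(-10, spec$n_core), terminals[seq_len(spec$n_core)]),
          role = "biomass")
  met <- do.call(rbind, unname(mets))
  rxn <- do.call(rbind, unname(rxns))
  rownames(met) <- rownames(rxn) <- NULL
  model <- metabolic_model(met, rxn, c("c", "e"), "bio1")
  model$media <- data.frame(
    metabolite_id = paste0("M", seq_len(P), "_0[e]"),
    max_uptake = 100, stringsAsFactors = FALSE)
  model$pathways <- pathways
  g <- growth_rate(model, model$media, cap_internal = 100,
                   cap_exchange = 100)
  if (g < 0.01) stop("internal error: generated model does not grow")
  model
}

#' Generate a gapfilling case with a verified minimal completion
#'
#' Removes `planted_removals` essential core-chain reactions from a
#' [make_model()] output and places them (GPR stripped) in a candidate
#' database padded with `n_decoys` distractors (dead-end consumers that can
#' never carry flux).  `known_minimum` is the size of the smallest database
#' subset that restores growth (biomass >= 0.01), verified by exhaustive
#' enumeration of all `2^|db|` subsets at generation time; the enumeration
#' also certifies that the unique minimum-cost completion equals the
#' removed set.
#'
#' @param spec a [fixture_spec()] with `planted_removals >= 1` and
#'   `planted_removals + n_decoys <= 12`.
#' @return list with `model` (truncated), `database` ([biochem_db()],
#'   uniform penalties), `media`, `known_minimum`, `removed`.
#' @export
make_gapfill_case <- function(spec) {
  stopifnot(spec$planted_removals >= 1L,
            spec$planted_removals + spec$n_decoys <= 12L)
  model <- make_model(spec)
  with_seed(spec$seed + 1000003L, make_gapfill_case_impl(spec, model))
}

make_gapfill_case_impl <- function(spec, model) {
  core_pw <- paste0("pwy", seq_len(spec$n_core))
  core_rxns <- unlist(model$pathways[core_pw])
  if (spec$planted_removals > length(core_rxns)) {
    stop("requested removals exceed the essential set", call. = FALSE)
  }
  removed <- sample(core_rxns, spec$planted_removals)
  ridx <- rxn_index(model, removed)
  db_rxns <- model$reactions[ridx, , drop = FALSE]
  db_rxns$gpr <- NA_character_
  db_rxns$gpr_dnf <- I(vector("list", nrow(db_rxns)))
  db_rxns$pathway <- NA_character_
  truncated <- subset_model(model, setdiff(model$reactions$id, removed))
  truncated$media <- model$media
  truncated$pathways <- lapply(model$pathways, setdiff, y = removed)
  # decoys: flux-capable but useless "leak" reactions that divert an
  # existing intermediate to a secretable metabolite -- they can never
  # restore growth, and carrying flux through them only costs penalty
  if (spec$n_decoys > 0) {
    cyt <- setdiff(model$metabolites$id[model$metabolites$compartment == "c"],
                   NULL)
    sinks <- exchange_metabolites(model)
    for (d in seq_len(spec$n_decoys)) {
      src <- sample(setdiff(cyt, sinks), 1)
      dst <- sample(sinks, 1)
      row <- data.frame(id = paste0("D", d), reversible = FALSE,
                        lower_bound = 0, upper_bound = 1000,
                        role = "internal", source = "database",
                        gpr = NA_character_, pathway = NA_character_,
                        stringsAsFactors = FALSE)
      row$stoich <- I(list(stats::setNames(c(-1, 1), c(src, dst))))
      db_rxns <- rbind_reactions(db_rxns, row)
    }
  }
  database <- biochem_db(db_rxns, config = penalty_config(uniform = TRUE))
  km <- verify_known_minimum(truncated, database, truncated$media)
  if (!identical(sort(km$best_set), sort(unname(removed)))) {
    stop("internal error: planted completion is not the verified optimum")
  }
  list(model = truncated, database = database, media = truncated$media,
       known_minimum = km$known_minimum, removed = unname(removed))
}

# exhaustive growth check over all database subsets (batched LPs)
verify_known_minimum <- function(model, database, media, cap = 100) {
  db_ids <- database$reactions$id
  nd <- length(db_ids)
  super <- add_reactions(model, database$reactions)
  super <- apply_media(super, media, cap)
  lpdat <- fba_lp_data(super, media, cap_internal = cap,
                       cap_exchange = cap)
  db_idx <- match(db_ids, super$reactions$id)
  bio <- match(super$biomass_id, super$reactions$id)
  cvec <- numeric(lpdat$nvar); cvec[bio] <- -1
  subsets <- lapply(0:(2^nd - 1L), function(m) {
    which(bitwAnd(m, 2^(seq_len(nd) - 1L)) > 0)
  })
  ub0 <- as.numeric(lpdat$base$ub)
  variants <- lapply(subsets, function(s) {
    ub <- ub0
    ub[db_idx[setdiff(seq_len(nd), s)]] <- 0
    list(ub = I(ub))
  })
  prob <- c(lpdat$base, list(kind = "milp", c = I(cvec),
                             variants = variants))
  res <- pf_solve(prob)
  grows <- vapply(res, function(r) {
    identical(r$status, "optimal") && -r$objective >= 0.01 - 1e-9
  }, logical(1))
  if (!any(grows)) stop("internal error: no subset restores growth")
  sizes <- lengths(subsets)
  kmin <- min(sizes[grows])
  cand <- which(grows & sizes == kmin)
  if (length(cand) != 1L) {
    stop("internal error: minimal completion is not unique")
  }
  list(known_minimum = kmin, best_set = db_ids[subsets[[cand]]])
}

#' Generate an expression matrix with planted active pathways
#'
#' Genes of reactions in `active_pathways` get a focal-condition value 5x
#' their cross-condition baseline (normalized score 5); all other genes get
#' 0.05x (score 0.05, below the 0.2 threshold).  Multiplicative lognormal
#' noise with sd `noise_sigma` is applied to every entry.  The focal
#' condition is the first column, `"target"`.
#'
#' @param model a [make_model()] output.
#' @param spec a [fixture_spec()].
#' @param active_pathways pathway names (e.g. `"pwy1"`) to plant as high.
#' @return numeric matrix genes x conditions.
#' @export
make_expression <- function(model, spec, active_pathways) {
  bad <- setdiff(active_pathways, names(model$pathways))
  if (length(bad)) {
    stop("unknown pathway id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  with_seed(spec$seed + 2000003L, {
    act_rxn <- unlist(model$pathways[active_pathways])
    genes <- character(0); hi <- logical(0)
    for (k in seq_len(nrow(model$reactions))) {
      gs <- gpr_genes(model$reactions$gpr_dnf[[k]])
      if (length(gs)) {
        genes <- c(genes, gs)
        hi <- c(hi, rep(model$reactions$id[k] %in% act_rxn, length(gs)))
      }
    }
    keep <- !duplicated(genes)
    genes <- genes[keep]; hi <- hi[keep]
    nc <- spec$n_conditions
    base <- stats::runif(length(genes), 50, 150)
    mat <- matrix(rep(base, nc), length(genes), nc)
    mat[, 1] <- base * ifelse(hi, 5, 0.05)
    if (spec$noise_sigma > 0) {
      mat <- mat * exp(matrix(stats::rnorm(length(mat), 0, spec$noise_sigma),
                              nrow(mat)))
    }
    dimnames(mat) <- list(genes,
                          c("target", paste0("ref", seq_len(nc - 1L))))
    mat
  })
}

#' Generate a measured-flux set from a feasible flux state
#'
#' Samples a feasible flux vector by maximizing a random linear objective
#' over the flux-fitting constraint set (growth enforced at >= 0.01),
#' selects the gene-associated internal reactions as "measured", and adds
#' Gaussian noise with sd `noise_sigma`.
#'
#' @param model a [make_model()] output.
#' @param spec a [fixture_spec()].
#' @param media media data.frame (default: the model's own).
#' @return list with `measured` (named, noisy), `truth` (noise-free named
#'   vector), `full` (the sampled full flux vector).
#' @export
make_flux_case <- function(model, spec, media = model$media) {
  with_seed(spec$seed + 3000003L, {
    # heterogeneous uptake limits so pathways carry distinct fluxes (a
    # uniform cap would drive every chain to the same vertex value and
    # leave the rank correlation undefined)
    media <- media
    media$max_uptake <- stats::runif(nrow(media), 5, 45)
    lpdat <- fba_lp_data(model, media, cap_internal = 1000,
                         cap_exchange = 50)
    lb <- as.numeric(lpdat$base$lb)
    bio <- match(model$biomass_id, model$reactions$id)
    lb[bio] <- 0.01
    cvec <- -stats::runif(lpdat$nvar)  # maximize a random positive combo
    prob <- c(lpdat$base, list(kind = "milp", c = I(cvec)))
    prob$lb <- I(lb)
    res <- pf_check_status(pf_solve(prob)[[1]], "flux sampling")
    full <- stats::setNames(res$x, model$reactions$id)
    sel <- model$reactions$id[model$reactions$role == "internal" &
                                model$reactions$id %in% gene_associated(model)]
    truth <- full[sel]
    measured <- truth + stats::rnorm(length(truth), 0, spec$noise_sigma)
    list(measured = measured, truth = truth, full = full)
  })
}
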