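test_that("a feasible measured vector is reproduced at distance zero", {
  spec <- fixture_spec(seed = 41)
  m <- make_model(spec)
  fc <- make_flux_case(m, spec)
  fit <- fit_fluxes(m, fc$measured, m$media)
  expect_lt(fit$distance, 1e-8)
  expect_equal(unname(fit$fitted[names(fc$measured)]),
               unname(fc$measured), tolerance = 1e-4)
  expect_equal(fit$spearman_rho, 1)
  expect_lt(fit$kkt, 1e-6)
  # mass balance holds for the fitted vector
  S <- stoich_matrix(m)
  expect_lt(max(abs(as.numeric(S %*% fit$fitted))), 1e-6)
})

test_that("an infeasible-sign measurement projects onto the bound", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1)),
    EX_B = list(stoich = c("B[c]" = 1), role = "exchange")))
  # R1 is irreversible: a measured -5 is projected to v = 0 (the fitted
  # vector is then constant, so rho is flagged undefined)
  fit <- suppressWarnings(fit_fluxes(m, c(R1 = -5, EX_A = 0),
                                     media_of("A[e]", 50), min_growth = 0))
  expect_true(is.na(fit$spearman_rho))
  expect_equal(unname(fit$fitted[["R1"]]), 0, tolerance = 1e-6)
  expect_equal(fit$distance, 25, tolerance = 1e-5)
})

test_that("fewer than two matched reactions or unknown ids error", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1)),
    EX_B = list(stoich = c("B[c]" = 1), role = "exchange")))
  expect_error(fit_fluxes(m, c(R1 = 1), media_of("A[e]"), min_growth = 0),
               "at least 2")
  expect_error(fit_fluxes(m, c(R1 = 1, nope = 2), media_of("A[e]"),
                          min_growth = 0), "not in model")
})

test_that("the QP optimum beats Monte-Carlo feasible points", {
  spec <- fixture_spec(seed = 42, noise_sigma = 1)
  m <- make_model(spec)
  fc <- make_flux_case(m, spec)
  fit <- fit_fluxes(m, fc$measured, m$media)
  # sample feasible vertices by random-objective LPs, then random convex
  # combinations of them; every such point must be no closer than the QP
  lp <- pathflux:::fba_lp_data(m, m$media, 1000, 50)
  lb <- as.numeric(lp$base$lb)
  lb[match(m$biomass_id, m$reactions$id)] <- 0.01
  set.seed(4242)
  variants <- lapply(1:20, function(i) list(c = I(rnorm(lp$nvar))))
  prob <- c(lp$base, list(kind = "milp", c = I(numeric(lp$nvar)),
                          variants = variants))
  prob$lb <- I(lb)
  res <- pathflux:::pf_solve(prob)
  verts <- do.call(rbind, lapply(res, function(r) r$x))
  idx <- match(names(fc$measured), m$reactions$id)
  for (i in 1:200) {
    w <- runif(nrow(verts)); w <- w / sum(w)
    v <- as.numeric(t(verts) %*% w)
    d <- sum((fc$measured - v[idx])^2)
    expect_gte(d, fit$distance - 1e-6)
  }
})

test_that("spearman matches cor.test in both p-value regimes", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(c(5, 6, 7, 8, 12, 25), 1)
    x <- rnorm(n); y <- rnorm(n)   # continuous: no ties
    got <- spearman_correlation(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = n < 10))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("spearman handles perfect, inverted and degenerate inputs", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9)
  expect_equal(spearman_correlation(x, x)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  expect_warning(out <- spearman_correlation(x, rep(2, 8)),
                 "zero rank variance")
  expect_true(is.na(out$rho))
  # midrank ties agree with cor on ranks
  y <- c(1, 1, 2, 2, 3, 3, 4, 4)
  expect_equal(spearman_correlation(x, y)$rho,
               cor(rank(x), rank(y)))
})

test_that("blocked fractions match a naive per-reaction LP oracle", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1)),
    EX_B = list(stoich = c("B[c]" = 1), role = "exchange"),
    DEAD = list(stoich = c("B[c]" = -1, "Z[c]" = 1))))
  med <- media_of("A[e]")
  # fully connected chain: 0%; the dead-end consumer alone is blocked
  expect_equal(blocked_fraction(m, med), 25)  # 1 of 4 reactions
  rng <- fva(m, med)
  expect_equal(rng$min[rng$id == "DEAD"], 0, tolerance = 1e-9)
  expect_equal(rng$max[rng$id == "DEAD"], 0, tolerance = 1e-9)
  expect_gt(rng$max[rng$id == "R1"], 1)

  # open linear chain with no dead end: 0 %
  m2 <- subset_model(m, c("EX_A", "R1", "EX_B"))
  expect_equal(blocked_fraction(m2, med), 0)

  # random fixture vs naive single-LP-at-a-time oracle
  spec <- fixture_spec(seed = 44, n_reactions = 12, n_pathways = 3,
                       n_core = 2)
  mf <- make_model(spec)
  rng <- fva(mf, mf$media)
  lp <- pathflux:::fba_lp_data(mf, mf$media, 1000, 50)
  for (k in seq_len(nrow(mf$reactions))) {
    for (sgn in c(1, -1)) {
      cvec <- numeric(lp$nvar); cvec[k] <- sgn
      res <- pathflux:::pf_solve(c(lp$base,
                                   list(kind = "milp", c = I(cvec))))[[1]]
      want <- if (sgn == 1) rng$min[k] else rng$max[k]
      expect_equal(if (sgn == 1) res$objective else -res$objective, want,
                   tolerance = 1e-6)
    }
  }
})

test_that("blocked fraction is monotone under reaction removal", {
  spec <- fixture_spec(seed = 45, n_reactions = 16, n_pathways = 4,
                       n_core = 2)
  m <- make_model(spec)
  med <- m$media
  b_full <- blocked_fraction(m, med)
  expect_equal(b_full, 0)
  # removing a mid-chain reaction strands its neighbours
  drop <- m$pathways$pwy3[2]
  m2 <- subset_model(m, setdiff(m$reactions$id, drop))
  expect_gt(blocked_fraction(m2, med), b_full)
})
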