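chain_gapfill_case <- function() {
  model <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "gA"),
    R3 = list(stoich = c("C[c]" = -1, "D[c]" = 1), gpr = "gC"),
    bio = list(stoich = c("D[c]" = -1), role = "biomass")),
    biomass = "bio")
  db_rxns <- data.frame(
    id = c("R2", "D1", "D2"), reversible = FALSE, lower_bound = 0,
    upper_bound = 1000, role = "internal", source = "database",
    gpr = NA_character_, pathway = NA_character_, stringsAsFactors = FALSE)
  db_rxns$stoich <- I(list(c("B[c]" = -1, "C[c]" = 1),
                           c("B[c]" = -1, "X[c]" = 1),
                           c("X[c]" = -1, "C[c]" = 1)))
  list(model = model, db = biochem_db(db_rxns), media = media_of("A[e]"))
}

test_that("the broken chain is repaired by exactly the missing reaction", {
  cs <- chain_gapfill_case()
  sol <- gapfill(cs$model, cs$db, cs$media, require_growth = TRUE,
                 reversals = FALSE)
  expect_identical(sol$added, "R2")
  expect_length(sol$reversed, 0)
  # forced growth at 0.01 pushes 0.01 through the single added reaction:
  # objective = gamma_gapfill * v = 1 * 0.01 (all slacks zero)
  expect_equal(sol$objective, 0.01, tolerance = 1e-6)
  expect_setequal(sol$active, c("R1", "R3", "bio"))
  expect_length(sol$inactive, 0)
})

test_that("an already-active model needs nothing: added empty, slack zero", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "gA"),
    bio = list(stoich = c("B[c]" = -1), role = "biomass")),
    biomass = "bio")
  sol <- gapfill(m, NULL, media_of("A[e]"), require_growth = TRUE,
                 reversals = FALSE)
  expect_length(sol$added, 0)
  expect_true(all(sol$slack < 1e-7))
  expect_equal(sol$objective, 0, tolerance = 1e-7)
})

test_that("an unproducible substrate leaves its reaction inactive at full slack", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "gA"),
    bio = list(stoich = c("B[c]" = -1), role = "biomass"),
    Q = list(stoich = c("U[c]" = -1, "V[c]" = 1), gpr = "gQ")),
    biomass = "bio")
  sol <- gapfill(m, NULL, media_of("A[e]"), a = 0.1, require_growth = TRUE,
                 reversals = FALSE)
  expect_identical(sol$inactive, "Q")
  expect_equal(unname(sol$slack[["Q"]]), 0.01, tolerance = 1e-7)
  # objective = a * gamma_activate * delta_Q = 0.1 * 1 * 0.01
  expect_equal(sol$objective, 0.001, tolerance = 1e-7)
})

test_that("direction-exclusivity binaries prevent fake activity", {
  # isolated reversible gene-associated reaction: the LP relaxation could
  # set v_for = v_rev = 0.005 (mass-balanced) and claim activity for free;
  # the MILP must pay the full slack instead
  m <- hand_model(list(
    R = list(stoich = c("A[c]" = -1, "B[c]" = 1), reversible = TRUE,
             gpr = "g1")))
  sol <- gapfill(m, NULL, media = NULL, a = 0.1, reversals = FALSE)
  expect_identical(sol$inactive, "R")
  expect_equal(sol$objective, 0.001, tolerance = 1e-8)
})

test_that("reversal candidates are priced and reported", {
  # growth requires running the irreversible transport T backwards
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    T = list(stoich = c("B[c]" = -1, "A[e]" = 1), gpr = "gT"),
    bio = list(stoich = c("B[c]" = -1), role = "biomass")),
    biomass = "bio")
  sol <- gapfill(m, NULL, media_of("A[e]"), require_growth = TRUE,
                 reversals = TRUE)
  expect_identical(sol$reversed, "T")
  expect_length(sol$added, 0)
  # reverse use of a transport reaction: (base 1 + reverse 2 + transport 1)
  # times the 0.01 growth-forced flux (tolerance covers the lexicographic
  # second stage's optimality window)
  expect_equal(sol$objective, 0.04, tolerance = 1e-4)
  # without reversals the problem is infeasible under forced growth
  expect_error(gapfill(m, NULL, media_of("A[e]"), require_growth = TRUE,
                       reversals = FALSE), "infeasible")
})

test_that("default penalties follow the surcharge table", {
  rxns <- data.frame(id = c("int", "tpt"), reversible = FALSE,
                     lower_bound = 0, upper_bound = 1000, role = "internal",
                     source = "database", gpr = NA_character_,
                     pathway = NA_character_, stringsAsFactors = FALSE)
  rxns$stoich <- I(list(c("A[c]" = -1, "B[c]" = 1),
                        c("A[e]" = -1, "B[c]" = 1)))
  p <- default_penalties(rxns)
  expect_equal(unname(p["int"]), 1)       # plain internal candidate
  expect_equal(unname(p["tpt"]), 2)       # + transport surcharge
  pu <- default_penalties(rxns, penalty_config(uniform = TRUE))
  expect_equal(unname(pu), c(1, 1))
  rxns$no_gene <- c(TRUE, FALSE)
  expect_equal(unname(default_penalties(rxns)["int"]), 2)
  expect_error(biochem_db(rxns, penalties = c(int = 0, tpt = 1)),
               "strictly positive")
})

test_that("integration reproduces growth and an empty solution is identity", {
  cs <- chain_gapfill_case()
  sol <- gapfill(cs$model, cs$db, cs$media, require_growth = TRUE,
                 reversals = FALSE)
  gm <- integrate_gapfill(cs$model, sol, cs$db, cs$media)
  expect_true(growth_rate(gm, cs$media, 100, 100) >= 0.01)
  k <- match("R2", gm$reactions$id)
  expect_identical(gm$reactions$source[k], "gapfilled")
  expect_true(is.na(gm$reactions$gpr[k]))

  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "gA"),
    bio = list(stoich = c("B[c]" = -1), role = "biomass")),
    biomass = "bio")
  sol0 <- gapfill(m, NULL, media_of("A[e]"), require_growth = TRUE,
                  reversals = FALSE)
  gm0 <- integrate_gapfill(m, sol0, NULL, media_of("A[e]"))
  expect_identical(gm0$reactions$id, m$reactions$id)
  expect_identical(gm0$reactions$lower_bound, m$reactions$lower_bound)
})

test_that("unconnectable database reactions are dropped with a warning", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "gA"),
    bio = list(stoich = c("B[c]" = -1), role = "biomass")),
    biomass = "bio")
  db_rxns <- data.frame(id = "orphan", reversible = FALSE, lower_bound = 0,
                        upper_bound = 1000, role = "internal",
                        source = "database", gpr = NA_character_,
                        pathway = NA_character_, stringsAsFactors = FALSE)
  db_rxns$stoich <- I(list(c("Zork[c]" = -1, "B[c]" = 1)))
  db <- biochem_db(db_rxns)
  expect_warning(
    sol <- gapfill(m, db, media_of("A[e]"), reversals = FALSE),
    "orphan")
  expect_length(sol$added, 0)
})

test_that("integrated models always grow on 12 random gapfill cases", {
  set.seed(99)
  for (seed in 1:12) {
    case <- make_gapfill_case(fixture_spec(seed = 100 + seed,
                                           planted_removals = sample(1:2, 1)))
    sol <- gapfill(case$model, case$database, case$media,
                   require_growth = TRUE, reversals = FALSE)
    gm <- integrate_gapfill(case$model, sol, case$database, case$media)
    expect_true(growth_rate(gm, case$media, 100, 100) >= 0.01 - 1e-9)
  }
})
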