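trade_off_model <- function(r2_coef = 1) {
  hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "h1"),
    R2 = list(stoich = c("B[c]" = -1, "C[c]" = r2_coef), gpr = "l1"),
    R3 = list(stoich = c("C[c]" = -1, "D[c]" = 1), gpr = "h2"),
    EX_D = list(stoich = c("D[c]" = 1), role = "exchange")))
}

test_that("a cheap low reaction is used to activate its high neighbours", {
  m <- trade_off_model()
  sc <- classify_scores(c("R1", "R2", "R3"), c(5, 0.01, 5))
  sol <- reduce_model(m, sc, media_of("A[e]"), require_growth = FALSE)
  expect_setequal(sol$active_high, c("R1", "R3"))
  expect_identical(sol$active_low, "R2")
  # objective = a * E_low * v_low = 0.1 * 0.01 * 0.01 (slacks zero)
  expect_equal(sol$objective, 1e-5, tolerance = 1e-7)
  # nothing had zero flux among the lows: reduced model is the parent
  expect_identical(sort(sol$reduced_model$reactions$id),
                   sort(m$reactions$id))
})

test_that("a dominating low reaction keeps its dependent high reaction off", {
  # R2 yields only 0.001 C per unit flux: activating R3 (>= 0.01) would
  # need v_R2 = 10, costing a*0.19*10 = 0.19 against a slack saving of
  # a*5*0.01 = 0.005 -> R3 stays off; R1 only needs v_R2 = 0.01
  m <- trade_off_model(r2_coef = 0.001)
  sc <- classify_scores(c("R1", "R2", "R3"), c(5, 0.19, 5))
  sol <- reduce_model(m, sc, media_of("A[e]"), require_growth = FALSE)
  expect_identical(sol$active_high, "R1")
  expect_identical(sol$inactive_high, "R3")
  expect_identical(sol$active_low, "R2")
  # v_R2 = 0.01 (R1's needs only); R3 then dribbles at 0.001 * 0.01 = 1e-5,
  # well under the 0.01 activity rule, and its slack is 0.01 - 1e-5:
  # objective = a*E_low*0.01 + a*E_high*(0.01 - 1e-5)
  expect_equal(sol$objective, 0.1 * (0.19 * 0.01) + 0.1 * (5 * (0.01 - 1e-5)),
               tolerance = 1e-6)
})

test_that("an all-high model activates everything at objective zero", {
  m <- trade_off_model()
  sc <- classify_scores(c("R1", "R2", "R3"), c(5, 5, 5))
  sol <- reduce_model(m, sc, media_of("A[e]"), require_growth = FALSE)
  expect_setequal(sol$active_high, c("R1", "R2", "R3"))
  expect_equal(sol$objective, 0, tolerance = 1e-8)
})

test_that("unscored reactions are free: constraints yes, objective no", {
  m <- trade_off_model()
  sc <- classify_scores(c("R1", "R3"), c(5, 5))  # R2 unscored
  sol <- reduce_model(m, sc, media_of("A[e]"), require_growth = FALSE)
  expect_setequal(sol$active_high, c("R1", "R3"))
  expect_equal(sol$objective, 0, tolerance = 1e-8)
  expect_length(sol$active_low, 0)
})

test_that("zero-flux low reactions are pruned, used ones kept", {
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "h1"),
    EX_B = list(stoich = c("B[c]" = 1), role = "exchange"),
    R2 = list(stoich = c("A[e]" = -1, "C[c]" = 1), gpr = "l1"),
    EX_C = list(stoich = c("C[c]" = 1), role = "exchange")))
  sc <- classify_scores(c("R1", "R2"), c(5, 0.1))
  sol <- reduce_model(m, sc, media_of("A[e]"), require_growth = FALSE)
  expect_identical(sol$inactive_low, "R2")
  expect_identical(setdiff(m$reactions$id, sol$reduced_model$reactions$id),
                   "R2")
  # subset property
  expect_true(all(sol$reduced_model$reactions$id %in% m$reactions$id))
})

test_that("counting: slack variables only for the high set", {
  m <- make_model(fixture_spec(seed = 31))
  mat <- make_expression(m, fixture_spec(seed = 31), c("pwy1", "pwy2"))
  sc <- score_model(m, mat, "target")
  sol <- reduce_model(m, sc, m$media)
  n_high <- sum(sc$class == "high")
  expect_length(sol$slack, n_high)
  n_low <- sum(sc$class == "low")
  expect_equal(length(sol$active_low) + length(sol$inactive_low), n_low)
})

test_that("an essential low-expression reaction survives pruning", {
  # the only route to biomass is low-expressed; forced growth keeps it
  m <- hand_model(list(
    EX_A = list(stoich = c("A[e]" = 1), role = "exchange"),
    R1 = list(stoich = c("A[e]" = -1, "B[c]" = 1), gpr = "l1"),
    R2 = list(stoich = c("B[c]" = -1, "D[c]" = 1), gpr = "h1"),
    bio = list(stoich = c("D[c]" = -1), role = "biomass")),
    biomass = "bio")
  sc <- classify_scores(c("R1", "R2"), c(0.05, 5))
  sol <- reduce_model(m, sc, media_of("A[e]"))
  expect_identical(sol$active_low, "R1")
  expect_true("R1" %in% sol$reduced_model$reactions$id)
  expect_true(growth_rate(sol$reduced_model, media_of("A[e]"),
                          100, 100) >= 0.01)
  # objective pays exactly the essential low flux: a * 0.05 * 0.01
  expect_equal(sol$objective, 0.1 * 0.05 * 0.01, tolerance = 1e-7)
})

test_that("an empty high set is rejected", {
  m <- trade_off_model()
  sc <- classify_scores(c("R1", "R2", "R3"), c(0.1, 0.1, 0.1))
  expect_error(reduce_model(m, sc, media_of("A[e]"),
                            require_growth = FALSE), "empty high")
})

test_that("the scaling factor cancels in the arg-min", {
  m <- trade_off_model(r2_coef = 0.001)
  sc <- classify_scores(c("R1", "R2", "R3"), c(5, 0.19, 5))
  sols <- lapply(c(0.01, 0.1, 0.25), function(a) {
    reduce_model(m, sc, media_of("A[e]"), a = a, require_growth = FALSE)
  })
  for (s in sols) {
    expect_identical(s$active_high, sols[[1]]$active_high)
    expect_identical(s$active_low, sols[[1]]$active_low)
  }
  # objectives scale linearly in a
  expect_equal(sols[[2]]$objective / sols[[1]]$objective, 10,
               tolerance = 1e-4)
})

test_that("weakly raising a low score toward high never shrinks activity", {
  m <- trade_off_model(r2_coef = 0.001)
  media <- media_of("A[e]")
  active_counts <- vapply(c(0.01, 0.1, 0.19, 0.3), function(s) {
    sc <- classify_scores(c("R1", "R2", "R3"), c(5, s, 5))
    sol <- reduce_model(m, sc, media, require_growth = FALSE)
    length(sol$active_high) + length(sol$active_low)
  }, numeric(1))
  expect_true(all(diff(active_counts) >= 0))
})
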