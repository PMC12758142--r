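test_that("Hill rate laws match hand-evaluated values and reject bad input", {
  # activating: zero at zero ligand, half-saturation at K, hand value
  expect_equal(hillActivating(0, 1, 5), 0)
  expect_equal(hillActivating(5, 1, 5), 0.5)
  expect_equal(hillActivating(15, 2, 5), 1.5)
  # repressing: mirror image
  expect_equal(hillRepressing(0, 1, 5), 1)
  expect_equal(hillRepressing(5, 1, 5), 0.5)
  expect_equal(hillRepressing(15, 2, 5), 0.5)
  expect_error(hillActivating(1, 1, 0), "K")
  expect_error(hillActivating(-1, 1, 1), "t3")
  expect_error(hillRepressing(1, -1, 1), "lambda_max")
})

test_that("Hill functions are bounded and monotone on a T3 grid", {
  grid <- c(0, 10^seq(-3, 3, length.out = 50))
  act <- hillActivating(grid, 0.7, 2.5)
  rep_ <- hillRepressing(grid, 0.7, 2.5)
  expect_true(all(act >= 0 & act <= 0.7))
  expect_true(all(rep_ >= 0 & rep_ <= 0.7))
  expect_true(all(diff(act) >= 0))
  expect_true(all(diff(rep_) <= 0))
})

test_that("parameter container validates its invariants", {
  expect_s4_class(ConeModelParams(), "ConeModelParams")
  expect_error(ConeModelParams(K_S = 0), "K_S")
  expect_error(ConeModelParams(lambda_N = -1), "non-negative")
  expect_error(ConeModelParams(mutant_degradation_fraction = 1.5), "<= 1")
  expect_error(ConeModelParams(t_max = 0), "t_max")
})

test_that("propensities combine counts and per-cell rates as specified", {
  p0 <- ConeModelParams()
  empty <- setNames(numeric(7), cellClasses())
  expect_true(all(propensities(empty, 1, p0) == 0))

  # at T3 = K_S = K_L, both Hill rates are lambda_max / 2
  p <- ConeModelParams(lambda_S_max = 0.02, K_S = 1, lambda_L_max = 0.02,
                       K_L = 1, lambda_N = 0.01)
  cts <- empty; cts["RPC"] <- 100
  a <- propensities(cts, 1, p)
  expect_equal(unname(a["RPC->IMMATURE_S"]), 1.0)
  expect_equal(unname(a["RPC->IMMATURE_LM"]), 1.0)
  expect_equal(unname(a["RPC->NONCONE"]), 1.0)
  expect_true(all(a[4:7] == 0))

  # secondary firing uses the opposite lineage's program: immature S fire g
  p2 <- ConeModelParams(lambda_L_max = 0.5, K_L = 1e-9, mu_S = 0.3)
  cts2 <- empty; cts2["IMMATURE_S"] <- 10
  a2 <- propensities(cts2, 1e6, p2)  # saturating T3
  expect_equal(unname(a2["IMMATURE_S->COEXPRESSING"]), 5, tolerance = 1e-6)
  expect_equal(unname(a2["IMMATURE_S->MATURE_S"]), 3)
})

test_that("propensities are linear in class counts", {
  p <- ConeModelParams()
  cts <- setNames(c(120, 30, 20, 5, 5, 2, 40), cellClasses())
  a1 <- propensities(cts, 0.8, p)
  a2 <- propensities(2 * cts, 0.8, p)
  expect_equal(a2, 2 * a1)
})

test_that("T3 derivative follows source-minus-degradation with the mutant scaling", {
  empty <- setNames(numeric(7), cellClasses())
  p <- ConeModelParams(sigma_basal = 2, sigma_exo = 5, t_exo = 42,
                       delta = 1e-3)
  # no degradation at zero T3; exogenous source gated by time
  expect_equal(t3Derivative(empty, 0, 0, p), 2)
  expect_equal(t3Derivative(empty, 0, 42, p), 7)

  # hand value: 1000 cells, delta 1e-3, fraction 0.06, T3 = 2 -> -0.12
  cts <- empty; cts["RPC"] <- 1000
  pm <- ConeModelParams(sigma_basal = 0, delta = 1e-3,
                        mutant_degradation_fraction = 0.06)
  expect_equal(t3Derivative(cts, 2, 0, pm), -0.12)

  # mutant scaling acts on the degradation term only
  pw <- ConeModelParams(sigma_basal = 3, delta = 1e-3)
  pmu <- ConeModelParams(sigma_basal = 3, delta = 1e-3,
                         mutant_degradation_fraction = 0.06)
  dw <- t3Derivative(cts, 2, 0, pw) - 3
  dm <- t3Derivative(cts, 2, 0, pmu) - 3
  expect_equal(dm, 0.06 * dw)

  # variant: immature cones join the degrading pool
  cts2 <- cts; cts2["IMMATURE_S"] <- 200; cts2["IMMATURE_LM"] <- 300
  pv <- ConeModelParams(sigma_basal = 0, delta = 1e-3,
                        dio3_in_immature_cones = TRUE)
  expect_equal(t3Derivative(cts2, 1, 0, pv), -1e-3 * 1500)
})

test_that("events conserve total cell number and reject empty sources", {
  cts <- setNames(c(5, 1, 1, 0, 0, 0, 0), cellClasses())
  out <- applyEvent(cts, 3)
  expect_equal(out[["RPC"]], 4)
  expect_equal(out[["NONCONE"]], 1)
  expect_equal(sum(out), sum(cts))
  # every event in the set conserves the total
  for (i in seq_len(nrow(eventTable()))) {
    expect_equal(sum(applyEvent(cts, i)), sum(cts))
  }
  none <- setNames(numeric(7), cellClasses())
  expect_error(applyEvent(none, 1), "no 'RPC' cells")
})

test_that("the event set is exactly the seven specified transitions", {
  ev <- eventTable()
  expect_equal(nrow(ev), 7)
  expect_setequal(
    paste(ev$source, ev$target, sep = "->"),
    c("RPC->IMMATURE_S", "RPC->IMMATURE_LM", "RPC->NONCONE",
      "IMMATURE_S->MATURE_S", "IMMATURE_LM->MATURE_LM",
      "IMMATURE_S->COEXPRESSING", "IMMATURE_LM->COEXPRESSING"))
  # terminal classes have no outgoing events
  expect_false(any(ev$source %in%
    c("MATURE_S", "MATURE_LM", "COEXPRESSING", "NONCONE")))
})

test_that("parameters round-trip through YAML and unknown keys are rejected", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  p <- ConeModelParams(mutant_degradation_fraction = 0.06, K_L = 2.2,
                       dio3_in_immature_cones = TRUE)
  writeModelParams(p, f)
  q <- readModelParams(f)
  for (s in slotNames(p)) expect_identical(slot(q, s), slot(p, s))
  expect_error(paramsFromList(list(K_S = 1, lambda_Z = 2)), "lambda_Z")
  expect_error(readModelParams(tempfile()), "not found")
})
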