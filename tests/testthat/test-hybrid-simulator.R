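test_that("a frozen system stays constant and exits at the horizon", {
  p <- frozenParams(t_max = 100)
  tr <- simulateOrganoid(p, initial_rpc = 10, seed = 1, t3_initial = 0)
  sn <- snapshots(tr)
  expect_equal(terminalStatus(tr), "horizon")
  expect_true(all(sn$RPC == 10))
  expect_equal(max(sn$time), 100)
})

test_that("a single cell with only the non-cone rate completes as NONCONE", {
  p <- frozenParams(lambda_N = 0.5, t_max = 1000)
  tr <- simulateOrganoid(p, initial_rpc = 1, seed = 3)
  expect_equal(terminalStatus(tr), "complete")
  expect_equal(unname(finalState(tr)$counts[["NONCONE"]]), 1)
  expect_equal(totalPhotoreceptors(tr), 0)
})

test_that("identical inputs give bit-identical trajectories", {
  p <- ConeModelParams()
  tr1 <- simulateOrganoid(p, initial_rpc = 800, seed = 11)
  tr2 <- simulateOrganoid(p, initial_rpc = 800, seed = 11)
  expect_identical(snapshots(tr1), snapshots(tr2))
  tr3 <- simulateOrganoid(p, initial_rpc = 800, seed = 12)
  expect_false(identical(snapshots(tr1), snapshots(tr3)))
})

test_that("trajectory snapshots satisfy the structural invariants", {
  tr <- simulateOrganoid(ConeModelParams(), initial_rpc = 2000, seed = 4)
  sn <- snapshots(tr)
  expect_true(validObject(tr))
  expect_equal(sn$time[1], 0)
  expect_equal(sn$T3[1], 0)
  tot <- rowSums(sn[, cellClasses()])
  expect_true(all(tot == 2000))
  for (cl in c("MATURE_S", "MATURE_LM", "COEXPRESSING", "NONCONE"))
    expect_true(all(diff(sn[[cl]]) >= 0))
})

test_that("closed-form T3 solution matches its hand-derived special cases", {
  p <- ConeModelParams(sigma_basal = 0, delta = 2e-3)
  # pure decay
  expect_equal(t3ClosedForm(3, 500, p, t3_initial = 4),
               4 * exp(-2e-3 * 500 * 3))
  # steady state
  p2 <- ConeModelParams(sigma_basal = 1, delta = 1e-3)
  expect_equal(t3ClosedForm(1e6, 2000, p2, t3_initial = 0), 1 / 2, tolerance = 1e-9)
  # sigma = 1, lam = 0.5, T0 = 0, t = 2 -> 2 (1 - e^-1)
  p3 <- ConeModelParams(sigma_basal = 1, delta = 5e-4)
  expect_equal(t3ClosedForm(2, 1000, p3, t3_initial = 0),
               2 * (1 - exp(-1)))
  # no degraders: linear growth
  expect_equal(t3ClosedForm(7, 0, p2, t3_initial = 1), 8)
})

test_that("the T3 integrator matches the closed form to 1e-6 relative accuracy", {
  # counts frozen (no fate events), so the degrader pool is constant
  for (cfg in list(list(n0 = 1000, sigma = 1, delta = 1e-3, t30 = 0),
                   list(n0 = 10000, sigma = 0, delta = 1e-3, t30 = 5),
                   list(n0 = 200, sigma = 2, delta = 1e-2, t30 = 1))) {
    p <- frozenParams(sigma_basal = cfg$sigma, delta = cfg$delta, t_max = 120)
    tr <- simulateOrganoid(p, initial_rpc = cfg$n0, seed = 1,
                           t3_initial = cfg$t30, record_every = 1L)
    sn <- snapshots(tr)
    ana <- t3ClosedForm(sn$time, cfg$n0, p, t3_initial = cfg$t30)
    scale <- pmax(ana, 1e-8)
    expect_lt(max(abs(sn$T3 - ana) / scale), 1e-6)
  }
})

test_that("pure-death dynamics match the exact Gillespie reference", {
  # only RPC -> NONCONE at rate lambda_N: completion time has mean H_n / lambda
  n0 <- 200; lamN <- 0.1; nrep <- 300
  p <- frozenParams(lambda_N = lamN, t_max = 2000)
  hyb <- vapply(seq_len(nrep), function(i) {
    tr <- simulateOrganoid(p, initial_rpc = n0, seed = 2000 + i,
                           record_every = 1000000L)
    c(finalState(tr)$time, finalState(tr)$counts[["NONCONE"]])
  }, numeric(2))
  expect_true(all(hyb[2, ] == n0))
  expected_mean <- sum(1 / seq_len(n0)) / lamN
  expected_se <- sqrt(sum(1 / seq_len(n0)^2) / lamN^2 / nrep)
  expect_lt(abs(mean(hyb[1, ]) - expected_mean), 4 * expected_se)

  # cross-check the analytic mean against the independent SSA oracle
  orc <- vapply(seq_len(nrep), function(i)
    ssaConstantRates(n0, 0, 0, lamN, 0, 0, seed = 5000 + i)$time, numeric(1))
  expect_lt(abs(mean(orc) - expected_mean), 4 * expected_se)
  # hybrid and oracle agree with each other
  expect_lt(abs(mean(hyb[1, ]) - mean(orc)),
            4 * sqrt(2) * expected_se)
})

test_that("with constant rates the hybrid final counts match the exact SSA law", {
  cr <- constantRateParams()
  nrep <- 300; n0 <- 150
  hyb <- finalCountsMatrix(lapply(seq_len(nrep), function(i)
    simulateOrganoid(cr$params, initial_rpc = n0, seed = 3000 + i,
                     t3_initial = cr$t3_initial, record_every = 1000000L)))
  pr <- terminalFateProbs(cr$f, cr$g, 0.1, 0.2, 0.25)
  pooled <- colSums(hyb)[names(pr)]
  chi <- suppressWarnings(chisq.test(pooled, p = pr))
  expect_gt(chi$p.value, 0.01)
  # and the oracle itself agrees with the closed-form probabilities
  orc <- t(vapply(seq_len(nrep), function(i)
    ssaConstantRates(n0, cr$f, cr$g, 0.1, 0.2, 0.25, seed = 800 + i)$counts,
    setNames(numeric(7), cellClasses())))
  chi2 <- suppressWarnings(chisq.test(colSums(orc)[names(pr)], p = pr))
  expect_gt(chi2$p.value, 0.01)
})

test_that("halving the step leaves final mean counts unchanged within MC error", {
  p <- ConeModelParams()
  n0 <- 2000; nrep <- 200
  run <- function(step) finalCountsMatrix(lapply(seq_len(nrep), function(i)
    simulateOrganoid(p, initial_rpc = n0, seed = 7000 + i, step = step,
                     record_every = 1000000L)))
  a <- run(0.1); b <- run(0.05)
  for (cl in c("MATURE_S", "MATURE_LM", "NONCONE")) {
    se <- sqrt(var(a[, cl]) / nrep + var(b[, cl]) / nrep)
    expect_lt(abs(mean(a[, cl]) - mean(b[, cl])), 2.5 * se)
  }
})

test_that("condition presets modify exactly the specified parameters", {
  base <- ConeModelParams()
  wt <- conditionParams("WT", base)
  expect_equal(wt@mutant_degradation_fraction, 1)
  expect_equal(wt@sigma_exo, 0)
  mut <- conditionParams("MUT", base)
  expect_equal(mut@mutant_degradation_fraction, 0.06)
  # degradation term is exactly 6% of wild type at identical state
  cts <- setNames(c(1000, 0, 0, 0, 0, 0, 0), cellClasses())
  src <- base@sigma_basal
  expect_equal(t3Derivative(cts, 2, 0, mut) - src,
               0.06 * (t3Derivative(cts, 2, 0, wt) - src))
  wt3 <- conditionParams("WT_T3", base, exo_rate = 3)
  expect_equal(wt3@sigma_exo, 3)
  expect_equal(wt3@mutant_degradation_fraction, 1)
  expect_error(conditionParams("WTX", base), "condition")
})
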