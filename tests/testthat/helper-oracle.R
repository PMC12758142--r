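# Independent reference implementations used as oracles. These deliberately
# avoid the package's hybrid C++ path: plain event-driven Gillespie in R for
# constant per-cell rates, and closed-form fate probabilities.

# Exact SSA for the full event set with CONSTANT per-cell rates f, g
# (no T3 coupling). Returns final counts named by cellClasses().
ssaConstantRates <- function(n0, f, g, lamN, muS, muL, seed) {
  set.seed(seed)
  cts <- setNames(numeric(7), cellClasses())
  cts["RPC"] <- n0
  t <- 0
  repeat {
    a <- c(cts[["RPC"]] * f, cts[["RPC"]] * g, cts[["RPC"]] * lamN,
           cts[["IMMATURE_S"]] * muS, cts[["IMMATURE_LM"]] * muL,
           cts[["IMMATURE_S"]] * g, cts[["IMMATURE_LM"]] * f)
    A <- sum(a)
    if (A <= 0) break
    t <- t + rexp(1L, A)
    ev <- sample.int(7L, 1L, prob = a)
    src <- c("RPC", "RPC", "RPC", "IMMATURE_S", "IMMATURE_LM",
             "IMMATURE_S", "IMMATURE_LM")[ev]
    tgt <- c("IMMATURE_S", "IMMATURE_LM", "NONCONE", "MATURE_S", "MATURE_LM",
             "COEXPRESSING", "COEXPRESSING")[ev]
    cts[[src]] <- cts[[src]] - 1
    cts[[tgt]] <- cts[[tgt]] + 1
  }
  list(counts = cts, time = t)
}

# Closed-form terminal-fate probabilities per starting RPC under constant
# rates: competing risks at the RPC stage, then maturation-vs-secondary-firing
# race at the immature stage.
terminalFateProbs <- function(f, g, lamN, muS, muL) {
  tot <- f + g + lamN
  pS <- f / tot; pL <- g / tot; pN <- lamN / tot
  c(MATURE_S = pS * muS / (muS + g),
    MATURE_LM = pL * muL / (muL + f),
    COEXPRESSING = pS * g / (muS + g) + pL * f / (muL + f),
    NONCONE = pN)
}

# Parameter set whose per-cell rates are constant over time: no T3 source and
# no degradation, so T3 stays at its initial value and the Hill rates are
# frozen constants.
constantRateParams <- function(t3c = 1, lamS = 0.2, KS = 1, lamL = 0.3,
                               KL = 2, lamN = 0.1, muS = 0.2, muL = 0.25) {
  list(params = ConeModelParams(
         lambda_S_max = lamS, K_S = KS, lambda_L_max = lamL, K_L = KL,
         lambda_N = lamN, mu_S = muS, mu_L = muL,
         sigma_basal = 0, sigma_exo = 0, delta = 0),
       t3_initial = t3c,
       f = lamS * t3c / (KS + t3c),
       g = lamL * t3c / (KL + t3c))
}

# Frozen-population parameters: no fate events at all (unless overridden),
# so only the T3 dynamics run.
frozenParams <- function(...) {
  args <- modifyList(list(lambda_S_max = 0, lambda_L_max = 0, lambda_N = 0,
                          mu_S = 0, mu_L = 0), list(...))
  do.call(ConeModelParams, args)
}

finalCountsMatrix <- function(trajs) {
  do.call(rbind, lapply(trajs, function(tr) finalState(tr)$counts))
}
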