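# Experiment drivers for the convergence-trend checks: per-fold posterior-mean
# stability of the variance parameters and the AXE / manual-CV gap as the
# number of clusters grows.

# One balanced random-intercept design at a given J: median over LCO folds of
#  - |E(phi | Y_-s) / E(phi | Y) - 1|
#  - |E(sigma^2 | Y_-s) / E(sigma^2 | Y) - 1|   (the Sigma = sigma^2 I analogue)
#  - ||AXE_s - MCV_s|| / ||MCV_s||              (relative predictive gap)
lcoStabilityAtJ <- function(J, seed, nj = 8, M = 400, burn = 200) {
  sim <- simulateLmm(J, nj, sigma = 1, phi = 1, seed = seed)
  d <- sim$data
  prior <- priorSpec(P1 = 2)
  full <- gibbsLmm(d, prior, M = M, burn = burn, chains = 1, seed = seed + 1)
  phiFull <- full@scaleMean[["phi"]]
  sig2Full <- mean(full@scaleDraws[, "theta"]^2)
  plug <- posteriorPlugin(full, prior, d)
  plan <- foldPlan(d, "lco")
  axe <- axePredictLmm(d, plan, plug, prior)
  X <- designMatrix(d)
  phiDev <- sigDev <- gap <- numeric(nFolds(plan))
  for (j in seq_len(nFolds(plan))) {
    s <- plan@folds[[j]]
    tr <- setdiff(seq_len(nObs(d)), s)
    fit <- gibbsLmm(d[tr], prior, M = M, burn = burn, chains = 1,
                    seed = axecv:::mixSeed(seed, j))
    phiDev[j] <- abs(fit@scaleMean[["phi"]] / phiFull - 1)
    sigDev[j] <- abs(mean(fit@scaleDraws[, "theta"]^2) / sig2Full - 1)
    mcvJ <- as.numeric(X[s, , drop = FALSE] %*% fit@betaMean)
    axeJ <- axe@yPred[axe@foldId == j]
    gap[j] <- sqrt(sum((axeJ - mcvJ)^2)) / sqrt(sum(mcvJ^2))
  }
  c(phi = median(phiDev), sigma = median(sigDev), gap = median(gap))
}

# All three stability statistics on a (seed x J) grid, one row per cell.
trendTable <- function(Jvalues, seeds) {
  do.call(rbind, lapply(seeds, function(sd0)
    do.call(rbind, lapply(Jvalues, function(J) {
      st <- lcoStabilityAtJ(J, seed = sd0)
      data.frame(seed = sd0, J = J, phi = st[["phi"]],
                 sigma = st[["sigma"]], gap = st[["gap"]])
    }))))
}

# Per-seed Spearman correlation of one statistic against J.
spearmanBySeed <- function(tab, stat) {
  vapply(split(tab, tab$seed),
         function(g) cor(g$J, g[[stat]], method = "spearman"), 1.0)
}

# Cluster-subsets experiment: per instance, |LRR| of AXE against per-fold
# manual CV on the designated test cluster.
runSubsetsExperiment <- function(reps = 3, N = 100, seed = 1,
                                 M = 400, burn = 200,
                                 Jvalues = c(3, 4, 6, 9, 12),
                                 deltaValues = seq(0.3, 0.7, 0.1)) {
  des <- radonSubsetsDesign(Jvalues = Jvalues, deltaValues = deltaValues,
                            reps = reps, N = N, seed = seed)
  out <- do.call(rbind, lapply(seq_along(des), function(i) {
    inst <- des[[i]]
    d <- inst$data
    prior <- priorSpec(P1 = 2)
    full <- gibbsLmm(d, prior, M = M, burn = burn, chains = 1,
                     seed = axecv:::mixSeed(seed, 1000 + i))
    plug <- posteriorPlugin(full, prior, d)
    axe <- axePredictLmm(d, inst$plan, plug, prior)
    mcv <- mcvPredict(d, inst$plan, prior, M = M, burn = burn, chains = 1,
                      seed = axecv:::mixSeed(seed, 2000 + i))
    l <- lrr(axe, mcv, d, inst$plan)
    data.frame(J = inst$J, delta = inst$delta, absLrr = abs(unname(l[1])))
  }))
  out
}

strictlyMonotone <- function(x) all(diff(x) > 0) || all(diff(x) < 0)
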