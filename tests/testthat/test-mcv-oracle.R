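# All Monte Carlo checks compare posterior means to closed forms within
# 3 Monte Carlo standard errors (batch-means estimate).

singleMeanData <- function(y) {
  cl <- factor(rep("a", length(y)))
  regressionData(y, matrix(0, length(y), 0),
                 matrix(1, length(y), 1), cl)
}

test_that("conjugate single-mean model recovers n*ybar/(n+1)", {
  d <- singleMeanData(c(1, 1, 1, 1))
  # mu ~ N(0, 1) via sigma point mass 1; phi fixed at 1
  prior <- fixedVariancePrior(d, sigma = 1, phi = 1, P1 = 0)
  fit <- gibbsLmm(d, prior, M = 1500, burn = 500, chains = 2, seed = 3)
  expect_lt(abs(fit@betaMean[1] - 0.8), 3 * fit@betaMcse[1])
})

test_that("point-mass hyperpriors reproduce the closed-form conditional posterior mean", {
  toy <- makeLmmToy(J = 4, nj = 5, sigma = 1.2, phi = 0.8, seed = 6)
  prior <- fixedVariancePrior(toy$data, sigma = 1.2, phi = 0.8)
  fit <- gibbsLmm(toy$data, prior, M = 1500, burn = 500, chains = 2, seed = 9)
  want <- conditionalPosteriorMean(designMatrix(toy$data), toy$data@y,
                                   axecv:::penaltyFromPlugin(toy$prior, toy$plugin),
                                   0.8)
  expect_true(all(abs(fit@betaMean - want) <= 3 * pmax(fit@betaMcse, 1e-12)))
  expect_equal(unname(fit@scaleMean[c("theta", "phi")]), c(1.2, 0.8))
})

test_that("identical seed and settings give bit-identical summaries", {
  toy <- makeLmmToy(J = 3, nj = 4, seed = 2)
  prior <- priorSpec(P1 = 2)
  a <- gibbsLmm(toy$data, prior, M = 200, burn = 100, chains = 2, seed = 42)
  b <- gibbsLmm(toy$data, prior, M = 200, burn = 100, chains = 2, seed = 42)
  expect_identical(a@betaDraws, b@betaDraws)
  expect_identical(a@scaleMean, b@scaleMean)
})

test_that("improper configurations are rejected before sampling", {
  cl <- factor(c("a", "a", "b", "b"))
  Z <- axecv:::clusterIndicators(cl)
  d <- regressionData(1:4, cbind(1, c(0, 0, 0, 0)), Z, cl)
  expect_error(gibbsLmm(d, priorSpec(P1 = 2), M = 10, burn = 5),
               "improper|all-zero")
  toy <- makeLmmToy()
  expect_error(gibbsLmm(toy$data,
                        priorSpec(P1 = 2, sigmaFamily = "unstructured"),
                        M = 10, burn = 5),
               "unstructured")
  expect_error(mcmcGlmm(toy$data, toy$prior, M = 10, burn = 5), "gibbsLmm")
})

test_that("half-t posterior scale means track the REML estimates at large J", {
  skip_if_not_installed("lme4")
  sim <- simulateLmm(30, 8, sigma = 1, phi = 1, seed = 13)
  prior <- priorSpec(P1 = 2)
  fit <- gibbsLmm(sim$data, prior, M = 800, burn = 300, chains = 2, seed = 5)
  df <- data.frame(y = sim$data@y, x1 = sim$data@Xfixed[, "x1"],
                   g = sim$data@clusterId)
  reml <- as.data.frame(lme4::VarCorr(lme4::lmer(y ~ x1 + (1 | g), df)))$sdcor
  # weak half-t prior, 30 clusters: posterior means sit near the REML fit
  expect_lt(abs(fit@scaleMean[["theta"]] - reml[1]), 0.15)
  expect_lt(abs(fit@scaleMean[["phi"]] - reml[2]), 0.15)
})

test_that("poisson intercept sampler agrees with dense quadrature", {
  cl <- factor(c("a", "a"))
  d <- regressionData(c(1, 3), matrix(1, 2, 1),
                      matrix(0, 2, 0), cl, family = "poisson",
                      termId = factor(character(0)),
                      thetaCluster = character(0))
  prior <- priorSpec(P1 = 1)  # flat prior on the intercept, no random block
  fit <- mcmcGlmm(d, prior, M = 3000, burn = 1000, chains = 2, seed = 4)
  want <- poissonInterceptQuadOracle(c(1, 3))
  expect_lt(abs(fit@betaMean[1] - want), 3 * max(fit@betaMcse[1], 0.01))
  expect_lt(abs(fit@betaMean[1] - log(2)), 0.5)  # mode region near log 2
})

test_that("symmetric binomial data give a zero posterior mean", {
  cl <- factor(rep("a", 6))
  d <- regressionData(rep(1, 6), matrix(1, 6, 1), matrix(0, 6, 0), cl,
                      family = "binomial", trials = rep(2, 6),
                      termId = factor(character(0)),
                      thetaCluster = character(0))
  prior <- priorSpec(Cinv = matrix(1))  # N(0,1) prior keeps it proper
  fit <- mcmcGlmm(d, prior, M = 3000, burn = 1000, chains = 2, seed = 10)
  expect_lt(abs(fit@betaMean[1]), 3 * max(fit@betaMcse[1], 0.01))
})

test_that("plug-in construction rebuilds Sigma from posterior means of its parameters", {
  toy <- makeLmmToy()
  fakeSummary <- new("PosteriorSummary",
                     betaMean = rep(0, 6), betaMcse = rep(0.01, 6),
                     scaleMean = c(theta = 1.5, phi = 1),
                     scaleMcse = c(theta = 0.01, phi = 0.01),
                     betaDraws = matrix(0, 10, 6),
                     scaleDraws = matrix(1, 10, 2),
                     settings = list(retained = 10))
  plug <- posteriorPlugin(fakeSummary, toy$prior, toy$data)
  expect_equal(plug@SigmaInv, diag(1 / 2.25, 4))
  expect_equal(plug@phiHat, 1)
  expect_match(plug@provenance, "posterior mean")
  # missing parameter errors
  badSummary <- fakeSummary
  badSummary@scaleMean <- c(phi = 1)
  expect_error(posteriorPlugin(badSummary, toy$prior, toy$data), "missing")
})

test_that("CAR plug-in is rebuilt from (tau, rho) means and is positive definite", {
  sim <- simulateCar(3, 3, rho = 0.4, tau = 1, phi = 0.5, obsPerSite = 3,
                     seed = 7)
  prior <- priorSpec(P1 = 1, sigmaFamily = "car", adjacency = sim$adjacency)
  fit <- gibbsLmm(sim$data, prior, M = 600, burn = 300, chains = 2, seed = 2)
  plug <- posteriorPlugin(fit, prior, sim$data)
  expect_true(all(c("tau", "rho") %in% names(plug@params)))
  W <- sim$adjacency
  want <- (diag(rowSums(W)) - plug@params$rho * W) / plug@params$tau^2
  expect_equal(plug@SigmaInv, want)
  expect_true(min(eigen(plug@SigmaInv, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)
})

test_that("manual CV with point-mass variances matches AXE within Monte Carlo error", {
  toy <- makeLmmToy(J = 4, nj = 4, sigma = 1, phi = 1, seed = 17)
  prior <- fixedVariancePrior(toy$data, sigma = 1, phi = 1)
  mcv <- mcvPredict(toy$data, toy$plan, prior, M = 1200, burn = 400,
                    chains = 2, seed = 21)
  axe <- axePredictLmm(toy$data, toy$plan, toy$plugin, toy$prior)
  ord <- order(mcv@rowId); orda <- order(axe@rowId)
  expect_true(all(abs(mcv@yPred[ord] - axe@yPred[orda]) <=
                    3 * pmax(mcv@mcse[ord], 1e-10)))
})

test_that("a fold holding out every row is rejected", {
  toy <- makeLmmToy(J = 2, nj = 3)
  plan <- foldPlan(toy$data, "custom", folds = list(1:6))
  expect_error(mcvPredict(toy$data, plan, toy$prior, M = 50, burn = 10),
               "empty training")
})

test_that("LOO manual CV on a fixed-variance toy matches joint-normal conditioning", {
  set.seed(23)
  cl <- factor(sprintf("r%d", 1:6))
  Z <- axecv:::clusterIndicators(cl)
  d <- regressionData(rnorm(6, 1), matrix(1, 6, 1), Z, cl)
  prior <- fixedVariancePrior(d, sigma = 1, phi = 1, P1 = 1)
  # finite N(0, 25) prior on the mean so the joint normal is proper
  prior@Cinv <- matrix(1 / 25)
  plan <- foldPlan(d, "loo")
  mcv <- mcvPredict(d, plan, prior, M = 1500, burn = 500, chains = 2, seed = 8)
  X <- designMatrix(d)
  Lam <- axecv:::blockDiag(matrix(25), diag(6))
  for (j in 1:6) {
    want <- jointNormalOracle(X, d@y, Lam, 1, j)
    got <- mcv@yPred[mcv@rowId == j]
    expect_lt(abs(got - want), 3 * max(mcv@mcse[mcv@rowId == j], 1e-3))
  }
})

test_that("conjugate posterior means stay within 3 MC-SEs of closed forms across seeds", {
  # 20 seeded single-mean instances: y_i ~ N(mu, phi^2), mu ~ N(0, sigma^2)
  # closed form: E(mu|Y) = sigma^2 sum(y) / (n sigma^2 + phi^2)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:8, 1)
    sigma <- runif(1, 0.5, 2); phi <- runif(1, 0.5, 2)
    y <- rnorm(n, 1, phi)
    d <- singleMeanData(y)
    prior <- fixedVariancePrior(d, sigma = sigma, phi = phi, P1 = 0)
    fit <- gibbsLmm(d, prior, M = 600, burn = 200, chains = 2,
                    seed = 100 + seed)
    want <- sigma^2 * sum(y) / (n * sigma^2 + phi^2)
    expect_lt(abs(fit@betaMean[1] - want), 3 * max(fit@betaMcse[1], 1e-3))
  }
})
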