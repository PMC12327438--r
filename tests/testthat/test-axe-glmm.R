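test_that("link families evaluate the IWLS triples", {
  logit <- linkFamily("binomial-logit")
  expect_equal(logit@gprime(0.5), 4)
  expect_equal(logit@v(0.5), 0.25)
  pois <- linkFamily("poisson-log")
  expect_equal(pois@gprime(2), 0.5)
  expect_equal(pois@v(2), 2)
  id <- linkFamily("gaussian-identity")
  expect_equal(id@gprime(c(-3, 7)), c(1, 1))
  expect_equal(id@v(c(-3, 7)), c(1, 1))
  expect_error(linkFamily("gamma-inverse"), "unknown")
  # link / inverse-link consistency on a grid
  eta <- seq(-5, 5, length.out = 101)
  expect_equal(logit@g(plogis(eta)), eta, tolerance = 1e-12)
  expect_equal(pois@g(exp(eta)), eta, tolerance = 1e-12)
})

glmmToy <- function(family, n = 4, seed = 8) {
  set.seed(seed)
  cl <- factor(rep(c("a", "b"), each = n / 2))
  Z <- axecv:::clusterIndicators(cl)
  y <- if (family == "binomial") rbinom(n, 1, 0.5) else rpois(n, 2)
  regressionData(y, cbind(intercept = rep(1, n)), Z, cl, family = family)
}

test_that("working response and weights match the IWLS formulas at beta = 0", {
  # logit, eta = 0, y = 1: u = 0.5, Ytilde = (1 - 0.5) * 4 = 2, w = 0.25
  cl <- factor(c("a", "a"))
  d <- regressionData(c(1, 0), matrix(1, 2, 1),
                      axecv:::clusterIndicators(cl), cl, family = "binomial")
  wm <- workingResponse(d, rep(0, 2), linkFamily("binomial-logit"))
  expect_equal(wm@u, c(0.5, 0.5))
  expect_equal(wm@Ytilde, c(2, -2))
  expect_equal(wm@w, c(0.25, 0.25))

  # log link, eta = 0, y = 3: u = 1, Ytilde = 2, w = 1
  dp <- regressionData(c(3, 1), matrix(1, 2, 1),
                       axecv:::clusterIndicators(cl), cl, family = "poisson")
  wmp <- workingResponse(dp, rep(0, 2), linkFamily("poisson-log"))
  expect_equal(wmp@Ytilde, c(2, 0))
  expect_equal(wmp@w, c(1, 1))

  # identity: Ytilde = y, w = 1/phi^2
  dg <- regressionData(c(1.5, -2), matrix(1, 2, 1),
                       axecv:::clusterIndicators(cl), cl)
  wmg <- workingResponse(dg, rep(0, 2), linkFamily("gaussian-identity"),
                         phi2 = 4)
  expect_equal(wmg@Ytilde, c(1.5, -2))
  expect_equal(wmg@w, c(0.25, 0.25))
})

test_that("binomial trials scale the weights on the proportion scale", {
  cl <- factor(c("a", "a"))
  d <- regressionData(c(5, 2), matrix(1, 2, 1),
                      axecv:::clusterIndicators(cl), cl, family = "binomial",
                      trials = c(10, 10))
  wm <- workingResponse(d, rep(0, 2), linkFamily("binomial-logit"))
  expect_equal(wm@Ytilde, c(0 + (0.5 - 0.5) * 4, (0.2 - 0.5) * 4))
  expect_equal(wm@w, c(2.5, 2.5))  # a * u(1-u) = 10 * 0.25
})

test_that("IWLS: gaussian gives OLS, intercept-only poisson gives log ybar, logit matches Newton", {
  set.seed(2)
  cl <- factor(rep(c("a", "b"), each = 3))
  Z <- axecv:::clusterIndicators(cl)
  dg <- regressionData(rnorm(6), matrix(rnorm(6), dimnames = list(NULL, "x1")),
                       Z, cl)
  # near-zero penalty on the random block; flat fixed prior: OLS limit
  fit <- iwlsFit(dg, diag(c(0, 1e-12, 1e-12)), linkFamily("gaussian-identity"))
  X <- designMatrix(dg)
  expect_true(fit@converged)
  expect_equal(as.numeric(X %*% fit@beta),
               as.numeric(X %*% qr.coef(qr(X), dg@y)), tolerance = 1e-6)

  # intercept-only poisson, flat penalty: MLE is log(mean(y)) = log 2
  clp <- factor(c("a", "a"))
  dp <- regressionData(c(1, 3), matrix(1, 2, 1),
                       axecv:::clusterIndicators(clp), clp, family = "poisson")
  # intercept flat; the cluster effect column duplicates it, so pin it hard
  fitp <- iwlsFit(dp, diag(c(0, 1e8)), linkFamily("poisson-log"))
  expect_equal(fitp@beta[1], log(2), tolerance = 1e-6)

  # penalized logit toy vs an independent Newton-Raphson oracle
  set.seed(77)
  Xl <- cbind(1, rnorm(4))
  cll <- factor(rep("a", 4))
  dl <- regressionData(c(1, 0, 1, 1), Xl,
                       matrix(0, 4, 0), cll, family = "binomial",
                       termId = factor(character(0)),
                       thetaCluster = character(0))
  penalty <- diag(2)
  fitl <- iwlsFit(dl, penalty, linkFamily("binomial-logit"))
  oracle <- newtonLogitOracle(Xl, dl@y, dl@trials, penalty)
  expect_true(fitl@converged)
  expect_equal(fitl@beta, oracle, tolerance = 1e-8)
})

test_that("gaussian-identity AXE-GLMM reproduces AXE-LMM exactly", {
  for (seed in 1:5) {
    toy <- makeLmmToy(J = 4, nj = 4, sigma = 1.3, phi = 0.7, seed = seed)
    penalty <- axecv:::penaltyFromPlugin(toy$prior, toy$plugin)
    fullFit <- iwlsFit(toy$data, penalty, linkFamily("gaussian-identity"),
                       phi2 = toy$plugin@phiHat^2)
    g <- axePredictGlmm(toy$data, toy$plan, toy$plugin, toy$prior, fullFit)
    l <- axePredictLmm(toy$data, toy$plan, toy$plugin, toy$prior)
    expect_equal(g@yPred, l@yPred, tolerance = 1e-12)
  }
})

logitClusterToy <- function(J = 6, nj = 10, seed = 14, sigma = 1) {
  sim <- simulateGlmm(J, nj, beta1 = c(0.2, 0.5), sigma = sigma,
                      family = "binomial", seed = seed)
  prior <- priorSpec(P1 = 2)
  plugin <- variancePlugin(phiHat = 1, data = sim$data,
                           sigma = c(theta = sigma))
  list(data = sim$data, prior = prior, plugin = plugin,
       plan = foldPlan(sim$data, "lco"))
}

test_that("frozen-weight fold solves match a direct weighted-ridge oracle", {
  toy <- logitClusterToy()
  fam <- linkFamily("binomial-logit")
  penalty <- axecv:::penaltyFromPlugin(toy$prior, toy$plugin)
  fullFit <- iwlsFit(toy$data, penalty, fam)
  est <- axePredictGlmm(toy$data, toy$plan, toy$plugin, toy$prior, fullFit)
  X <- designMatrix(toy$data)
  for (j in seq_len(nFolds(toy$plan))) {
    s <- toy$plan@folds[[j]]
    tr <- setdiff(seq_len(nrow(X)), s)
    W <- diag(fullFit@w[tr])
    beta <- solve(t(X[tr, ]) %*% W %*% X[tr, ] + penalty,
                  t(X[tr, ]) %*% W %*% fullFit@Ytilde[tr])
    want <- plogis(as.numeric(X[s, ] %*% beta))
    expect_equal(est@yPred[est@foldId == j], want, tolerance = 1e-12)
  }
})

test_that("refinement iterations converge to the from-scratch training-data IWLS fit", {
  toy <- logitClusterToy()
  fam <- linkFamily("binomial-logit")
  penalty <- axecv:::penaltyFromPlugin(toy$prior, toy$plugin)
  fullFit <- iwlsFit(toy$data, penalty, fam)
  est <- axePredictGlmm(toy$data, toy$plan, toy$plugin, toy$prior, fullFit,
                        refineIters = 50L)
  X <- designMatrix(toy$data)
  for (j in seq_len(nFolds(toy$plan))) {
    s <- toy$plan@folds[[j]]
    tr <- setdiff(seq_len(nrow(X)), s)
    refit <- iwlsFit(toy$data[tr], penalty, fam)
    want <- plogis(as.numeric(X[s, ] %*% refit@beta))
    expect_equal(est@yPred[est@foldId == j], want, tolerance = 1e-6)
  }
})

test_that("frozen-weight contract: held-out responses only enter through the full fit", {
  toy <- logitClusterToy()
  fam <- linkFamily("binomial-logit")
  penalty <- axecv:::penaltyFromPlugin(toy$prior, toy$plugin)
  fullFit <- iwlsFit(toy$data, penalty, fam)
  est <- axePredictGlmm(toy$data, toy$plan, toy$plugin, toy$prior, fullFit)
  # flip every held-out response of fold 1 AFTER the full fit: the fold-1
  # solve sees only training-row entries of the frozen Ytilde/W, so its
  # predictions cannot change
  d2 <- toy$data
  s <- toy$plan@folds[[1]]
  d2@y[s] <- d2@trials[s] - d2@y[s]
  est2 <- axePredictGlmm(d2, toy$plan, toy$plugin, toy$prior, fullFit)
  expect_identical(est2@yPred[est2@foldId == 1], est@yPred[est@foldId == 1])
})

test_that("IWLS keeps weights positive and means in the domain at every step", {
  toy <- logitClusterToy(seed = 99, sigma = 2)
  penalty <- axecv:::penaltyFromPlugin(toy$prior, toy$plugin)
  fam <- linkFamily("binomial-logit")
  beta <- rep(0, ncol(designMatrix(toy$data)))
  X <- designMatrix(toy$data)
  for (it in 1:10) {
    wm <- workingResponse(toy$data, beta, fam)
    expect_true(all(wm@w > 0))
    expect_true(all(wm@u > 0 & wm@u < 1))
    beta <- axecv:::pwlsSolve(X, wm@Ytilde, wm@w, penalty)
  }
})

test_that("refinement never increases the penalized working objective on toys", {
  toy <- logitClusterToy(seed = 5)
  fam <- linkFamily("binomial-logit")
  penalty <- axecv:::penaltyFromPlugin(toy$prior, toy$plugin)
  X <- designMatrix(toy$data)
  s <- toy$plan@folds[[1]]
  tr <- setdiff(seq_len(nrow(X)), s)
  trData <- toy$data[tr]
  Xtr <- X[tr, ]
  fullFit <- iwlsFit(toy$data, penalty, fam)
  beta <- axecv:::pwlsSolve(Xtr, fullFit@Ytilde[tr], fullFit@w[tr], penalty)
  # penalized deviance-style objective: -2 loglik + beta' P beta
  objective <- function(b) {
    u <- plogis(as.numeric(Xtr %*% b))
    -2 * sum(dbinom(trData@y, trData@trials, u, log = TRUE)) +
      as.numeric(t(b) %*% penalty %*% b)
  }
  objs <- objective(beta)
  for (k in 1:20) {
    wm <- workingResponse(trData, beta, fam)
    beta <- axecv:::pwlsSolve(Xtr, wm@Ytilde, wm@w, penalty)
    objs <- c(objs, objective(beta))
  }
  expect_true(all(diff(objs) < 1e-8))
})
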