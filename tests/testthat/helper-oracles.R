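# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use dense inversion / direct conditioning / quadrature,
# never the package's Cholesky path.

# beta-hat by explicit dense inversion of the penalized normal equations
denseSolveOracle <- function(X, y, penalty, phi) {
  V <- solve(crossprod(X) / phi^2 + penalty)
  as.numeric(V %*% (crossprod(X, y) / phi^2))
}

# E(Y_s | Y_-s) by direct joint-normal conditioning: Y ~ N(0, X Lam X' + phi^2 I)
# with Lam = blockdiag(C, Sigma) the full prior covariance.
jointNormalOracle <- function(X, y, Lam, phi, s) {
  S <- X %*% Lam %*% t(X) + diag(phi^2, nrow(X))
  tr <- setdiff(seq_len(nrow(X)), s)
  as.numeric(S[s, tr, drop = FALSE] %*% solve(S[tr, tr], y[tr]))
}

# Penalized logistic regression by damped Newton-Raphson on the exact
# penalized log-likelihood (counts y with trials a).
newtonLogitOracle <- function(X, y, a, penalty, maxIter = 200, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxIter)) {
    eta <- as.numeric(X %*% beta)
    u <- plogis(eta)
    grad <- as.numeric(crossprod(X, y - a * u)) - penalty %*% beta
    H <- crossprod(X * (a * u * (1 - u)), X) + penalty
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}

# 1-D posterior mean by dense quadrature for intercept-only poisson-log with
# flat prior on the intercept.
poissonInterceptQuadOracle <- function(y, lo = -10, hi = 10, n = 20000) {
  b <- seq(lo, hi, length.out = n)
  logpost <- vapply(b, function(bb) sum(dpois(y, exp(bb), log = TRUE)), 1.0)
  w <- exp(logpost - max(logpost))
  sum(b * w) / sum(w)
}

# Balanced gaussian random-intercept toy with a known-variance prior spec.
makeLmmToy <- function(J = 4, nj = 5, sigma = 1, phi = 1, seed = 1) {
  sim <- simulateLmm(J, nj, beta1 = c(1, 0.5), sigma = sigma, phi = phi,
                     seed = seed)
  prior <- priorSpec(P1 = ncol(sim$data@Xfixed))
  plugin <- variancePlugin(phiHat = phi, data = sim$data,
                           sigma = c(theta = sigma))
  list(data = sim$data, truth = sim$truth, prior = prior, plugin = plugin,
       plan = foldPlan(sim$data, "lco"))
}

pointMassPrior <- function(value) list(dist = "point_mass", value = value)

# Prior spec with point masses on every scale (variances fixed and known).
fixedVariancePrior <- function(data, sigma = 1, phi = 1, P1 = ncol(data@Xfixed)) {
  priorSpec(P1 = P1,
            scalePriors = setNames(rep(list(pointMassPrior(sigma)),
                                       nlevels(data@termId)),
                                   levels(data@termId)),
            phiPrior = pointMassPrior(phi))
}
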