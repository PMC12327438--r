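# Seeded generators for clustered regression data: balanced and unbalanced
# random-intercept designs with gaussian, binomial or poisson responses, a
# proper-CAR lattice design for spatially structured random effects, and the
# cluster-subsets experimental design (one large held-out cluster holding a
# fraction delta of the rows, J-1 training clusters sharing the rest).

clusterIndicators <- function(clusterId) {
  clusterId <- as.factor(clusterId)
  Z <- matrix(0, length(clusterId), nlevels(clusterId),
              dimnames = list(NULL, levels(clusterId)))
  Z[cbind(seq_along(clusterId), as.integer(clusterId))] <- 1
  Z
}

makeCovariates <- function(n, scheme) {
  switch(scheme,
    "intercept" = matrix(1, n, 1, dimnames = list(NULL, "intercept")),
    "intercept+x" = cbind(intercept = rep(1, n), x1 = rnorm(n)),
    stop(sprintf("unknown covariate scheme '%s'", scheme)))
}

#' Simulate a random-intercept linear mixed model
#'
#' Draws cluster effects theta_j ~ N(0, sigma^2) and residuals
#' eps ~ N(0, phi^2), and assembles
#' \code{y = Xfixed beta1 + theta[cluster] + eps}.
#'
#' @param J number of clusters.
#' @param clusterSizes integer vector of length J (or a single size recycled).
#' @param beta1 fixed-effect coefficients matching the covariate scheme.
#' @param sigma random-intercept standard deviation (>= 0; 0 degenerates to
#'   no cluster effect).
#' @param phi residual standard deviation (> 0).
#' @param scheme covariate scheme: "intercept" or "intercept+x".
#' @param seed integer seed; the same seed and design give an identical
#'   dataset.
#' @return list with elements \code{data} ([RegressionData-class]) and
#'   \code{truth} ([SimTruth-class]).
#' @export
simulateLmm <- function(J, clusterSizes, beta1 = c(1, 0.5), sigma = 1,
                        phi = 1, scheme = "intercept+x", seed = 1L) {
  if (J < 1L) stop("J must be >= 1")
  clusterSizes <- rep_len(as.integer(clusterSizes), J)
  if (any(clusterSizes < 1L)) stop("cluster sizes must be >= 1")
  if (sigma < 0 || phi <= 0) stop("require sigma >= 0 and phi > 0")
  set.seed(seed)
  n <- sum(clusterSizes)
  clusterId <- factor(rep(sprintf("c%02d", seq_len(J)), clusterSizes))
  Xf <- makeCovariates(n, scheme)
  if (length(beta1) != ncol(Xf)) beta1 <- rep_len(beta1, ncol(Xf))
  theta <- rnorm(J, 0, sigma)
  y <- as.numeric(Xf %*% beta1) + theta[as.integer(clusterId)] +
    rnorm(n, 0, phi)
  data <- regressionData(y, Xf, clusterIndicators(clusterId), clusterId,
                         family = "gaussian")
  truth <- new("SimTruth", beta1 = as.numeric(beta1), theta = theta,
               sigma = sigma, phi = phi, family = "gaussian",
               seed = as.integer(seed),
               descriptor = list(J = J, clusterSizes = clusterSizes,
                                 scheme = scheme))
  list(data = data, truth = truth)
}

#' Simulate a random-intercept generalized linear mixed model
#'
#' @inheritParams simulateLmm
#' @param family "binomial" (logit link) or "poisson" (log link).
#' @param trials binomial trials or Poisson exposure per row (recycled).
#' @return list(data, truth); the response holds success/event counts with
#'   the trials/exposure stored alongside.
#' @export
simulateGlmm <- function(J, clusterSizes, beta1 = c(0, 0.5), sigma = 1,
                         family = c("binomial", "poisson"), trials = 1,
                         scheme = "intercept+x", seed = 1L) {
  family <- match.arg(family)
  clusterSizes <- rep_len(as.integer(clusterSizes), J)
  if (any(clusterSizes < 1L)) stop("cluster sizes must be >= 1")
  if (sigma < 0) stop("require sigma >= 0")
  if (family == "binomial" && any(trials < 1)) stop("binomial trials must be >= 1")
  if (any(trials <= 0)) stop("trials/exposure must be positive")
  set.seed(seed)
  n <- sum(clusterSizes)
  clusterId <- factor(rep(sprintf("c%02d", seq_len(J)), clusterSizes))
  Xf <- makeCovariates(n, scheme)
  if (length(beta1) != ncol(Xf)) beta1 <- rep_len(beta1, ncol(Xf))
  theta <- rnorm(J, 0, sigma)
  eta <- as.numeric(Xf %*% beta1) + theta[as.integer(clusterId)]
  a <- rep_len(trials, n)
  y <- if (family == "binomial") rbinom(n, a, plogis(eta))
       else rpois(n, a * exp(eta))
  data <- regressionData(y, Xf, clusterIndicators(clusterId), clusterId,
                         family = family, trials = a)
  truth <- new("SimTruth", beta1 = as.numeric(beta1), theta = theta,
               sigma = sigma, phi = 1, family = family,
               seed = as.integer(seed),
               descriptor = list(J = J, clusterSizes = clusterSizes,
                                 scheme = scheme, trials = trials))
  list(data = data, truth = truth)
}

#' Rook-adjacency matrix of an r x c lattice
#' @param nrowGrid,ncolGrid lattice dimensions.
#' @export
latticeAdjacency <- function(nrowGrid, ncolGrid) {
  n <- nrowGrid * ncolGrid
  idx <- function(i, j) (j - 1L) * nrowGrid + i
  A <- matrix(0, n, n)
  for (j in seq_len(ncolGrid)) for (i in seq_len(nrowGrid)) {
    if (i < nrowGrid) { A[idx(i, j), idx(i + 1L, j)] <- 1; A[idx(i + 1L, j), idx(i, j)] <- 1 }
    if (j < ncolGrid) { A[idx(i, j), idx(i, j + 1L)] <- 1; A[idx(i, j + 1L), idx(i, j)] <- 1 }
  }
  A
}

#' Simulate a proper-CAR (Gaussian Markov random field) lattice model
#'
#' Spatial effects are drawn from
#' \eqn{\theta \sim N(0, \tau^2 (D - \rho W)^{-1})} on the rook adjacency of
#' an \code{nrowGrid x ncolGrid} lattice (D = diagonal of degrees), with
#' \code{obsPerSite} gaussian observations per site.
#'
#' @param nrowGrid,ncolGrid lattice dimensions (>= 2 each).
#' @param rho spatial dependence, |rho| < 1.
#' @param tau conditional scale (> 0).
#' @param phi residual standard deviation (> 0).
#' @param beta1 intercept (single fixed effect).
#' @param obsPerSite observations per lattice site.
#' @param seed integer seed.
#' @return list(data, truth); each site is one cluster.
#' @export
simulateCar <- function(nrowGrid, ncolGrid, rho = 0.5, tau = 1, phi = 1,
                        beta1 = 0, obsPerSite = 1L, seed = 1L) {
  if (nrowGrid < 2L || ncolGrid < 2L) stop("lattice must be at least 2 x 2")
  if (abs(rho) >= 1) stop("require |rho| < 1")
  if (tau <= 0 || phi <= 0) stop("require tau > 0 and phi > 0")
  set.seed(seed)
  A <- latticeAdjacency(nrowGrid, ncolGrid)
  K <- nrow(A)
  Q <- (diag(rowSums(A)) - rho * A) / tau^2
  R <- chol(Q)
  theta <- backsolve(R, rnorm(K))
  clusterId <- factor(rep(sprintf("s%03d", seq_len(K)), each = obsPerSite))
  n <- K * obsPerSite
  Xf <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  y <- beta1 + theta[as.integer(clusterId)] + rnorm(n, 0, phi)
  data <- regressionData(y, Xf, clusterIndicators(clusterId), clusterId,
                         family = "gaussian")
  truth <- new("SimTruth", beta1 = beta1, theta = as.numeric(theta),
               sigma = tau, phi = phi, family = "gaussian",
               seed = as.integer(seed),
               descriptor = list(nrowGrid = nrowGrid, ncolGrid = ncolGrid,
                                 rho = rho, obsPerSite = obsPerSite))
  list(data = data, truth = truth, adjacency = A)
}

#' Cluster-subsets experimental design
#'
#' For each combination of cluster count J and test-data fraction delta,
#' builds a dataset whose designated test cluster holds \code{ceiling(delta*N)}
#' rows while the remaining J - 1 clusters share the rest, and a fold plan
#' with the test cluster as the single evaluated fold.  Infeasible
#' combinations (too few rows left for J - 1 nonempty clusters) are skipped
#' with a message.
#'
#' @param Jvalues cluster counts (default \code{c(3, 4, 6, 9, 12)}).
#' @param deltaValues test-data fractions (default \code{seq(0.3, 0.7, 0.1)}).
#' @param reps replicates per (J, delta) cell.
#' @param N total rows per dataset.
#' @param sigma,phi,beta1,scheme passed to [simulateLmm()].
#' @param seed master seed; each instance gets a derived seed.
#' @return list of instances, each a list with \code{data}, \code{truth},
#'   \code{plan} (single-fold), \code{J}, \code{delta}, \code{rep}.
#' @export
radonSubsetsDesign <- function(Jvalues = c(3, 4, 6, 9, 12),
                               deltaValues = seq(0.3, 0.7, by = 0.1),
                               reps = 1L, N = 100L, sigma = 1, phi = 1,
                               beta1 = c(1, 0.5), scheme = "intercept+x",
                               seed = 1L) {
  out <- list()
  k <- 0L
  for (J in Jvalues) for (delta in deltaValues) for (r in seq_len(reps)) {
    k <- k + 1L
    nTest <- as.integer(ceiling(delta * N))
    nRest <- N - nTest
    if (nRest < J - 1L) {
      message(sprintf("skipping infeasible (J=%d, delta=%.2f)", J, delta))
      next
    }
    base <- rep(nRest %/% max(J - 1L, 1L), max(J - 1L, 0L))
    extra <- nRest - sum(base)
    if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    sizes <- c(nTest, base)
    sim <- simulateLmm(J, sizes, beta1 = beta1, sigma = sigma, phi = phi,
                       scheme = scheme, seed = mixSeed(seed, k))
    testRows <- which(sim$data@clusterId == "c01")
    plan <- foldPlan(sim$data, kind = "custom", folds = list(testRows),
                     foldNames = "c01")
    out[[length(out) + 1L]] <- list(data = sim$data, truth = sim$truth,
                                    plan = plan, J = J, delta = delta,
                                    rep = r)
  }
  out
}
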