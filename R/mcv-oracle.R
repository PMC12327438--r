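# Internal MCMC oracle.
#
# Provides (a) full-data posterior means of the variance parameters, the
# plug-ins (SigmaHat, phiHat) = (E(Sigma|Y), E(phi|Y)); and (b) ground-truth
# manual cross-validation E(Y_s | Y_-s) by re-running the sampler on each
# training set.  Gaussian models use a blocked Gibbs sampler (the coefficient
# block is drawn exactly from its conditional Gaussian); binomial/poisson
# models use Metropolis-within-Gibbs with adaptive random-walk coefficient
# updates.  Inverse-gamma scale hyperpriors are updated conjugately; half-t
# priors by slice sampling.

mixSeed <- function(seed, id) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(id) * 40503) %%
             2147483629)
}

checkSamplerConfig <- function(data, prior) {
  if (prior@sigmaFamily == "unstructured")
    stop("the internal samplers support iid_by_term and car covariance families; supply an unstructured plug-in directly")
  p1 <- ncol(data@Xfixed)
  if (p1 != nrow(prior@Cinv))
    stop("prior Cinv dimension does not match the fixed-effect design")
  if (p1 > 0 && all(prior@Cinv == 0)) {
    zero <- which(colSums(abs(data@Xfixed)) == 0)
    if (length(zero))
      stop(sprintf("flat fixed-effect prior with all-zero column(s) %s: posterior improper",
                   paste(zero, collapse = ", ")))
  }
  if (prior@sigmaFamily == "car" &&
      nrow(prior@adjacency) != ncol(data@Xrandom))
    stop("CAR adjacency dimension does not match the random-effect design")
}

initScales <- function(prior, data) {
  startVal <- function(p) if (p$dist == "point_mass") p$value else 1
  if (prior@sigmaFamily == "car") {
    rho0 <- if (prior@rhoPrior$dist == "point_mass") prior@rhoPrior$value
            else (prior@rhoPrior$lo + prior@rhoPrior$hi) / 2
    c(tau = startVal(prior@scalePriors[["tau"]]), rho = rho0)
  } else {
    terms <- levels(data@termId)
    vapply(terms, function(tm) startVal(prior@scalePriors[[tm]]), 1.0)
  }
}

currentSigmaInv <- function(prior, data, scales) {
  if (prior@sigmaFamily == "car")
    buildSigmaInv("car", list(tau = scales[["tau"]], rho = scales[["rho"]]),
                  adjacency = prior@adjacency)
  else
    buildSigmaInv("iid_by_term", list(sigma = scales), termId = data@termId)
}

updateScaleIid <- function(sigma, q, p, prior) {
  switch(prior$dist,
    point_mass = prior$value,
    inverse_gamma = sqrt(1 / rgamma(1, prior$a + p / 2, rate = prior$b + q / 2)),
    half_t = sliceSample(sigma, function(s) {
      if (s <= 0) return(-Inf)
      -p * log(s) - q / (2 * s^2) + logPriorScale(s, prior)
    }, w = max(sigma, 0.5), lower = 1e-10, upper = Inf)
  )
}

updatePhiGaussian <- function(phi, rss, n, prior) {
  switch(prior$dist,
    point_mass = prior$value,
    inverse_gamma = sqrt(1 / rgamma(1, prior$a + n / 2, rate = prior$b + rss / 2)),
    half_t = sliceSample(phi, function(s) {
      if (s <= 0) return(-Inf)
      -n * log(s) - rss / (2 * s^2) + logPriorScale(s, prior)
    }, w = max(phi, 0.5), lower = 1e-10, upper = Inf)
  )
}

# CAR: q_D = beta2' D beta2, q_W = beta2' W beta2; quadratic form
# beta2' SigmaInv beta2 = (q_D - rho q_W) / tau^2.
updateCarScales <- function(scales, beta2, prior, carCache) {
  qD <- sum(carCache$deg * beta2^2)
  qW <- as.numeric(crossprod(beta2, carCache$W %*% beta2))
  p2 <- length(beta2)
  rho <- scales[["rho"]]
  q <- qD - rho * qW
  tauPrior <- prior@scalePriors[["tau"]]
  tau <- updateScaleIid(scales[["tau"]], q, p2, tauPrior)
  rp <- prior@rhoPrior
  if (rp$dist != "point_mass") {
    lam <- carCache$lambda
    logfRho <- function(r) {
      v <- 1 - r * lam
      if (any(v <= 0)) return(-Inf)
      0.5 * sum(log(v)) - (qD - r * qW) / (2 * tau^2)
    }
    rho <- sliceSample(rho, logfRho, w = 0.2,
                       lower = rp$lo, upper = rp$hi)
  }
  c(tau = tau, rho = rho)
}

makeCarCache <- function(prior) {
  W <- prior@adjacency
  deg <- rowSums(W)
  Dm <- diag(1 / sqrt(deg))
  lambda <- eigen(Dm %*% W %*% Dm, symmetric = TRUE, only.values = TRUE)$values
  list(W = W, deg = deg, lambda = lambda)
}

summarizeChains <- function(betaChains, scaleChains, settings) {
  betaAll <- do.call(rbind, betaChains)
  scaleAll <- do.call(rbind, scaleChains)
  perChainMcse <- function(chains) {
    m <- vapply(chains, function(ch) apply(ch, 2, batchMcse),
                numeric(ncol(chains[[1]])))
    m <- matrix(m, ncol = length(chains))
    sqrt(rowSums(m^2)) / length(chains)
  }
  new("PosteriorSummary",
      betaMean = colMeans(betaAll),
      betaMcse = perChainMcse(betaChains),
      scaleMean = colMeans(scaleAll),
      scaleMcse = setNames(perChainMcse(scaleChains),
                           colnames(scaleChains[[1]])),
      betaDraws = betaAll, scaleDraws = scaleAll,
      settings = settings)
}

#' Blocked Gibbs sampler for the gaussian hierarchical linear model
#'
#' The coefficient block is drawn exactly from its conditional Gaussian
#' (mean \code{phi^-2 V X'Y}, covariance \code{V}); inverse-gamma scale
#' hyperpriors are updated conjugately and half-t priors by slice sampling.
#'
#' @param data a gaussian [RegressionData-class].
#' @param prior a [PriorSpec-class] (iid_by_term or car covariance family).
#' @param M draws per chain (including burn-in).
#' @param burn burn-in per chain.
#' @param chains number of chains.
#' @param seed master seed; chain streams are derived deterministically.
#' @return A [PosteriorSummary-class] pooling the retained draws.
#' @export
gibbsLmm <- function(data, prior, M = 2000L, burn = 1000L, chains = 4L,
                     seed = 1L) {
  if (data@family != "gaussian")
    stop("gibbsLmm requires the gaussian family; use mcmcGlmm")
  checkSamplerConfig(data, prior)
  X <- designMatrix(data)
  n <- nrow(X); p1 <- ncol(data@Xfixed); p2 <- ncol(data@Xrandom)
  XtX <- crossprod(X); Xty <- crossprod(X, data@y)
  carCache <- if (prior@sigmaFamily == "car") makeCarCache(prior) else NULL
  keep <- M - burn
  if (keep < 1L) stop("M must exceed burn")
  betaChains <- vector("list", chains); scaleChains <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(mixSeed(seed, ch))
    scales <- initScales(prior, data)
    phi <- if (prior@phiPrior$dist == "point_mass") prior@phiPrior$value else 1
    betaKeep <- matrix(NA_real_, keep, p1 + p2)
    scaleKeep <- matrix(NA_real_, keep, length(scales) + 1L,
                        dimnames = list(NULL, c(names(scales), "phi")))
    for (it in seq_len(M)) {
      SigmaInv <- currentSigmaInv(prior, data, scales)
      A <- XtX / phi^2 + blockDiag(prior@Cinv, SigmaInv)
      beta <- rmvnormPrecision(A, Xty / phi^2, context = "Gibbs coefficient block")
      beta2 <- beta[p1 + seq_len(p2)]
      if (prior@sigmaFamily == "car") {
        scales <- updateCarScales(scales, beta2, prior, carCache)
      } else {
        for (tm in levels(data@termId)) {
          cols <- which(data@termId == tm)
          scales[[tm]] <- updateScaleIid(scales[[tm]],
                                         sum(beta2[cols]^2), length(cols),
                                         prior@scalePriors[[tm]])
        }
      }
      rss <- sum((data@y - X %*% beta)^2)
      phi <- updatePhiGaussian(phi, rss, n, prior@phiPrior)
      if (it > burn) {
        betaKeep[it - burn, ] <- beta
        scaleKeep[it - burn, ] <- c(scales, phi)
      }
    }
    betaChains[[ch]] <- betaKeep; scaleChains[[ch]] <- scaleKeep
  }
  summarizeChains(betaChains, scaleChains,
                  list(sampler = "gibbs", chains = chains, draws = M,
                       burn = burn, seed = seed, retained = keep * chains))
}

glmmLogLik <- function(data, eta) {
  if (data@family == "binomial") {
    u <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    sum(dbinom(data@y, data@trials, u, log = TRUE))
  } else {
    sum(dpois(data@y, data@trials * exp(eta), log = TRUE))
  }
}

#' Metropolis-within-Gibbs sampler for binomial/poisson mixed models
#'
#' Coefficients are updated one at a time by adaptive random-walk Metropolis
#' (proposal scales tuned toward 0.2-0.4 acceptance during burn-in, frozen
#' after); scale hyperpriors are updated conjugately or by slice sampling
#' exactly as in [gibbsLmm()].  The dispersion is fixed at 1.
#'
#' @inheritParams gibbsLmm
#' @return A [PosteriorSummary-class]; \code{settings$acceptance} carries the
#'   mean post-burn-in acceptance rate.  A warning is raised if it falls
#'   below 0.01.
#' @export
mcmcGlmm <- function(data, prior, M = 2000L, burn = 1000L, chains = 4L,
                     seed = 1L) {
  if (data@family == "gaussian")
    stop("gaussian family: use gibbsLmm (exact conditional updates)")
  checkSamplerConfig(data, prior)
  X <- designMatrix(data)
  p1 <- ncol(data@Xfixed); p2 <- ncol(data@Xrandom); P <- p1 + p2
  carCache <- if (prior@sigmaFamily == "car") makeCarCache(prior) else NULL
  keep <- M - burn
  if (keep < 1L) stop("M must exceed burn")
  nzRows <- lapply(seq_len(P), function(p) which(X[, p] != 0))
  rowLogLik <- function(rows, eta) {
    if (data@family == "binomial") {
      u <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
      sum(dbinom(data@y[rows], data@trials[rows], u, log = TRUE))
    } else sum(dpois(data@y[rows], data@trials[rows] * exp(eta), log = TRUE))
  }
  betaChains <- vector("list", chains); scaleChains <- vector("list", chains)
  accAll <- numeric(0)
  for (ch in seq_len(chains)) {
    set.seed(mixSeed(seed, 1000L + ch))
    scales <- initScales(prior, data)
    beta <- rep(0, P)
    eta <- as.numeric(X %*% beta)
    step <- rep(0.5, P)
    accCount <- rep(0L, P); accWindow <- rep(0L, P); windowN <- 0L
    betaKeep <- matrix(NA_real_, keep, P)
    scaleKeep <- matrix(NA_real_, keep, length(scales) + 1L,
                        dimnames = list(NULL, c(names(scales), "phi")))
    for (it in seq_len(M)) {
      SigmaInv <- currentSigmaInv(prior, data, scales)
      penalty <- blockDiag(prior@Cinv, SigmaInv)
      for (p in seq_len(P)) {
        rows <- nzRows[[p]]
        if (!length(rows)) next
        prop <- beta[p] + step[p] * rnorm(1)
        etaProp <- eta[rows] + X[rows, p] * (prop - beta[p])
        dLik <- rowLogLik(rows, etaProp) - rowLogLik(rows, eta[rows])
        cross <- sum(penalty[p, ] * beta) - penalty[p, p] * beta[p]
        dPrior <- -0.5 * (penalty[p, p] * (prop^2 - beta[p]^2) +
                          2 * cross * (prop - beta[p]))
        if (log(runif(1)) < dLik + dPrior) {
          eta[rows] <- etaProp; beta[p] <- prop
          accWindow[p] <- accWindow[p] + 1L
          if (it > burn) accCount[p] <- accCount[p] + 1L
        }
      }
      windowN <- windowN + 1L
      if (it <= burn && windowN == 50L) {
        rate <- accWindow / 50
        step <- step * exp(pmin(pmax(rate - 0.3, -0.5), 0.5))
        accWindow[] <- 0L; windowN <- 0L
      }
      beta2 <- beta[p1 + seq_len(p2)]
      if (prior@sigmaFamily == "car") {
        scales <- updateCarScales(scales, beta2, prior, carCache)
      } else {
        for (tm in levels(data@termId)) {
          cols <- which(data@termId == tm)
          scales[[tm]] <- updateScaleIid(scales[[tm]],
                                         sum(beta2[cols]^2), length(cols),
                                         prior@scalePriors[[tm]])
        }
      }
      if (it > burn) {
        betaKeep[it - burn, ] <- beta
        scaleKeep[it - burn, ] <- c(scales, 1)
      }
    }
    betaChains[[ch]] <- betaKeep; scaleChains[[ch]] <- scaleKeep
    accAll <- c(accAll, mean(accCount / keep))
  }
  if (mean(accAll) < 0.01)
    warning(sprintf("Metropolis acceptance rate %.4f after adaptation; summaries unreliable",
                    mean(accAll)))
  summarizeChains(betaChains, scaleChains,
                  list(sampler = "metropolis-within-gibbs", chains = chains,
                       draws = M, burn = burn, seed = seed,
                       retained = keep * chains, acceptance = mean(accAll)))
}

#' Run the appropriate sampler for a dataset's family
#' @inheritParams gibbsLmm
#' @export
posteriorFit <- function(data, prior, M = 2000L, burn = 1000L, chains = 4L,
                         seed = 1L) {
  if (data@family == "gaussian") gibbsLmm(data, prior, M, burn, chains, seed)
  else mcmcGlmm(data, prior, M, burn, chains, seed)
}

#' Plug-in variance parameters from a posterior summary
#'
#' Rebuilds \eqn{\hat\Sigma^{-1}} from the posterior means of the generating
#' parameters (per-term sigmas, or tau/rho for CAR) and takes
#' \eqn{\hat\phi} as the posterior mean of phi.
#'
#' @param summary a [PosteriorSummary-class].
#' @param prior the [PriorSpec-class] used for sampling.
#' @param data the [RegressionData-class] (for term structure).
#' @return A [VariancePlugin-class] with provenance
#'   "full-data posterior mean".
#' @export
posteriorPlugin <- function(summary, prior, data) {
  sm <- summary@scaleMean
  if (!"phi" %in% names(sm)) stop("posterior summary is missing phi")
  if (prior@sigmaFamily == "car") {
    if (!all(c("tau", "rho") %in% names(sm)))
      stop("posterior summary is missing tau/rho for the CAR family")
    SigmaInv <- buildSigmaInv("car",
                              list(tau = sm[["tau"]], rho = sm[["rho"]]),
                              adjacency = prior@adjacency)
    params <- list(tau = sm[["tau"]], rho = sm[["rho"]])
  } else {
    terms <- levels(data@termId)
    miss <- setdiff(terms, names(sm))
    if (length(miss))
      stop(sprintf("posterior summary is missing scale(s): %s",
                   paste(miss, collapse = ", ")))
    SigmaInv <- buildSigmaInv("iid_by_term", list(sigma = sm[terms]),
                              termId = data@termId)
    params <- list(sigma = sm[terms])
  }
  new("VariancePlugin", SigmaInv = SigmaInv, phiHat = sm[["phi"]],
      provenance = "full-data posterior mean", params = params)
}

#' Ground-truth manual cross-validation by per-fold re-sampling
#'
#' For each fold, re-runs the sampler on the training rows only and returns
#' the posterior predictive mean for the held-out rows: for gaussian models
#' the posterior mean of \eqn{X_s \beta}; for binomial/poisson the mean over
#' draws of the inverse link of \eqn{X_s \beta} (Jensen-correct).
#'
#' @param data a [RegressionData-class].
#' @param plan a [FoldPlan-class].
#' @param prior a [PriorSpec-class].
#' @param M,burn,chains sampler settings per fold.
#' @param seed master seed; per-fold streams are derived deterministically.
#' @return A [CVEstimates-class] with method "mcv" and per-row Monte Carlo
#'   standard errors.  Folds whose sampler failed are dropped with a warning
#'   listing them (attribute \code{missingFolds}).
#' @export
mcvPredict <- function(data, plan, prior, M = 2000L, burn = 1000L,
                       chains = 4L, seed = 1L) {
  X <- designMatrix(data)
  fam <- linkFamily(dataLinkName(data))
  rowId <- integer(0); foldId <- integer(0)
  yPred <- numeric(0); mcse <- numeric(0)
  failed <- integer(0)
  for (j in seq_along(plan@folds)) {
    s <- plan@folds[[j]]
    tr <- setdiff(seq_len(nrow(X)), s)
    if (length(tr) == 0L)
      stop(sprintf("fold %d holds out every row: empty training set", j))
    res <- tryCatch({
      fit <- posteriorFit(data[tr], prior, M = M, burn = burn,
                          chains = chains, seed = mixSeed(seed, j))
      etaDraws <- fit@betaDraws %*% t(X[s, , drop = FALSE])  # draws x n_s
      predDraws <- if (data@family == "gaussian") etaDraws
                   else matrix(fam@ginv(etaDraws), nrow(etaDraws))
      list(pred = colMeans(predDraws),
           mcse = apply(predDraws, 2, batchMcse))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("fold %d (%s) sampler failed: %s", j, plan@foldNames[j],
                      conditionalMessage(res)))
      failed <- c(failed, j)
      next
    }
    rowId <- c(rowId, as.integer(s))
    foldId <- c(foldId, rep(j, length(s)))
    yPred <- c(yPred, res$pred)
    mcse <- c(mcse, res$mcse)
  }
  r <- meanScaleResponse(data)
  out <- new("CVEstimates", rowId = rowId, foldId = foldId,
             yTrue = r[rowId], yPred = yPred, method = "mcv", mcse = mcse)
  attr(out, "missingFolds") <- failed
  out
}
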