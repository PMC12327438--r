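#' @import methods
#' @importFrom stats rnorm rgamma rpois rbinom runif sd var median quantile
#'   plogis qlogis dbinom dpois cor setNames rt
NULL

#' Clustered regression data for hierarchical mixed models
#'
#' Container for the data entering a Bayesian hierarchical regression:
#' a response vector, a fixed-effect design, a random-effect design, cluster
#' labels, the response family and per-row known constants (binomial trials or
#' Poisson exposure).  Random-effect columns are tagged with the random term
#' they belong to, and the cluster-pertinent subset (the \eqn{\theta} effects
#' that define leave-one-cluster-out folds) is tagged with the cluster each
#' column belongs to.
#'
#' @slot y numeric response vector of length N.  For the gaussian family a
#'   continuous response; for binomial the success count; for poisson the
#'   event count.
#' @slot Xfixed numeric N x P1 fixed-effect design matrix (may have 0 columns).
#' @slot Xrandom numeric N x P2 random-effect design matrix.
#' @slot clusterId factor of length N giving the cluster of each row.
#' @slot family character, one of \code{"gaussian"}, \code{"binomial"},
#'   \code{"poisson"}.
#' @slot trials numeric length-N known constants: binomial trials or Poisson
#'   exposure; all 1 for gaussian.
#' @slot termId factor of length P2 assigning each random column to a named
#'   random-effect term.
#' @slot thetaCluster character of length P2: for cluster-pertinent columns,
#'   the cluster level the column belongs to; \code{NA} for random columns
#'   that do not define cross-validation folds.
#'
#' @details The validity method enforces the leave-one-cluster-out contract:
#' for every cluster with rows present, the rows belonging to that cluster are
#' exactly the rows with a nonzero entry in that cluster's \eqn{\theta}
#' columns, so holding out the cluster removes all observations informing its
#' random effect.  Columns tagged to a cluster with no rows (as happens in
#' training subsets) must be identically zero.
#'
#' @seealso [regressionData()], [simulateLmm()]
#' @export
setClass("RegressionData",
  representation(
    y = "numeric",
    Xfixed = "matrix",
    Xrandom = "matrix",
    clusterId = "factor",
    family = "character",
    trials = "numeric",
    termId = "factor",
    thetaCluster = "character"
  )
)

setValidity("RegressionData", function(object) {
  n <- length(object@y)
  msgs <- character(0)
  if (n < 1L) msgs <- c(msgs, "response must have length >= 1")
  if (nrow(object@Xfixed) != n) msgs <- c(msgs, "Xfixed row count != length(y)")
  if (nrow(object@Xrandom) != n) msgs <- c(msgs, "Xrandom row count != length(y)")
  if (length(object@clusterId) != n) msgs <- c(msgs, "clusterId length != length(y)")
  if (length(object@trials) != n) msgs <- c(msgs, "trials length != length(y)")
  if (!object@family %in% c("gaussian", "binomial", "poisson"))
    msgs <- c(msgs, sprintf("unknown family '%s'", object@family))
  p2 <- ncol(object@Xrandom)
  if (length(object@termId) != p2) msgs <- c(msgs, "termId length != ncol(Xrandom)")
  if (length(object@thetaCluster) != p2)
    msgs <- c(msgs, "thetaCluster length != ncol(Xrandom)")
  if (any(!is.finite(object@trials)) || any(object@trials <= 0))
    msgs <- c(msgs, "trials/exposure must be positive and finite")
  if (n >= 1L && nlevels(object@clusterId) >= 1L && length(msgs) == 0L) {
    present <- levels(object@clusterId)[tabulate(object@clusterId,
      nbins = nlevels(object@clusterId)) > 0L]
    if (length(present) < 1L) msgs <- c(msgs, "no nonempty cluster")
    theta <- !is.na(object@thetaCluster)
    for (cl in unique(object@thetaCluster[theta])) {
      cols <- which(!is.na(object@thetaCluster) & object@thetaCluster == cl)
      rowsNz <- which(rowSums(abs(object@Xrandom[, cols, drop = FALSE])) > 0)
      rowsCl <- which(as.character(object@clusterId) == cl)
      if (cl %in% present) {
        if (!setequal(rowsNz, rowsCl))
          msgs <- c(msgs, sprintf(
            "cluster '%s': rows with nonzero theta columns differ from the cluster's rows (LCO validity)",
            cl))
      } else if (length(rowsNz) > 0L) {
        msgs <- c(msgs, sprintf(
          "cluster '%s' has no rows but nonzero theta columns", cl))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Prior specification for a hierarchical regression
#'
#' Fixed-effect prior precision, the structural family of the random-effect
#' covariance \eqn{\Sigma}, and hyperpriors on the scale parameters and on the
#' residual scale \eqn{\phi}.
#'
#' @slot Cinv numeric P1 x P1 fixed-effect prior precision.  A matrix of zeros
#'   encodes the flat (infinite-variance) prior.
#' @slot sigmaFamily character: \code{"iid_by_term"} (one scale per random
#'   term, \eqn{\Sigma} block diagonal \eqn{\sigma_k^2 I}),
#'   \code{"unstructured"} (free P2 x P2 covariance), or \code{"car"}
#'   (proper conditional autoregressive precision
#'   \eqn{\tau^{-2}(D - \rho W)} on a supplied adjacency).
#' @slot adjacency numeric symmetric 0/1 adjacency matrix (P2 x P2) used when
#'   \code{sigmaFamily == "car"}; otherwise a 0 x 0 matrix.
#' @slot scalePriors named list of hyperpriors, one per random term (or one
#'   named \code{"tau"} for CAR).  Each element is a list with \code{dist} in
#'   \code{{"inverse_gamma","half_t","point_mass"}} and parameters
#'   (\code{a,b} for inverse-gamma on the variance; \code{nu,scale} for a
#'   half-t on the standard deviation; \code{value} for a point mass on the
#'   standard deviation).
#' @slot phiPrior list: hyperprior on the residual standard deviation
#'   \eqn{\phi}, same format as \code{scalePriors} entries.
#' @slot rhoPrior list: prior on the CAR spatial dependence \eqn{\rho}, either
#'   \code{list(dist="uniform", lo=, hi=)} with \eqn{-1 < lo < hi < 1} or a
#'   point mass.  Ignored unless \code{sigmaFamily == "car"}.
#'
#' @details The prior mean of all coefficients is fixed at zero; nonzero prior
#' means should be absorbed into the response as offsets before constructing
#' the data object.
#'
#' @seealso [priorSpec()]
#' @export
setClass("PriorSpec",
  representation(
    Cinv = "matrix",
    sigmaFamily = "character",
    adjacency = "matrix",
    scalePriors = "list",
    phiPrior = "list",
    rhoPrior = "list"
  )
)

setValidity("PriorSpec", function(object) {
  msgs <- character(0)
  if (nrow(object@Cinv) != ncol(object@Cinv)) msgs <- c(msgs, "Cinv must be square")
  if (nrow(object@Cinv) > 0 &&
      max(abs(object@Cinv - t(object@Cinv))) > 1e-8 * (1 + max(abs(object@Cinv))))
    msgs <- c(msgs, "Cinv must be symmetric")
  if (nrow(object@Cinv) > 0) {
    ev <- eigen(object@Cinv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      msgs <- c(msgs, "Cinv must be positive semi-definite")
  }
  if (!object@sigmaFamily %in% c("iid_by_term", "unstructured", "car"))
    msgs <- c(msgs, sprintf("unknown sigmaFamily '%s'", object@sigmaFamily))
  if (object@sigmaFamily == "car") {
    A <- object@adjacency
    if (nrow(A) == 0) msgs <- c(msgs, "car family requires an adjacency matrix")
    else {
      if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 0)
        msgs <- c(msgs, "adjacency must be square and symmetric")
      if (any(!A %in% c(0, 1)) || any(diag(A) != 0))
        msgs <- c(msgs, "adjacency must be binary with zero diagonal")
      if (any(rowSums(A) == 0))
        msgs <- c(msgs, "adjacency has an isolated node; CAR precision would be singular at rho -> 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Cross-validation fold plan
#'
#' Ordered list of disjoint held-out row-index sets.
#'
#' @slot folds list of integer vectors, the held-out rows of each fold.
#' @slot kind character: \code{"loo"}, \code{"lco"} or \code{"custom"}.
#' @slot foldNames character labels (cluster levels for LCO folds).
#' @export
setClass("FoldPlan",
  representation(folds = "list", kind = "character", foldNames = "character")
)

setValidity("FoldPlan", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("loo", "lco", "custom"))
    msgs <- c(msgs, sprintf("unknown fold kind '%s'", object@kind))
  if (length(object@folds) < 1L) msgs <- c(msgs, "at least one fold required")
  idx <- unlist(object@folds)
  if (length(idx) && anyDuplicated(idx)) msgs <- c(msgs, "folds must be disjoint")
  if (any(vapply(object@folds, length, 1L) == 0L)) msgs <- c(msgs, "empty fold")
  if (object@kind == "loo" && any(vapply(object@folds, length, 1L) != 1L))
    msgs <- c(msgs, "loo folds must be singletons")
  if (length(object@foldNames) != length(object@folds))
    msgs <- c(msgs, "foldNames length != number of folds")
  if (length(msgs)) msgs else TRUE
})

#' Plug-in variance parameters
#'
#' The pair \eqn{(\hat\Sigma, \hat\phi)} plugged into the conditional
#' posterior mean: typically the full-data posterior means of the
#' random-effect covariance and of the residual standard deviation.
#'
#' @slot SigmaInv numeric P2 x P2 positive-definite random-effect prior
#'   precision \eqn{\hat\Sigma^{-1}}.
#' @slot phiHat positive scalar, the residual standard deviation plug-in.
#' @slot provenance character tag (e.g. "full-data posterior mean").
#' @slot params list of the generating parameters (per-term sigmas, or
#'   \code{tau}/\code{rho} for CAR), kept for reporting.
#' @export
setClass("VariancePlugin",
  representation(SigmaInv = "matrix", phiHat = "numeric",
                 provenance = "character", params = "list")
)

setValidity("VariancePlugin", function(object) {
  msgs <- character(0)
  if (!is.finite(object@phiHat) || object@phiHat <= 0)
    msgs <- c(msgs, "phiHat must be a positive scalar")
  S <- object@SigmaInv
  if (nrow(S) != ncol(S)) msgs <- c(msgs, "SigmaInv must be square")
  else if (nrow(S) > 0) {
    if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
      msgs <- c(msgs, "SigmaInv must be symmetric")
    ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA_real_)
    if (anyNA(ev) || min(ev) <= 0)
      msgs <- c(msgs, "SigmaInv must be positive definite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cross-validated predictive estimates
#'
#' Per-row held-out predictions aligned to original row indices.
#'
#' @slot rowId integer original row indices of the predictions.
#' @slot foldId integer fold index of each predicted row.
#' @slot yTrue numeric observed response on the mean scale (y for gaussian,
#'   y / trials for binomial and poisson).
#' @slot yPred numeric predicted mean for each held-out row.
#' @slot method character label ("axe", "mcv", ...).
#' @slot mcse numeric Monte Carlo standard error per prediction (NA for
#'   deterministic methods).
#' @export
setClass("CVEstimates",
  representation(rowId = "integer", foldId = "integer", yTrue = "numeric",
                 yPred = "numeric", method = "character", mcse = "numeric")
)

setValidity("CVEstimates", function(object) {
  msgs <- character(0)
  n <- length(object@rowId)
  if (length(object@foldId) != n || length(object@yTrue) != n ||
      length(object@yPred) != n || length(object@mcse) != n)
    msgs <- c(msgs, "slot lengths differ")
  if (anyDuplicated(object@rowId)) msgs <- c(msgs, "a row is predicted twice")
  if (length(msgs)) msgs else TRUE
})

#' Posterior summary from the internal samplers
#'
#' Posterior means and Monte Carlo standard errors of the coefficients and of
#' the variance-generating scale parameters, with retained draws.
#'
#' @slot betaMean numeric posterior mean of the P coefficients.
#' @slot betaMcse numeric Monte Carlo standard errors of \code{betaMean}.
#' @slot scaleMean named numeric posterior means of the scale parameters
#'   (per-term sigmas or tau/rho) and of \code{phi}.
#' @slot scaleMcse named numeric Monte Carlo standard errors.
#' @slot betaDraws numeric M x P matrix of retained coefficient draws.
#' @slot scaleDraws numeric M x K matrix of retained scale draws.
#' @slot settings list: chains, draws per chain, burn-in, seed, acceptance
#'   diagnostics for Metropolis updates.
#' @export
setClass("PosteriorSummary",
  representation(betaMean = "numeric", betaMcse = "numeric",
                 scaleMean = "numeric", scaleMcse = "numeric",
                 betaDraws = "matrix", scaleDraws = "matrix",
                 settings = "list")
)

setValidity("PosteriorSummary", function(object) {
  msgs <- character(0)
  sc <- object@scaleMean
  if (is.null(names(sc)) || any(names(sc) == ""))
    msgs <- c(msgs, "scaleMean must be a named vector")
  pos <- setdiff(names(sc), "rho")
  if (any(!is.finite(sc[pos])) || any(sc[pos] <= 0))
    msgs <- c(msgs, "scale posterior means must be positive")
  if (any(!is.finite(object@scaleMcse)))
    msgs <- c(msgs, "non-finite Monte Carlo standard error")
  M <- object@settings$retained
  if (!is.null(M) && nrow(object@betaDraws) != M)
    msgs <- c(msgs, "draw count differs from declared retained draws")
  if (length(msgs)) msgs else TRUE
})

#' Log-RMSE-ratio diagnostic report
#'
#' Per-fold log ratios of approximate to ground-truth cross-validated RMSE,
#' their percentage curve and normalized area under it, and the finite-sample
#' decision on whether the approximation can replace full manual
#' cross-validation.
#'
#' @slot lrr numeric per-fold log RMSE ratios (NA where the ground-truth
#'   sum of squares was zero).
#' @slot foldId integer fold indices the ratios belong to.
#' @slot meanLrr numeric mean over finite ratios.
#' @slot sdLrr numeric sample standard deviation over finite ratios (NA when
#'   fewer than two finite values).
#' @slot curve data.frame with columns \code{x} and \code{proportion}: the
#'   proportion of folds with |LRR| <= x on a grid over [0, log 2].
#' @slot aucRaw numeric exact area under the percentage curve on [0, log 2].
#' @slot aucNormalized numeric \code{aucRaw / log(2)}, in [0, 1].
#' @slot delta numeric decision threshold.
#' @slot decision character: \code{"approximation-acceptable"} or
#'   \code{"run-full-MCV"}.
#' @slot nNonFinite integer count of folds excluded from the aggregates.
#' @export
setClass("LRRReport",
  representation(lrr = "numeric", foldId = "integer", meanLrr = "numeric",
                 sdLrr = "numeric", curve = "data.frame", aucRaw = "numeric",
                 aucNormalized = "numeric", delta = "numeric",
                 decision = "character", nNonFinite = "integer")
)

#' Link family for generalized linear mixed models
#'
#' The link function, its inverse and derivative, and the variance function,
#' with the conventions of iteratively weighted least squares: for the logit
#' link \eqn{g'(u) = 1/(u(1-u))} and \eqn{v(u) = u(1-u)}; for the log link
#' \eqn{g'(u) = 1/u} and \eqn{v(u) = u}; for the identity link both are 1.
#'
#' @slot name character family-link name.
#' @slot g function mean -> linear predictor.
#' @slot ginv function linear predictor -> mean.
#' @slot gprime function derivative of the link at the mean.
#' @slot v function variance function of the mean.
#' @export
setClass("LinkFamily",
  representation(name = "character", g = "function", ginv = "function",
                 gprime = "function", v = "function")
)

#' Working-response model state
#'
#' One iteratively-weighted-least-squares state: the working response, the
#' diagonal weights, the fitted means and the coefficients that produced
#' them.
#'
#' @slot Ytilde numeric working response.
#' @slot w numeric positive diagonal weights.
#' @slot u numeric fitted means.
#' @slot beta numeric coefficients at this state.
#' @slot converged logical whether the IWLS loop met its tolerance.
#' @slot iterations integer IWLS iterations used.
#' @export
setClass("WorkingModel",
  representation(Ytilde = "numeric", w = "numeric", u = "numeric",
                 beta = "numeric", converged = "logical",
                 iterations = "integer")
)

setValidity("WorkingModel", function(object) {
  msgs <- character(0)
  if (any(!is.finite(object@Ytilde))) msgs <- c(msgs, "non-finite working response")
  if (any(!is.finite(object@w)) || any(object@w <= 0))
    msgs <- c(msgs, "weights must be positive and finite")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth of a simulated dataset
#'
#' @slot beta1 numeric true fixed effects.
#' @slot theta numeric true cluster random effects (or spatial effects).
#' @slot sigma numeric true random-effect scale(s); for CAR, tau.
#' @slot phi numeric true residual scale.
#' @slot family character response family.
#' @slot seed integer seed the dataset was generated from.
#' @slot descriptor list design descriptor (J, cluster sizes, covariates,
#'   and for CAR the grid and rho).
#' @export
setClass("SimTruth",
  representation(beta1 = "numeric", theta = "numeric", sigma = "numeric",
                 phi = "numeric", family = "character", seed = "integer",
                 descriptor = "list")
)
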