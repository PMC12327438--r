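#' Construct a RegressionData object
#'
#' @param y numeric response (counts for binomial/poisson).
#' @param Xfixed fixed-effect design matrix (N x P1); may be NULL for none.
#' @param Xrandom random-effect design matrix (N x P2).
#' @param clusterId factor or vector of cluster labels, length N.
#' @param family "gaussian", "binomial" or "poisson".
#' @param trials binomial trials / Poisson exposure per row (default 1).
#' @param termId term label of each random column (default one term "theta").
#' @param thetaCluster cluster level each random column pertains to
#'   (NA for columns that do not define CV folds).  The default assumes one
#'   indicator column per cluster, in the order of \code{levels(clusterId)}.
#' @return A validated [RegressionData-class] object.
#' @export
regressionData <- function(y, Xfixed, Xrandom, clusterId,
                           family = "gaussian", trials = rep(1, length(y)),
                           termId = NULL, thetaCluster = NULL) {
  if (is.null(Xfixed)) Xfixed <- matrix(0, length(y), 0)
  Xfixed <- as.matrix(Xfixed)
  Xrandom <- as.matrix(Xrandom)
  clusterId <- as.factor(clusterId)
  p2 <- ncol(Xrandom)
  if (is.null(termId)) termId <- factor(rep("theta", p2))
  termId <- as.factor(termId)
  if (is.null(thetaCluster)) {
    if (p2 != nlevels(clusterId))
      stop("default thetaCluster assumes one random column per cluster; supply thetaCluster")
    thetaCluster <- levels(clusterId)
  }
  new("RegressionData", y = as.numeric(y), Xfixed = Xfixed, Xrandom = Xrandom,
      clusterId = clusterId, family = family, trials = as.numeric(trials),
      termId = termId, thetaCluster = as.character(thetaCluster))
}

#' Construct a PriorSpec
#'
#' @param P1 number of fixed-effect columns (used when \code{Cinv} is NULL).
#' @param Cinv fixed-effect prior precision; NULL or "flat" for the flat prior.
#' @param sigmaFamily "iid_by_term", "unstructured" or "car".
#' @param adjacency CAR adjacency matrix (required for "car").
#' @param scalePriors named list of hyperpriors (see [PriorSpec-class]);
#'   default a half-t(3, 2.5) on every scale.
#' @param phiPrior hyperprior on the residual scale; default half-t(3, 2.5).
#' @param rhoPrior prior on the CAR dependence parameter; default
#'   uniform(0, 0.99).
#' @param terms character term names needing scale priors (default "theta";
#'   "tau" for CAR).
#' @return A validated [PriorSpec-class] object.
#' @export
priorSpec <- function(P1 = 0L, Cinv = NULL, sigmaFamily = "iid_by_term",
                      adjacency = NULL, scalePriors = NULL,
                      phiPrior = list(dist = "half_t", nu = 3, scale = 2.5),
                      rhoPrior = list(dist = "uniform", lo = 0, hi = 0.99),
                      terms = if (sigmaFamily == "car") "tau" else "theta") {
  if (is.null(Cinv) || identical(Cinv, "flat"))
    Cinv <- matrix(0, P1, P1)
  if (is.null(adjacency)) adjacency <- matrix(0, 0, 0)
  if (is.null(scalePriors))
    scalePriors <- setNames(
      rep(list(list(dist = "half_t", nu = 3, scale = 2.5)), length(terms)),
      terms)
  new("PriorSpec", Cinv = as.matrix(Cinv), sigmaFamily = sigmaFamily,
      adjacency = as.matrix(adjacency), scalePriors = scalePriors,
      phiPrior = phiPrior, rhoPrior = rhoPrior)
}

#' Build a cross-validation fold plan
#'
#' @param data a [RegressionData-class] object.
#' @param kind "lco" (one fold per cluster), "loo" (one fold per row) or
#'   "custom".
#' @param folds list of integer row-index vectors when \code{kind="custom"}.
#' @param foldNames optional labels for custom folds.
#' @return A [FoldPlan-class].
#' @export
foldPlan <- function(data, kind = c("lco", "loo", "custom"), folds = NULL,
                     foldNames = NULL) {
  kind <- match.arg(kind)
  if (kind == "lco") {
    lv <- levels(data@clusterId)
    lv <- lv[tabulate(data@clusterId, nbins = length(lv)) > 0L]
    folds <- lapply(lv, function(cl) which(data@clusterId == cl))
    foldNames <- lv
  } else if (kind == "loo") {
    folds <- as.list(seq_along(data@y))
    foldNames <- as.character(seq_along(data@y))
  } else {
    if (is.null(folds)) stop("custom plan requires folds")
    folds <- lapply(folds, as.integer)
    if (is.null(foldNames)) foldNames <- as.character(seq_along(folds))
  }
  new("FoldPlan", folds = folds, kind = kind, foldNames = as.character(foldNames))
}

#' @describeIn foldPlan Number of folds.
#' @param plan a FoldPlan.
#' @export
nFolds <- function(plan) length(plan@folds)

#' @describeIn foldPlan Held-out size of each fold.
#' @export
foldSizes <- function(plan) vapply(plan@folds, length, 1L)

#' Construct a VariancePlugin from explicit values
#'
#' @param SigmaInv positive-definite random-effect precision, or NULL to build
#'   one from \code{sigma}/\code{tau},\code{rho}.
#' @param phiHat residual standard deviation plug-in.
#' @param data a [RegressionData-class] (needed when building from sigma).
#' @param prior a [PriorSpec-class] (needed for CAR).
#' @param sigma named per-term standard deviations (iid family).
#' @param tau,rho CAR parameters.
#' @param provenance character tag.
#' @return A [VariancePlugin-class].
#' @export
variancePlugin <- function(SigmaInv = NULL, phiHat, data = NULL, prior = NULL,
                           sigma = NULL, tau = NULL, rho = NULL,
                           provenance = "fixed/known") {
  params <- list()
  if (is.null(SigmaInv)) {
    if (!is.null(sigma)) {
      SigmaInv <- buildSigmaInv("iid_by_term", list(sigma = sigma),
                                termId = data@termId)
      params$sigma <- sigma
    } else if (!is.null(tau)) {
      SigmaInv <- buildSigmaInv("car", list(tau = tau, rho = rho),
                                adjacency = prior@adjacency)
      params$tau <- tau; params$rho <- rho
    } else stop("supply SigmaInv, sigma, or tau/rho")
  }
  new("VariancePlugin", SigmaInv = as.matrix(SigmaInv), phiHat = phiHat,
      provenance = provenance, params = params)
}

# ---- accessors ----

#' @rdname RegressionData-class
#' @param object,x a RegressionData.
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))
#' @rdname RegressionData-class
#' @export
setMethod("nObs", "RegressionData", function(x) length(x@y))

#' @rdname RegressionData-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname RegressionData-class
#' @export
setMethod("nClusters", "RegressionData", function(x)
  sum(tabulate(x@clusterId, nbins = nlevels(x@clusterId)) > 0L))

#' Full design matrix (fixed columns then random columns)
#' @param x a RegressionData.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname designMatrix
#' @export
setMethod("designMatrix", "RegressionData", function(x)
  cbind(x@Xfixed, x@Xrandom))

#' Response on the mean scale (y / trials for binomial and poisson)
#' @param x a RegressionData.
#' @export
setGeneric("meanScaleResponse", function(x) standardGeneric("meanScaleResponse"))
#' @rdname meanScaleResponse
#' @export
setMethod("meanScaleResponse", "RegressionData", function(x)
  if (x@family == "gaussian") x@y else x@y / x@trials)

#' Row subset of a RegressionData
#'
#' Keeps all design columns (so a training subset retains the held-out
#' cluster's indicator columns, which the penalty shrinks to zero) and drops
#' cluster levels with no remaining rows.
#' @param x a RegressionData; \code{i} integer row indices.
#' @param i,j,...,drop standard subset arguments (only \code{i} is used).
#' @export
setMethod("[", "RegressionData", function(x, i, j, ..., drop = FALSE) {
  new("RegressionData", y = x@y[i],
      Xfixed = x@Xfixed[i, , drop = FALSE],
      Xrandom = x@Xrandom[i, , drop = FALSE],
      clusterId = droplevels(x@clusterId[i]),
      family = x@family, trials = x@trials[i],
      termId = x@termId, thetaCluster = x@thetaCluster)
})

#' @rdname CVEstimates-class
#' @param x a CVEstimates.
#' @param row.names,optional,... passed through.
#' @export
setMethod("as.data.frame", "CVEstimates",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(row_id = x@rowId, fold_id = x@foldId, y_true = x@yTrue,
               y_pred = x@yPred, method = x@method[1L], mcse = x@mcse)
  })

# ---- show methods ----

setMethod("show", "RegressionData", function(object) {
  cat(sprintf("RegressionData: %d rows, %d clusters, family %s\n",
              nObs(object), nClusters(object), object@family))
  cat(sprintf("  fixed columns: %d, random columns: %d (%d terms)\n",
              ncol(object@Xfixed), ncol(object@Xrandom),
              nlevels(object@termId)))
})

setMethod("show", "PriorSpec", function(object) {
  flat <- nrow(object@Cinv) == 0 || all(object@Cinv == 0)
  cat(sprintf("PriorSpec: %s fixed-effect prior, Sigma family '%s'\n",
              if (flat) "flat" else "finite", object@sigmaFamily))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan (%s): %d folds, sizes %s\n", object@kind,
              nFolds(object),
              paste(range(foldSizes(object)), collapse = "-")))
})

setMethod("show", "VariancePlugin", function(object) {
  cat(sprintf("VariancePlugin (%s): phiHat = %.4g, P2 = %d\n",
              object@provenance, object@phiHat, nrow(object@SigmaInv)))
})

setMethod("show", "CVEstimates", function(object) {
  cat(sprintf("CVEstimates [%s]: %d predictions over %d folds\n",
              object@method[1L], length(object@rowId),
              length(unique(object@foldId))))
})

setMethod("show", "PosteriorSummary", function(object) {
  s <- object@settings
  cat(sprintf("PosteriorSummary: %d retained draws (%s chains x %s, burn %s)\n",
              nrow(object@betaDraws), s$chains, s$draws, s$burn))
  sm <- object@scaleMean
  cat("  scale means:", paste(sprintf("%s=%.4g", names(sm), sm), collapse = ", "),
      "\n")
})

setMethod("show", "LRRReport", function(object) {
  cat(sprintf("LRRReport: %d folds (%d non-finite), mean %.4g, sd %s\n",
              length(object@lrr), object@nNonFinite, object@meanLrr,
              if (is.na(object@sdLrr)) "NA" else sprintf("%.4g", object@sdLrr)))
  cat(sprintf("  AUC-LRRP %.4g (normalized %.4g); decision: %s (delta = %g)\n",
              object@aucRaw, object@aucNormalized, object@decision,
              object@delta))
})
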