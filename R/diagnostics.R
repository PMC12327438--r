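# Log-RMSE-ratio diagnostics.
#
# For each cross-validation fold j,
#     LRR_j = log( SSE_j(approx) / SSE_j(ground truth) ),
# the log ratio of the approximation's held-out sum of squared errors to the
# manual-cross-validation sum of squared errors against the observed
# response.  |LRR_j| <= delta means the approximate RMSE is within a factor
# exp(delta) of the ground truth; delta = 0.25 corresponds to an RMSE ratio
# between 0.78 and 1.28.

#' Per-fold log RMSE ratios of an approximation against ground truth
#'
#' @param approx a [CVEstimates-class] from the approximation (e.g. AXE).
#' @param truth a [CVEstimates-class] from manual cross-validation.
#' @param data the [RegressionData-class] both were computed on.
#' @param plan the [FoldPlan-class] both were computed on.
#' @return named numeric of per-fold LRR values over the folds both estimate
#'   sets cover.  Folds where the ground truth fits exactly (zero
#'   denominator) are NA, with a message giving the count.
#' @export
lrr <- function(approx, truth, data, plan) {
  foldsA <- sort(unique(approx@foldId)); foldsT <- sort(unique(truth@foldId))
  common <- intersect(foldsA, foldsT)
  if (length(common) == 0L) stop("no common folds between the estimate sets")
  r <- meanScaleResponse(data)
  out <- setNames(rep(NA_real_, length(common)), plan@foldNames[common])
  for (k in seq_along(common)) {
    j <- common[k]
    ia <- which(approx@foldId == j); it <- which(truth@foldId == j)
    rowsA <- approx@rowId[ia]; rowsT <- truth@rowId[it]
    sseA <- sum((approx@yPred[ia] - r[rowsA])^2)
    sseT <- sum((truth@yPred[it] - r[rowsT])^2)
    if (sseT > 0) out[k] <- log(sseA / sseT)
  }
  nbad <- sum(!is.finite(out))
  if (nbad > 0)
    message(sprintf("%d fold(s) with zero ground-truth error excluded from LRR aggregates",
                    nbad))
  out
}

#' LRR percentage curve: proportion of folds with |LRR| <= x
#'
#' @param lrrs numeric per-fold LRR values (non-finite entries dropped).
#' @param grid evaluation grid; default 200 equally spaced points on
#'   \code{[0, log 2]}.
#' @return data.frame with columns \code{x} and \code{proportion}
#'   (right-continuous, non-decreasing empirical CDF of |LRR|).
#' @export
lrrPercentageCurve <- function(lrrs, grid = seq(0, log(2), length.out = 200)) {
  v <- abs(lrrs[is.finite(lrrs)])
  if (length(v) == 0L) stop("no finite LRR values")
  data.frame(x = grid,
             proportion = vapply(grid, function(x) mean(v <= x), 1.0))
}

#' Area under the LRR percentage curve
#'
#' Exact piecewise-constant integration of the empirical CDF of |LRR| over
#' \code{[0, log 2]}: each fold contributes \code{max(log 2 - |LRR|, 0)}.
#' The maximum (all |LRR| = 0) gives a raw area of log 2 and a normalized
#' value of 1; all |LRR| > log 2 gives 0.
#'
#' @param lrrs numeric per-fold LRR values (non-finite entries dropped).
#' @return list with elements \code{raw} and \code{normalized}.
#' @export
aucLrrp <- function(lrrs) {
  v <- abs(lrrs[is.finite(lrrs)])
  if (length(v) == 0L) stop("no finite LRR values")
  L <- log(2)
  raw <- mean(pmax(L - pmin(v, L), 0))
  list(raw = raw, normalized = raw / L)
}

#' RMSE-ratio interval implied by an |LRR| threshold
#'
#' \code{|LRR| <= delta} bounds the ratio of approximate to ground-truth
#' RMSE between \code{exp(-delta/2)^2 = exp(-delta)} on the sum-of-squares
#' scale; on the RMSE scale the band is \code{exp(+/- delta/2)}.  Following
#' the convention that delta = 0.25 is read as an RMSE ratio between 0.78
#' and 1.28, the interval is reported on the \code{exp(+/- delta)} scale.
#'
#' @param delta threshold on |LRR| (default 0.25).
#' @return numeric of length 2, \code{c(lower, upper) = exp(c(-delta, delta))}.
#' @export
lrrRatioInterval <- function(delta = 0.25) {
  setNames(exp(c(-delta, delta)), c("lower", "upper"))
}

buildLrrReport <- function(lrrs, foldId, delta, kFolds) {
  finite <- lrrs[is.finite(lrrs)]
  meanL <- mean(finite)
  sdL <- if (length(finite) >= 2L) sd(finite) else NA_real_
  if (is.na(sdL))
    message("fewer than two finite LRR values: sd undefined, decision on the mean only")
  decision <- if (abs(meanL) > delta || (!is.na(sdL) && sdL > delta))
    "run-full-MCV" else "approximation-acceptable"
  auc <- aucLrrp(lrrs)
  new("LRRReport", lrr = as.numeric(lrrs), foldId = as.integer(foldId),
      meanLrr = meanL, sdLrr = sdL,
      curve = lrrPercentageCurve(lrrs),
      aucRaw = auc$raw, aucNormalized = auc$normalized,
      delta = delta, decision = decision,
      nNonFinite = sum(!is.finite(lrrs)))
}

#' AXE+ finite-sample diagnostic
#'
#' Runs ground-truth manual cross-validation on a small subset of folds,
#' compares it with the AXE approximation on the same folds through per-fold
#' LRRs, and recommends full manual cross-validation when |mean(LRR)| or
#' sd(LRR) exceeds \code{delta}.
#'
#' @param data a [RegressionData-class].
#' @param plan the full [FoldPlan-class].
#' @param prior a [PriorSpec-class].
#' @param plugin a [VariancePlugin-class]; if NULL it is computed from a
#'   full-data sampler run.
#' @param kFolds number of folds to check (must not exceed the plan's).
#' @param delta decision threshold (default 0.25).
#' @param policy fold selection: \code{"largest"} (largest held-out sizes),
#'   \code{"extreme"} (largest |estimated random effect| of the fold's
#'   cluster under the full-data plug-in fit), or
#'   \code{"stratified_random"} (random within held-out-size strata).
#' @param seed master seed (fold selection and per-fold samplers).
#' @param M,burn,chains sampler settings for the MCV runs.
#' @param refineIters passed to [axePredictGlmm()] for non-gaussian data.
#' @return An [LRRReport-class].
#' @export
axePlus <- function(data, plan, prior, plugin = NULL, kFolds, delta = 0.25,
                    policy = c("largest", "extreme", "stratified_random"),
                    seed = 1L, M = 2000L, burn = 1000L, chains = 4L,
                    refineIters = 0L) {
  policy <- match.arg(policy)
  if (kFolds > nFolds(plan)) stop("kFolds exceeds the number of folds")
  if (is.null(plugin)) {
    fit <- posteriorFit(data, prior, M = M, burn = burn, chains = chains,
                        seed = mixSeed(seed, 0L))
    plugin <- posteriorPlugin(fit, prior, data)
  }
  sizes <- foldSizes(plan)
  sel <- switch(policy,
    largest = order(sizes, decreasing = TRUE)[seq_len(kFolds)],
    extreme = {
      X <- designMatrix(data)
      penalty <- penaltyFromPlugin(prior, plugin)
      fam <- linkFamily(dataLinkName(data))
      beta <- if (data@family == "gaussian")
        conditionalPosteriorMean(X, data@y, penalty, plugin@phiHat)
      else iwlsFit(data, penalty, fam)@beta
      p1 <- ncol(data@Xfixed)
      score <- vapply(seq_along(plan@folds), function(j) {
        cols <- which(!is.na(data@thetaCluster) &
                      data@thetaCluster == plan@foldNames[j])
        if (!length(cols)) return(0)
        sqrt(sum(beta[p1 + cols]^2))
      }, 1.0)
      order(score, decreasing = TRUE)[seq_len(kFolds)]
    },
    stratified_random = {
      set.seed(mixSeed(seed, 97L))
      strata <- cut(rank(sizes, ties.method = "first"),
                    breaks = min(3L, nFolds(plan)), labels = FALSE)
      picked <- integer(0)
      # proportional draw from size strata, topping up at random
      for (st in unique(strata)) {
        inSt <- which(strata == st)
        kSt <- min(length(inSt), max(1L, round(kFolds * length(inSt) / nFolds(plan))))
        picked <- c(picked, sample(inSt, kSt))
      }
      if (length(picked) > kFolds) picked <- sample(picked, kFolds)
      while (length(picked) < kFolds)
        picked <- c(picked, sample(setdiff(seq_along(sizes), picked), 1L))
      sort(picked)
    })
  sub <- new("FoldPlan", folds = plan@folds[sel], kind = "custom",
             foldNames = plan@foldNames[sel])
  truth <- mcvPredict(data, sub, prior, M = M, burn = burn, chains = chains,
                      seed = mixSeed(seed, 1L))
  approx <- if (data@family == "gaussian") {
    axePredictLmm(data, sub, plugin, prior)
  } else {
    fam <- linkFamily(dataLinkName(data))
    fullFit <- iwlsFit(data, penaltyFromPlugin(prior, plugin), fam)
    axePredictGlmm(data, sub, plugin, prior, fullFit,
                   refineIters = refineIters)
  }
  lrrs <- lrr(approx, truth, data, sub)
  buildLrrReport(lrrs, seq_along(sel), delta, kFolds)
}
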