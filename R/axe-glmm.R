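# AXE for generalized linear mixed models.
#
# IWLS turns the GLMM locally into a weighted linear mixed model for the
# working response: Ytilde | beta ~ N(X beta, W^-1).  At the convergence of
# the FULL-data fit, the working response and weights are frozen; each
# cross-validation fold then reduces to one penalized weighted least-squares
# solve on the training rows
#     betaHat = (X'WX + blockdiag(C^-1, SigmaInvHat))^-1 X'W Ytilde
# restricted to the training rows, and the held-out prediction is the inverse
# link of X_s betaHat.  Optional refinement iterations re-run IWLS on the
# training rows starting from that solution.

#' One IWLS step: working response, weights and fitted means
#'
#' @param data a [RegressionData-class].
#' @param beta current coefficient vector (length P1+P2).
#' @param fam a [LinkFamily-class] matching \code{data@family}.
#' @param phi2 dispersion (variance scale); 1 for binomial/poisson.
#' @return A [WorkingModel-class] (not yet converged; one step only).
#' @export
workingResponse <- function(data, beta, fam, phi2 = 1) {
  X <- designMatrix(data)
  eta <- as.numeric(X %*% beta)
  uRaw <- if (fam@name == "binomial-logit") plogis(eta)
          else if (fam@name == "poisson-log") exp(eta) else eta
  u <- fam@ginv(eta)
  if (any(u != uRaw))
    warning("fitted means on the boundary were clipped before weighting")
  r <- meanScaleResponse(data)
  gp <- fam@gprime(u)
  Ytilde <- eta + (r - u) * gp
  w <- data@trials / (phi2 * fam@v(u) * gp^2)
  new("WorkingModel", Ytilde = Ytilde, w = w, u = u, beta = as.numeric(beta),
      converged = FALSE, iterations = 1L)
}

#' Penalized IWLS fit
#'
#' Alternates [workingResponse()] and a penalized weighted least-squares
#' solve until the maximum absolute coefficient change is below \code{tol}.
#'
#' @inheritParams workingResponse
#' @param penalty P x P prior precision from [buildPenalty()].
#' @param maxIter,tol convergence controls.
#' @param betaInit starting coefficients (default zero).
#' @return A [WorkingModel-class] at convergence (\code{converged} honest).
#' @export
iwlsFit <- function(data, penalty, fam, phi2 = 1, maxIter = 100L,
                    tol = 1e-8, betaInit = NULL) {
  X <- designMatrix(data)
  beta <- if (is.null(betaInit)) rep(0, ncol(X)) else as.numeric(betaInit)
  wm <- NULL
  for (it in seq_len(maxIter)) {
    wm <- workingResponse(data, beta, fam, phi2)
    betaNew <- pwlsSolve(X, wm@Ytilde, wm@w, penalty, context = "IWLS solve")
    if (any(!is.finite(betaNew)))
      stop(sprintf("IWLS diverged at iteration %d; last finite coefficients: %s",
                   it, paste(signif(beta, 4), collapse = ", ")))
    delta <- max(abs(betaNew - beta))
    beta <- betaNew
    if (delta < tol) {
      wm <- workingResponse(data, beta, fam, phi2)
      wm@beta <- beta; wm@converged <- TRUE; wm@iterations <- it
      return(wm)
    }
  }
  wm <- workingResponse(data, beta, fam, phi2)
  wm@beta <- beta; wm@converged <- FALSE; wm@iterations <- maxIter
  wm
}

#' Approximate cross-validated means for a generalized linear mixed model
#'
#' Solves, for each fold, the penalized weighted least-squares system on the
#' training rows with working response and weights FROZEN at the full-data
#' IWLS convergence, and back-transforms through the inverse link.  With
#' \code{refineIters > 0}, that many additional IWLS updates are run on the
#' training rows (updating weights from the training data) starting from the
#' frozen-weight solution.
#'
#' @param data a [RegressionData-class].
#' @param plan a [FoldPlan-class].
#' @param plugin a [VariancePlugin-class] from the full data.
#' @param prior a [PriorSpec-class].
#' @param fullFit the [WorkingModel-class] returned by [iwlsFit()] on the FULL
#'   data (with the plug-in penalty).
#' @param refineIters number of extra IWLS iterations per fold (default 0; in
#'   practice the frozen-weight solution is already accurate).
#' @param tol convergence tolerance for the refinement iterations.
#' @return A [CVEstimates-class] with predictions on the mean scale.
#' @export
axePredictGlmm <- function(data, plan, plugin, prior, fullFit,
                           refineIters = 0L, tol = 1e-8) {
  fam <- linkFamily(dataLinkName(data))
  X <- designMatrix(data)
  if (length(fullFit@Ytilde) != nrow(X))
    stop("full-data fit does not match the data (family or size mismatch)")
  penalty <- penaltyFromPlugin(prior, plugin)
  phi2 <- if (data@family == "gaussian") plugin@phiHat^2 else 1
  rowId <- integer(0); foldId <- integer(0); yPred <- numeric(0)
  for (j in seq_along(plan@folds)) {
    s <- plan@folds[[j]]
    tr <- setdiff(seq_len(nrow(X)), s)
    if (length(tr) == 0L) stop(sprintf("fold %d leaves an empty training set", j))
    beta <- tryCatch(
      pwlsSolve(X[tr, , drop = FALSE], fullFit@Ytilde[tr], fullFit@w[tr],
                penalty),
      error = function(e) stop(sprintf("fold %d (%s): %s", j,
                                       plan@foldNames[j], conditionMessage(e))))
    if (refineIters > 0L) {
      trData <- data[tr]
      for (k in seq_len(refineIters)) {
        wm <- workingResponse(trData, beta, fam, phi2)
        betaNew <- pwlsSolve(X[tr, , drop = FALSE], wm@Ytilde, wm@w, penalty)
        if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
        beta <- betaNew
      }
    }
    pred <- fam@ginv(as.numeric(X[s, , drop = FALSE] %*% beta))
    yPred <- c(yPred, pred)
    rowId <- c(rowId, as.integer(s))
    foldId <- c(foldId, rep(j, length(s)))
  }
  r <- meanScaleResponse(data)
  new("CVEstimates", rowId = rowId, foldId = foldId, yTrue = r[rowId],
      yPred = yPred, method = "axe",
      mcse = rep(NA_real_, length(rowId)))
}
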