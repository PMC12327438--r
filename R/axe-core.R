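# Closed-form cross-validated mean estimates for linear mixed models.
#
# The model is Y | beta, phi ~ N(X beta, phi^2 I) with beta = (beta1', beta2')',
# beta1 ~ N(0, C) fixed effects and beta2 ~ N(0, Sigma) random effects.
# Conditioned on (Sigma, phi), the posterior mean of beta is the penalized
# least-squares solution
#     E(beta | Sigma, phi, Y) = phi^-2 V X'Y,
#     V = (phi^-2 X'X + blockdiag(C^-1, Sigma^-1))^-1 .
# Plugging the full-data posterior means (SigmaHat, phiHat) into this formula
# with the training rows of each cross-validation fold gives the approximate
# cross-validated mean for the held-out rows: Xs %*% betaHat.

#' Build the random-effect prior precision SigmaInv
#'
#' @param sigmaFamily "iid_by_term", "unstructured" or "car".
#' @param params for iid_by_term: \code{list(sigma=)} with one (named) value
#'   per term; for unstructured: \code{list(Sigma=)}; for car:
#'   \code{list(tau=, rho=)}.
#' @param termId factor assigning random columns to terms (iid family).
#' @param adjacency CAR adjacency matrix.
#' @return P2 x P2 positive-definite precision matrix.
#' @export
buildSigmaInv <- function(sigmaFamily, params, termId = NULL, adjacency = NULL) {
  switch(sigmaFamily,
    iid_by_term = {
      sigma <- params$sigma
      if (is.null(names(sigma)) && length(sigma) == 1L && !is.null(termId))
        sigma <- setNames(rep(sigma, nlevels(termId)), levels(termId))
      bad <- !is.finite(sigma) | sigma <= 0
      if (any(bad))
        stop(sprintf("invalid scale for term(s) %s: sigma must be positive",
                     paste(names(sigma)[bad], collapse = ", ")))
      prec <- sigma[as.character(termId)]^-2
      diag(as.numeric(prec), length(prec))
    },
    unstructured = {
      S <- as.matrix(params$Sigma)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0) stop("invalid Sigma: not positive definite")
      chol2inv(chol(S))
    },
    car = {
      tau <- params$tau; rho <- params$rho
      if (!is.finite(tau) || tau <= 0) stop("invalid scale tau: must be positive")
      if (!is.finite(rho) || abs(rho) >= 1)
        stop("invalid CAR rho: require |rho| < 1")
      W <- as.matrix(adjacency)
      D <- diag(rowSums(W))
      tau^-2 * (D - rho * W)
    },
    stop(sprintf("unknown sigmaFamily '%s'", sigmaFamily))
  )
}

#' Block-diagonal prior precision penalty blockdiag(Cinv, SigmaInv)
#'
#' The P x P penalty added to the scaled cross-product in the conditional
#' posterior mean: the fixed-effect prior precision (zero under a flat prior)
#' and the random-effect precision built from the supplied scale parameters.
#'
#' @param prior a [PriorSpec-class].
#' @param sigmaParams scale parameters in the format [buildSigmaInv()] expects.
#' @param termId factor assigning random columns to terms.
#' @return symmetric positive-semidefinite (P1+P2) x (P1+P2) matrix, strictly
#'   positive definite on the random-effect block.
#' @export
buildPenalty <- function(prior, sigmaParams, termId = NULL) {
  SigmaInv <- buildSigmaInv(prior@sigmaFamily, sigmaParams,
                            termId = termId, adjacency = prior@adjacency)
  blockDiag(prior@Cinv, SigmaInv)
}

penaltyFromPlugin <- function(prior, plugin) {
  blockDiag(prior@Cinv, plugin@SigmaInv)
}

#' Conditional posterior mean of the coefficients given variance parameters
#'
#' Computes \code{phi^-2 V X'y} with \code{V = (phi^-2 X'X + penalty)^-1}
#' through a Cholesky factorization of the precision (never an explicit
#' inverse).
#'
#' @param X design matrix (rows of one fold's training data, or the full data).
#' @param y response aligned with X.
#' @param penalty P x P prior precision from [buildPenalty()].
#' @param phi residual standard deviation.
#' @return coefficient vector of length P.
#' @export
conditionalPosteriorMean <- function(X, y, penalty, phi) {
  A <- crossprod(X) / phi^2 + penalty
  as.numeric(cholSolve(A, crossprod(X, y) / phi^2,
                       context = "conditional posterior mean"))
}

# Penalized weighted least squares: solve (X'WX + penalty) beta = X'W ytilde.
pwlsSolve <- function(X, ytilde, w, penalty, context = "weighted solve") {
  Xw <- X * w
  A <- crossprod(Xw, X) + penalty
  as.numeric(cholSolve(A, crossprod(Xw, ytilde), context = context))
}

#' Approximate cross-validated means for a linear mixed model
#'
#' For each fold, fits the conditional posterior mean on the training rows
#' with the plug-in variance parameters and predicts the held-out rows.
#' Deterministic given its inputs.
#'
#' @param data a gaussian-family [RegressionData-class].
#' @param plan a [FoldPlan-class] valid for \code{data}.
#' @param plugin a [VariancePlugin-class] (typically full-data posterior means).
#' @param prior a [PriorSpec-class] supplying the fixed-effect prior precision.
#' @return A [CVEstimates-class] with method label "axe".
#' @export
axePredictLmm <- function(data, plan, plugin, prior) {
  if (data@family != "gaussian")
    stop("axePredictLmm requires the gaussian family; use axePredictGlmm")
  X <- designMatrix(data)
  penalty <- penaltyFromPlugin(prior, plugin)
  phi <- plugin@phiHat
  # fixed-effect columns with no prior precision must stay identifiable on
  # every training set; the jitter fallback must not silently rescue them
  flatCols <- which(colSums(abs(prior@Cinv)) == 0)
  rowId <- integer(0); foldId <- integer(0); yPred <- numeric(0)
  for (j in seq_along(plan@folds)) {
    s <- plan@folds[[j]]
    tr <- setdiff(seq_len(nrow(X)), s)
    if (length(tr) == 0L) stop(sprintf("fold %d leaves an empty training set", j))
    if (length(flatCols)) {
      empty <- flatCols[colSums(abs(data@Xfixed[tr, flatCols, drop = FALSE])) == 0]
      if (length(empty))
        stop(sprintf(
          "fold %d (%s): removing it empties fixed-effect column(s) %s under a flat prior (rank deficient)",
          j, plan@foldNames[j], paste(empty, collapse = ", ")))
    }
    beta <- tryCatch(
      conditionalPosteriorMean(X[tr, , drop = FALSE], data@y[tr], penalty, phi),
      error = function(e) stop(sprintf("fold %d (%s): %s", j,
                                       plan@foldNames[j], conditionalMessage(e))))
    yPred <- c(yPred, as.numeric(X[s, , drop = FALSE] %*% beta))
    rowId <- c(rowId, as.integer(s))
    foldId <- c(foldId, rep(j, length(s)))
  }
  new("CVEstimates", rowId = rowId, foldId = foldId,
      yTrue = data@y[rowId], yPred = yPred, method = "axe",
      mcse = rep(NA_real_, length(rowId)))
}
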