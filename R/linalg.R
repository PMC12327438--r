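# Symmetric positive-definite solves used throughout: Cholesky with a small
# jitter fallback (at most 3 escalations of +1e-10 * mean diagonal, each x100)
# before declaring the system singular.

cholFactor <- function(A, context = "system") {
  jitter <- 0
  base <- 1e-10 * mean(diag(A))
  if (!is.finite(base) || base <= 0) base <- 1e-10
  for (k in 0:3) {
    R <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jitter <- if (jitter == 0) base else jitter * 100
  }
  stop(sprintf(
    "rank-deficient %s: the penalized normal equations are singular even after jitter; check for collinear fixed-effect columns under a flat prior",
    context))
}

# Solve A x = b for symmetric PD A; b may be a matrix.
cholSolve <- function(A, b, context = "system") {
  R <- cholFactor(A, context)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

# Draw N(mean, A^{-1}) given the precision A and rhs so that mean = A^{-1} rhs.
rmvnormPrecision <- function(A, rhs, context = "system") {
  R <- cholFactor(A, context)
  m <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  as.numeric(m + backsolve(R, rnorm(nrow(A))))
}

blockDiag <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  if (nrow(A)) out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  if (nrow(B)) out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

# Batch-means Monte Carlo standard error of a vector of (possibly
# autocorrelated) draws.
batchMcse <- function(x) {
  n <- length(x)
  if (n < 10L) return(stats::sd(x) / sqrt(max(n, 1)))
  nb <- max(5L, floor(sqrt(n)))
  bs <- floor(n / nb)
  means <- vapply(seq_len(nb), function(b)
    mean(x[((b - 1L) * bs + 1L):(b * bs)]), 1.0)
  stats::sd(means) / sqrt(nb)
}
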