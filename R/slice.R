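# Univariate slice sampler (stepping out + shrinkage, Neal 2003), used for
# non-conjugate scale updates (half-t priors) and the CAR dependence
# parameter.

sliceSample <- function(x0, logf, w = 1, lower = -Inf, upper = Inf,
                        maxSteps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  z <- f0 - stats::rexp(1)
  u <- runif(1)
  L <- max(x0 - w * u, lower)
  R <- min(L + w, upper)
  j <- floor(maxSteps * runif(1)); k <- maxSteps - 1 - j
  while (j > 0 && L > lower && logf(L) > z) { L <- max(L - w, lower); j <- j - 1 }
  while (k > 0 && R < upper && logf(R) > z) { R <- min(R + w, upper); k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Log densities of the supported scale hyperpriors, on the standard-deviation
# scale (up to constants).
logPriorScale <- function(sigma, prior) {
  switch(prior$dist,
    half_t = {
      if (sigma <= 0) return(-Inf)
      -(prior$nu + 1) / 2 * log1p((sigma / prior$scale)^2 / prior$nu)
    },
    inverse_gamma = {
      # IG(a, b) on the VARIANCE sigma^2; transform to sigma: x 2 sigma jacobian
      if (sigma <= 0) return(-Inf)
      v <- sigma^2
      (-prior$a - 1) * log(v) - prior$b / v + log(2 * sigma)
    },
    point_mass = if (abs(sigma - prior$value) < 1e-12) 0 else -Inf,
    stop(sprintf("unknown hyperprior '%s'", prior$dist))
  )
}
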