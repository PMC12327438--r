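# Link/variance triples with the IWLS conventions: working response
# Ytilde_i = X_i beta + (r_i - u_i) g'(u_i) and weights
# w_i = a_i / (phi^2 v(u_i) g'(u_i)^2), where r_i is the response on the mean
# scale (success proportion or event rate) and a_i the trials/exposure.

.MEAN_EPS <- 1e-8

#' Link family constructor
#'
#' @param name one of "gaussian-identity", "binomial-logit", "poisson-log".
#' @return A [LinkFamily-class] with the link, inverse link, link derivative
#'   and variance function.  Means are clipped away from the boundary
#'   (logit: \code{[1e-8, 1-1e-8]}; log: floored at \code{1e-8}) before the
#'   derivative and variance are evaluated.
#' @examples
#' fam <- linkFamily("binomial-logit")
#' fam@gprime(0.5)  # 4
#' fam@v(0.5)       # 0.25
#' @export
linkFamily <- function(name) {
  switch(name,
    "gaussian-identity" = new("LinkFamily", name = name,
      g = function(u) u, ginv = function(eta) eta,
      gprime = function(u) rep(1, length(u)),
      v = function(u) rep(1, length(u))),
    "binomial-logit" = new("LinkFamily", name = name,
      g = function(u) qlogis(u),
      ginv = function(eta) pmin(pmax(plogis(eta), .MEAN_EPS), 1 - .MEAN_EPS),
      gprime = function(u) 1 / (u * (1 - u)),
      v = function(u) u * (1 - u)),
    "poisson-log" = new("LinkFamily", name = name,
      g = function(u) log(u),
      ginv = function(eta) pmax(exp(eta), .MEAN_EPS),
      gprime = function(u) 1 / u,
      v = function(u) u),
    stop(sprintf("unknown link family '%s'", name))
  )
}

# Family name of a RegressionData -> LinkFamily name.
dataLinkName <- function(data) {
  switch(data@family,
    gaussian = "gaussian-identity",
    binomial = "binomial-logit",
    poisson = "poisson-log")
}
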