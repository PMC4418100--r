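# Circular and re-parameterised distributions used by the synchrony model.

#' Wrapped Cauchy density
#'
#' Circular density with mean direction `mu` and concentration `rho` in
#' \[0, 1): `rho = 0` is the uniform circle (no synchrony), `rho -> 1`
#' concentrates all mass at `mu` (perfect synchrony).  `rho` equals the mean
#' resultant length (mean cosine) of the distribution.
#'
#' @param theta angle(s), radians; the density is 2*pi-periodic.
#' @param mu mean direction, radians.
#' @param rho concentration in \[0, 1).
#' @param log if `TRUE`, return the log density.
#' @return density values, recycled over the longest argument.
#' @export
dwrapcauchy <- function(theta, mu = 0, rho = 0, log = FALSE) {
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1)")
  ld <- log1p(-rho^2) - base::log(2 * pi) -
    base::log(1 + rho^2 - 2 * rho * cos(theta - mu))
  if (log) ld else exp(ld)
}

#' Wrapped Cauchy random draws
#'
#' Inverse-CDF construction: `theta = mu + 2*atan(((1-rho)/(1+rho)) *
#' tan(pi*(U - 1/2)))`, wrapped to (-pi, pi].
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param rho concentration in \[0, 1).
#' @return `n` angles in (-pi, pi].
#' @export
rwrapcauchy <- function(n, mu = 0, rho = 0) {
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1)")
  u <- stats::runif(n)
  wrap_angle(mu + 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5))))
}

#' Beta density parameterised by mode and shape
#'
#' The hierarchical distribution of per-frequency synchrony levels: a beta
#' distribution given by its mode `M` in (0, 1) and shape `nu = alpha +
#' beta`.  The standard shapes are `alpha = M*(nu - 2) + 1` and `beta =
#' (1 - M)*(nu - 2) + 1`; `nu > 2` guarantees an interior mode at `M`.
#' Small `nu` allows synchrony to differ widely between frequencies, large
#' `nu` shrinks all frequencies towards a common level.
#'
#' @param x value(s) in \[0, 1\].
#' @param mode the mode `M`, in (0, 1).
#' @param shape the shape `nu = alpha + beta`, must exceed 2.
#' @param log if `TRUE`, return the log density.
#' @export
dbetamode <- function(x, mode, shape, log = FALSE) {
  if (any(shape <= 2)) stop("shape must exceed 2 for an interior mode")
  if (any(mode <= 0 | mode >= 1)) stop("mode must be in (0, 1)")
  a <- mode * (shape - 2) + 1
  b <- (1 - mode) * (shape - 2) + 1
  stats::dbeta(x, a, b, log = log)
}

#' Scaled inverse chi-squared distribution
#'
#' If `W ~ chisq(nu)` then `nu*s2/W` has the scaled inverse chi-squared
#' distribution with `nu` degrees of freedom and scale `s2`; its mode is
#' `nu*s2/(nu + 2)`.  Conjugate prior for a normal variance.
#'
#' @param x,q,p usual distribution-function arguments.
#' @param n number of draws.
#' @param nu degrees of freedom (> 0).
#' @param s2 scale (> 0).
#' @param log if `TRUE`, return the log density.
#' @name sinvchisq
NULL

#' @rdname sinvchisq
#' @export
dsinvchisq <- function(x, nu, s2, log = FALSE) {
  ld <- (nu / 2) * base::log(nu * s2 / 2) - lgamma(nu / 2) -
    (nu / 2 + 1) * base::log(x) - nu * s2 / (2 * x)
  ld[x <= 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname sinvchisq
#' @export
psinvchisq <- function(q, nu, s2) {
  ifelse(q <= 0, 0, 1 - stats::pchisq(nu * s2 / q, nu))
}

#' @rdname sinvchisq
#' @export
qsinvchisq <- function(p, nu, s2) {
  nu * s2 / stats::qchisq(1 - p, nu)
}

#' @rdname sinvchisq
#' @export
rsinvchisq <- function(n, nu, s2) {
  nu * s2 / stats::rchisq(n, nu)
}
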