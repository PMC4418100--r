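# Hyperprior elicitation.
#
# The prior constants are not stated directly as distribution parameters but
# as elicitation conditions ("95% of the density between 5 and 200", "mode
# 0.0625, 95th percentile 1"); the solvers below turn those statements into
# (shape, rate) / (nu0, sigma0^2) pairs by root finding.

#' Gamma parameters from a central probability interval
#'
#' Finds the gamma distribution whose equal-tailed central interval
#' \[lo, hi\] carries probability `mass` — i.e. `F(lo) = (1 - mass)/2` and
#' `F(hi) = 1 - (1 - mass)/2`.  Used for the vague prior on the beta shape
#' `nu`: 95% of the density between 5 (synchrony very different between
#' frequencies) and 200 (nearly common synchrony).
#'
#' @param lo,hi interval endpoints, `0 < lo < hi`.
#' @param mass central probability, in (0, 1); default 0.95.
#' @return list with `shape` and `rate`.
#' @export
solve_gamma_interval <- function(lo, hi, mass = 0.95) {
  stopifnot(lo > 0, hi > lo, mass > 0, mass < 1)
  tail <- (1 - mass) / 2
  rate_for <- function(shape) stats::qgamma(tail, shape) / lo
  g <- function(shape) stats::pgamma(hi, shape, rate_for(shape)) - (1 - tail)
  bounds <- c(1e-3, 1e3)
  if (g(bounds[1]) * g(bounds[2]) > 0)
    stop("no gamma distribution satisfies the interval condition within search bounds")
  shape <- stats::uniroot(g, bounds, tol = 1e-12)$root
  list(shape = shape, rate = rate_for(shape))
}

#' Scaled inverse chi-squared parameters from mode and upper percentile
#'
#' Finds `(nu0, sigma0^2)` such that the scaled inverse chi-squared
#' distribution has mode `nu0*sigma0^2/(nu0 + 2) = mode` and 95th
#' percentile `p95`.  Used for the prior on the between-individual variance
#' of the noise-colour parameter.
#'
#' @param mode most likely value of the variance (> 0).
#' @param p95 upper 95% percentile (> mode).
#' @return list with `nu0` and `sigma0_sq`.
#' @export
solve_scaled_inv_chi2 <- function(mode, p95) {
  stopifnot(mode > 0, p95 > mode)
  s2_for <- function(nu0) mode * (nu0 + 2) / nu0
  h <- function(nu0) psinvchisq(p95, nu0, s2_for(nu0)) - 0.95
  bounds <- c(2.01, 1e3)
  if (h(bounds[1]) * h(bounds[2]) > 0)
    stop("no scaled inverse chi-squared satisfies the conditions within search bounds")
  nu0 <- stats::uniroot(h, bounds, tol = 1e-12)$root
  list(nu0 = nu0, sigma0_sq = s2_for(nu0))
}

#' Prior specification for the synchrony and colour models
#'
#' Bundles every prior used by [fit_synchrony()], [scan_cutoff()] and
#' [fit_colour()], solving the elicited constants once:
#' \itemize{
#'   \item `nu` (beta shape): gamma with 95% central density in
#'     `nu_interval` (default c(5, 200); the alternatives c(5, 10) and
#'     c(100, 200) are the sensitivity priors).
#'   \item `M` (beta mode): `Beta(M_prior[1], M_prior[2])`; c(1, 1) is the
#'     default uniform, c(0.5, 0.5) and c(5, 5) are the sensitivity priors.
#'   \item `mu_f`: Uniform(-pi, pi).
#'   \item `gamma_bar`: Normal(`gammabar_mean`, variance `gammabar_var`);
#'     defaults 0 and 4, i.e. 95% of prior mass in about (-4, 4).
#'   \item `sigma_gamma^2`: scaled inverse chi-squared solved from
#'     `sigma_gamma_mode` (default 0.0625, i.e. sd most likely 0.25) and
#'     `sigma_gamma_p95` (default 1, i.e. 95% sure sd < 1).
#'   \item `abar_log`, `sigma_alog^2`: improper flat priors.
#' }
#'
#' @param nu_interval length-2 central 95% interval for the beta shape.
#' @param nu_mass probability carried by `nu_interval`.
#' @param M_prior length-2 beta shape parameters for the mode M, or one of
#'   `"uniform"` (Beta(1,1)), `"jeffreys"` (Beta(0.5,0.5)),
#'   `"concentrated"` (Beta(5,5)).
#' @param gammabar_mean,gammabar_var normal prior for the population colour.
#' @param sigma_gamma_mode,sigma_gamma_p95 elicited mode and 95th percentile
#'   of the between-individual colour variance.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(nu_interval = c(5, 200), nu_mass = 0.95,
                       M_prior = c(1, 1),
                       gammabar_mean = 0, gammabar_var = 4,
                       sigma_gamma_mode = 0.0625, sigma_gamma_p95 = 1) {
  if (is.character(M_prior)) {
    M_prior <- switch(match.arg(M_prior, c("uniform", "jeffreys", "concentrated")),
                      uniform = c(1, 1), jeffreys = c(0.5, 0.5),
                      concentrated = c(5, 5))
  }
  stopifnot(length(M_prior) == 2, all(M_prior > 0))
  nu <- solve_gamma_interval(nu_interval[1], nu_interval[2], nu_mass)
  sg <- solve_scaled_inv_chi2(sigma_gamma_mode, sigma_gamma_p95)
  structure(list(
    nu_shape = nu$shape, nu_rate = nu$rate,
    nu_interval = nu_interval, nu_mass = nu_mass,
    M_alpha = M_prior[1], M_beta = M_prior[2],
    gammabar_mean = gammabar_mean, gammabar_var = gammabar_var,
    sigma_gamma_nu0 = sg$nu0, sigma_gamma_s0sq = sg$sigma0_sq,
    sigma_gamma_mode = sigma_gamma_mode, sigma_gamma_p95 = sigma_gamma_p95
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification\n")
  cat(sprintf("  nu     ~ Gamma(shape = %.4f, rate = %.5f)  [%.0f%% mass in (%g, %g)]\n",
              x$nu_shape, x$nu_rate, 100 * x$nu_mass,
              x$nu_interval[1], x$nu_interval[2]))
  cat(sprintf("  M      ~ Beta(%g, %g)\n", x$M_alpha, x$M_beta))
  cat("  mu_f   ~ Uniform(-pi, pi)\n")
  cat(sprintf("  gamma_bar     ~ Normal(%g, var = %g)\n",
              x$gammabar_mean, x$gammabar_var))
  cat(sprintf("  sigma_gamma^2 ~ Scaled-Inv-Chi2(nu0 = %.3f, s0^2 = %.5f)  [mode %g, p95 %g]\n",
              x$sigma_gamma_nu0, x$sigma_gamma_s0sq,
              x$sigma_gamma_mode, x$sigma_gamma_p95))
  cat("  abar_log, sigma_alog^2: flat\n")
  invisible(x)
}
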