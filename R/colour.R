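# Hierarchical Bayesian estimation of 1/f-noise colour.
#
# Periodogram ordinates are modelled through the Whittle approximation as
# independent exponential variables with mean Y_fn = a_n * f^(-gamma_n);
# gamma_n is the noise colour of individual n (red > 0, white = 0, blue < 0)
# and a_n a positive nuisance scale.  Individual parameters are pooled
# through normal population models on gamma_n and log(a_n), with conjugate
# (normal / scaled inverse chi-squared) hyperpriors on the gamma level and
# flat hyperpriors on the log-scale level.

# Conditional posterior of the population colour mean given the individual
# colours and their variance: Normal(mean, sd) by normal-normal conjugacy.
cond_gammabar <- function(gam, s2g, priors) {
  N <- length(gam)
  V <- 1 / (N / s2g + 1 / priors$gammabar_var)
  c(mean = V * (sum(gam) / s2g + priors$gammabar_mean / priors$gammabar_var),
    sd = sqrt(V))
}

# Conditional posterior of the between-individual colour variance:
# Scaled-Inv-Chi2(nu, s2) by scaled-inverse-chi-squared conjugacy.
cond_sigma_gamma_sq <- function(gam, gbar, priors) {
  N <- length(gam)
  nu_n <- priors$sigma_gamma_nu0 + N
  c(nu = nu_n,
    s2 = (priors$sigma_gamma_nu0 * priors$sigma_gamma_s0sq +
            sum((gam - gbar)^2)) / nu_n)
}

#' Whittle log likelihood of the 1/f model
#'
#' `sum_n sum_f [ -log(Y_fn) - psi_fn / Y_fn ]` with
#' `Y_fn = a_n * f^(-gamma_n)`, the log density of independent exponential
#' ordinates with mean equal to the model spectrum.
#'
#' @param psi m x N matrix of periodogram ordinates (frequencies in rows).
#' @param a positive scale, one per individual.
#' @param gamma noise colour, one per individual.
#' @return the log likelihood (a single number).
#' @export
whittle_loglik <- function(psi, a, gamma) {
  psi <- as.matrix(psi)
  if (any(a <= 0)) stop("scale a must be positive")
  sum(per_ind_whittle_loglik(psi, a, gamma))
}

# Vector of per-individual Whittle log likelihoods.
per_ind_whittle_loglik <- function(psi, a, gamma) {
  m <- nrow(psi)
  lf <- log(seq_len(m))
  logY <- matrix(log(a), m, length(a), byrow = TRUE) - outer(lf, gamma)
  colSums(-logY - psi * exp(-logY))
}

#' Fit the hierarchical 1/f-noise colour model
#'
#' Metropolis-within-Gibbs sampler: random-walk Metropolis updates for each
#' `gamma_n` and `log(a_n)` (vectorised across individuals, adapted towards
#' 20-40% acceptance during burn-in), and exact Gibbs updates for the
#' population parameters via normal / scaled-inverse-chi-squared conjugacy:
#' `gamma_bar | . ~ Normal`, `sigma_gamma^2 | . ~ Scaled-Inv-Chi2`,
#' `abar_log | . ~ Normal`, `sigma_alog^2 | . ~ Scaled-Inv-Chi2(N - 2, S/(N-2))`
#' (the flat-prior posterior, proper for N >= 3).
#'
#' @param psi m x N ordinate matrix or a `spectral_decomp`.
#' @param priors a [prior_spec()].
#' @param chains,iters,burn MCMC settings.
#' @param seed integer seed.
#' @return an object of class `colour_fit` with posterior `samples`
#'   (matrices `gamma`, `log_a`; vectors `gamma_bar`, `sigma_gamma`,
#'   `abar_log`, `sigma_alog`), a `summaries` table (posterior mean and
#'   central 95% credible interval), and `diagnostics`.
#' @export
fit_colour <- function(psi, priors = prior_spec(), chains = 4, iters = 20000,
                       burn = 0.5, seed = 1) {
  if (inherits(psi, "spectral_decomp")) {
    ids <- psi$individual_ids
    psi <- psi$ordinates
  } else {
    psi <- as.matrix(psi)
    ids <- colnames(psi)
    if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(psi)))
  }
  m <- nrow(psi); N <- ncol(psi)
  if (N < 3) stop("need at least 3 individuals (flat hyperprior on the scale level)")
  if (any(psi < 0)) stop("periodogram ordinates must be non-negative")
  keep <- iters - floor(burn * iters)
  if (keep < 1) stop("burn-in leaves no samples")
  chain_seeds <- seed_streams(seed, chains)
  lf <- log(seq_len(m))

  # Log-log least-squares fits give data-informed starting values.
  init_slope <- numeric(N); init_inter <- numeric(N)
  for (n in seq_len(N)) {
    y <- log(pmax(psi[, n], min(psi[psi > 0]) * 1e-3))
    cf <- stats::lm.fit(cbind(1, lf), y)$coefficients
    init_inter[n] <- cf[1]; init_slope[n] <- cf[2]
  }

  run_chain <- function(cs) {
    set.seed(cs)
    gam <- -init_slope + stats::rnorm(N, 0, 0.2)
    la <- init_inter + stats::rnorm(N, 0, 0.3)
    gbar <- mean(gam); s2g <- max(stats::var(gam), 0.05)
    abar <- mean(la); s2a <- max(stats::var(la), 0.05)
    ls_g <- rep(log(0.3), N); ls_a <- rep(log(0.3), N)
    ll <- per_ind_whittle_loglik(psi, exp(la), gam)

    n_burn <- iters - keep
    S_g <- matrix(NA_real_, keep, N); S_la <- matrix(NA_real_, keep, N)
    S_gbar <- numeric(keep); S_sg <- numeric(keep)
    S_abar <- numeric(keep); S_sa <- numeric(keep); S_dev <- numeric(keep)
    acc <- c(gamma = 0, log_a = 0); n_acc <- 0
    b_g <- numeric(N); b_a <- numeric(N); b_n <- 0

    for (it in seq_len(iters)) {
      adapting <- it <= n_burn
      # gamma_n updates
      g2 <- gam + exp(ls_g) * stats::rnorm(N)
      ll2 <- per_ind_whittle_loglik(psi, exp(la), g2)
      d <- (ll2 + stats::dnorm(g2, gbar, sqrt(s2g), log = TRUE)) -
           (ll + stats::dnorm(gam, gbar, sqrt(s2g), log = TRUE))
      a_ok <- log(stats::runif(N)) < d
      gam[a_ok] <- g2[a_ok]; ll[a_ok] <- ll2[a_ok]
      if (adapting) b_g <- b_g + a_ok else acc["gamma"] <- acc["gamma"] + mean(a_ok)

      # log(a_n) updates
      la2 <- la + exp(ls_a) * stats::rnorm(N)
      ll2 <- per_ind_whittle_loglik(psi, exp(la2), gam)
      d <- (ll2 + stats::dnorm(la2, abar, sqrt(s2a), log = TRUE)) -
           (ll + stats::dnorm(la, abar, sqrt(s2a), log = TRUE))
      a_ok <- log(stats::runif(N)) < d
      la[a_ok] <- la2[a_ok]; ll[a_ok] <- ll2[a_ok]
      if (adapting) b_a <- b_a + a_ok else acc["log_a"] <- acc["log_a"] + mean(a_ok)

      # Gibbs: population colour level (normal prior on gamma_bar)
      cg <- cond_gammabar(gam, s2g, priors)
      gbar <- stats::rnorm(1, cg[1], cg[2])
      cs <- cond_sigma_gamma_sq(gam, gbar, priors)
      s2g <- rsinvchisq(1, cs[1], cs[2])

      # Gibbs: scale level (flat hyperpriors)
      abar <- stats::rnorm(1, mean(la), sqrt(s2a / N))
      S <- sum((la - abar)^2)
      s2a <- S / stats::rchisq(1, N - 2)

      if (adapting) {
        b_n <- b_n + 1
        if (b_n == 50) {
          clamp <- function(x) pmin(pmax(x, log(1e-4)), log(10))
          ls_g <- clamp(ls_g + 0.5 * (b_g / 50 - 0.3))
          ls_a <- clamp(ls_a + 0.5 * (b_a / 50 - 0.3))
          b_g[] <- 0; b_a[] <- 0; b_n <- 0
        }
      } else {
        k <- it - n_burn
        S_g[k, ] <- gam; S_la[k, ] <- la
        S_gbar[k] <- gbar; S_sg[k] <- sqrt(s2g)
        S_abar[k] <- abar; S_sa[k] <- sqrt(s2a)
        S_dev[k] <- -2 * sum(ll)
        n_acc <- n_acc + 1
      }
    }
    list(g = S_g, la = S_la, gbar = S_gbar, sg = S_sg, abar = S_abar,
         sa = S_sa, dev = S_dev, acc = acc / n_acc)
  }

  res <- lapply(chain_seeds, run_chain)
  samples <- list(
    gamma = do.call(rbind, lapply(res, `[[`, "g")),
    log_a = do.call(rbind, lapply(res, `[[`, "la")),
    gamma_bar = unlist(lapply(res, `[[`, "gbar")),
    sigma_gamma = unlist(lapply(res, `[[`, "sg")),
    abar_log = unlist(lapply(res, `[[`, "abar")),
    sigma_alog = unlist(lapply(res, `[[`, "sa")),
    deviance = unlist(lapply(res, `[[`, "dev")))
  colnames(samples$gamma) <- colnames(samples$log_a) <- ids

  smry <- function(v) c(mean(v), stats::quantile(v, c(0.025, 0.975),
                                                 names = FALSE))
  tab <- rbind(t(apply(samples$gamma, 2, smry)),
               smry(samples$gamma_bar),
               smry(samples$sigma_gamma),
               t(apply(samples$log_a, 2, smry)),
               smry(samples$abar_log),
               smry(samples$sigma_alog))
  summaries <- data.frame(
    parameter = c(paste0("gamma[", ids, "]"), "gamma_bar", "sigma_gamma",
                  paste0("log_a[", ids, "]"), "abar_log", "sigma_alog"),
    mean = tab[, 1], lower95 = tab[, 2], upper95 = tab[, 3],
    row.names = NULL)
  rh <- max(rhat(vapply(res, `[[`, numeric(keep), "gbar")),
            rhat(vapply(res, `[[`, numeric(keep), "dev")))
  if (is.finite(rh) && rh > 1.1)
    warning(sprintf("colour MCMC: split R-hat %.3f > 1.1", rh))
  structure(list(samples = samples, summaries = summaries,
                 psi = psi, m = m, N = N, frequency = seq_len(m),
                 individual_ids = ids,
                 diagnostics = list(chains = chains, iters = iters,
                                    burn = burn, rhat = rh,
                                    accept = Reduce(`+`, lapply(res, `[[`, "acc")) / chains),
                 priors = priors, seed = seed),
            class = "colour_fit")
}

#' @export
print.colour_fit <- function(x, ...) {
  cat(sprintf("Hierarchical 1/f-noise colour fit: N = %d individuals, m = %d frequencies\n",
              x$N, x$m))
  g <- x$summaries[grepl("^gamma", x$summaries$parameter), ]
  cat("Posterior mean [95% CI] of noise colour:\n")
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-12s %.2f [%.2f, %.2f]\n", g$parameter[i], g$mean[i],
                g$lower95[i], g$upper95[i]))
  cat(sprintf("Split R-hat: %.3f\n", x$diagnostics$rhat))
  invisible(x)
}

#' @export
summary.colour_fit <- function(object, ...) {
  print(object)
  invisible(object$summaries)
}

#' @export
coef.colour_fit <- function(object, ...) {
  c(stats::setNames(colMeans(object$samples$gamma),
                    paste0("gamma[", object$individual_ids, "]")),
    gamma_bar = mean(object$samples$gamma_bar),
    sigma_gamma = mean(object$samples$sigma_gamma),
    stats::setNames(colMeans(object$samples$log_a),
                    paste0("log_a[", object$individual_ids, "]")),
    abar_log = mean(object$samples$abar_log),
    sigma_alog = mean(object$samples$sigma_alog))
}

# One joint posterior draw index per realization.
draw_rows <- function(fit, n) {
  sample.int(nrow(fit$samples$gamma), n, replace = TRUE)
}

#' Posterior-predictive periodogram bands
#'
#' For each replication, draws `(a_n, gamma_n)` jointly from the posterior
#' and then a periodogram `psi* ~ Exp(mean a_n f^(-gamma_n))`; reports the
#' per-frequency, per-individual predictive mean and central 95% band.
#'
#' @param object a `colour_fit`.
#' @param n_reps number of posterior-predictive replications.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with columns `frequency`, `individual`, `mean`,
#'   `lower`, `upper`.
#' @export
predict.colour_fit <- function(object, n_reps = 1000, seed = NULL, ...) {
  if (nrow(object$samples$gamma) < 100)
    stop("need at least 100 posterior draws")
  if (!is.null(seed)) set.seed(seed)
  m <- object$m; N <- object$N
  rows <- draw_rows(object, n_reps)
  draws <- array(NA_real_, c(n_reps, m, N))
  lf <- log(seq_len(m))
  for (r in seq_len(n_reps)) {
    g <- object$samples$gamma[rows[r], ]
    a <- exp(object$samples$log_a[rows[r], ])
    Y <- exp(matrix(log(a), m, N, byrow = TRUE) - outer(lf, g))
    draws[r, , ] <- matrix(stats::rexp(m * N), m, N) * Y
  }
  out <- expand.grid(frequency = seq_len(m),
                     individual = object$individual_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- as.vector(apply(draws, c(2, 3), mean))
  out$lower <- as.vector(apply(draws, c(2, 3), stats::quantile, 0.025))
  out$upper <- as.vector(apply(draws, c(2, 3), stats::quantile, 0.975))
  out
}

#' Posterior-predictive periodogram draws
#'
#' @param object a `colour_fit`.
#' @param nsim number of simulated periodogram matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` m x N matrices.
#' @export
simulate.colour_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$m; N <- object$N
  lf <- log(seq_len(m))
  rows <- draw_rows(object, nsim)
  lapply(rows, function(r) {
    g <- object$samples$gamma[r, ]
    a <- exp(object$samples$log_a[r, ])
    Y <- exp(matrix(log(a), m, N, byrow = TRUE) - outer(lf, g))
    matrix(stats::rexp(m * N), m, N) * Y
  })
}

#' Standardised spectral residuals at the posterior mean
#'
#' `Z_fn = psi_fn / Y_fn` evaluated at the posterior means of `(a, gamma)`;
#' approximately unit-exponential if the 1/f model holds.
#'
#' @param object a `colour_fit`.
#' @param ... unused.
#' @return m x N matrix of residuals.
#' @export
residuals.colour_fit <- function(object, ...) {
  g <- colMeans(object$samples$gamma)
  a <- exp(colMeans(object$samples$log_a))
  lf <- log(seq_len(object$m))
  Y <- exp(matrix(log(a), object$m, object$N, byrow = TRUE) - outer(lf, g))
  object$psi / Y
}

#' Residual diagnostics for the 1/f model
#'
#' Validates the Whittle likelihood (independent exponential ordinates with
#' mean `a_n f^(-gamma_n)`).  Realizations of the model spectrum are
#' generated by joint posterior draws of `(a_n, gamma_n)`; for each, the
#' standardised residuals `Z_fn = psi_fn / Y_fn` are tested per individual
#' for autocorrelation (Pearson correlation of `(Z_f, Z_{f+lag})` at lags 1,
#' 5 and 10) and for exponentiality (one-sample Kolmogorov-Smirnov against
#' the unit exponential).  A test is declared significant for an individual
#' when more than 50% of realizations yield p < 0.05.
#'
#' @param fit a `colour_fit`.
#' @param n_realizations number of posterior realizations (>= 100).
#' @param lags autocorrelation lags to test.
#' @param seed optional seed.
#' @return an object of class `residual_report`: matrices `proportions`
#'   (individual x test, fraction of realizations with p < 0.05) and
#'   `verdicts` (proportion > 0.5).
#' @export
residual_diagnostics <- function(fit, n_realizations = 1000,
                                 lags = c(1, 5, 10), seed = NULL) {
  stopifnot(inherits(fit, "colour_fit"))
  if (n_realizations < 100) stop("need at least 100 realizations")
  m <- fit$m; N <- fit$N
  if (any(lags >= m)) stop("lag must be smaller than the number of frequencies")
  if (!is.null(seed)) set.seed(seed)
  lf <- log(seq_len(m))
  tests <- c(paste0("lag", lags), "ks_exp")
  hits <- matrix(0, N, length(tests),
                 dimnames = list(fit$individual_ids, tests))
  rows <- draw_rows(fit, n_realizations)
  for (r in seq_len(n_realizations)) {
    g <- fit$samples$gamma[rows[r], ]
    a <- exp(fit$samples$log_a[rows[r], ])
    Y <- exp(matrix(log(a), m, N, byrow = TRUE) - outer(lf, g))
    Z <- fit$psi / Y
    for (n in seq_len(N)) {
      z <- Z[, n]
      for (j in seq_along(lags)) {
        lag <- lags[j]
        p <- stats::cor.test(z[seq_len(m - lag)],
                             z[(lag + 1):m])$p.value
        hits[n, j] <- hits[n, j] + (p < 0.05)
      }
      p <- stats::ks.test(z, stats::pexp)$p.value
      hits[n, length(lags) + 1] <- hits[n, length(lags) + 1] + (p < 0.05)
    }
  }
  prop <- hits / n_realizations
  structure(list(proportions = prop, verdicts = prop > 0.5,
                 n_realizations = n_realizations, lags = lags),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("Residual diagnostics (%d posterior realizations; verdict = >50%% of realizations with p < 0.05)\n",
              x$n_realizations))
  cat("\nFraction of realizations with p < 0.05:\n")
  print(round(x$proportions, 3))
  cat("\nVerdicts:\n")
  print(x$verdicts)
  invisible(x)
}

#' Periodogram with posterior-predictive band
#'
#' Log-log plot of observed ordinates with the posterior-predictive mean and
#' central 95% band for each individual.
#'
#' @param x a `colour_fit`.
#' @param band optional precomputed output of [predict.colour_fit()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.colour_fit <- function(x, band = NULL, ...) {
  if (is.null(band)) band <- predict(x, n_reps = 500)
  f <- seq_len(x$m)
  graphics::matplot(f, x$psi, log = "xy", pch = 1, col = seq_len(x$N),
                    xlab = "frequency (cycles per record)",
                    ylab = "periodogram ordinate", ...)
  for (n in seq_len(x$N)) {
    b <- band[band$individual == x$individual_ids[n], ]
    graphics::lines(f, b$mean, col = n)
    graphics::lines(f, b$lower, col = n, lty = 3)
    graphics::lines(f, b$upper, col = n, lty = 3)
  }
  invisible(x)
}
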