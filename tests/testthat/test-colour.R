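# Whittle likelihood, hierarchical colour fit, predictive bands, residuals.

test_that("Whittle log likelihood matches elementwise brute force and its limits", {
  set.seed(41)
  psi <- matrix(rexp(6), 3, 2)
  # white noise at unit scale: mean 1 everywhere, so ll = -sum(psi)
  expect_equal(whittle_loglik(psi, a = c(1, 1), gamma = c(0, 0)), -sum(psi))
  a <- c(0.5, 2); gam <- c(0.3, 1.1)
  brute <- 0
  for (n in 1:2) for (f in 1:3) {
    Y <- a[n] * f^(-gam[n])
    brute <- brute - log(Y) - psi[f, n] / Y
  }
  expect_equal(whittle_loglik(psi, a, gam), brute, tolerance = 1e-10)
  # residuals at their mean: psi = Y gives -sum(1 + log Y)
  Y <- sweep(exp(-outer(log(1:3), gam)), 2, a, "*")
  expect_equal(whittle_loglik(Y, a, gam), -sum(1 + log(Y)), tolerance = 1e-10)
  expect_error(whittle_loglik(psi, c(-1, 1), gam), "positive")
})

test_that("Gibbs conditional for the population colour matches a quadrature oracle", {
  p <- prior_spec()
  gam <- c(0.9, 0.5, 0.7, 1.1, 0.6)
  s2g <- 0.04
  cond <- movesync:::cond_gammabar(gam, s2g, p)
  # independent route: numeric posterior moments on a fine grid
  grid <- seq(-3, 3, length.out = 20001)
  post <- dnorm(grid, p$gammabar_mean, sqrt(p$gammabar_var)) *
    vapply(grid, function(g) prod(dnorm(gam, g, sqrt(s2g))), numeric(1))
  post <- post / sum(post)
  expect_equal(unname(cond["mean"]), sum(grid * post), tolerance = 1e-6)
  expect_equal(unname(cond["sd"]),
               sqrt(sum(grid^2 * post) - sum(grid * post)^2), tolerance = 1e-5)
  # variance conditional: quadrature moments of the scaled-inv-chi2 density
  cs <- movesync:::cond_sigma_gamma_sq(gam, 0.8, p)
  dens <- function(x) dsinvchisq(x, p$sigma_gamma_nu0, p$sigma_gamma_s0sq) *
    vapply(x, function(s2) prod(dnorm(gam, 0.8, sqrt(s2))), numeric(1))
  zc <- integrate(dens, 0, 50, rel.tol = 1e-10)$value
  m1 <- integrate(function(x) x * dens(x), 0, 50, rel.tol = 1e-10)$value / zc
  nu_n <- cs["nu"]; s2_n <- cs["s2"]
  expect_equal(unname(m1), unname(nu_n * s2_n / (nu_n - 2)), tolerance = 1e-6)
})

test_that("colour fit recovers known individual and population parameters", {
  set.seed(42)
  psi <- rpsi(31, 6, a = rep(1, 6), gamma = rep(1, 6))
  f <- fit_colour(psi, chains = fast$chains, iters = fast$iters, seed = 5)
  gb <- f$summaries[f$summaries$parameter == "gamma_bar", ]
  expect_lt(gb$lower95, 1); expect_gt(gb$upper95, 1)
  expect_equal(gb$mean, 1, tolerance = 0.3)
  expect_true(all(f$summaries$lower95 <= f$summaries$mean &
                    f$summaries$mean <= f$summaries$upper95))
  cf <- coef(f)
  expect_length(cf, 6 + 6 + 4)
})

test_that("multiplying one individual's ordinates shifts log a and not gamma", {
  set.seed(43)
  psi <- rpsi(31, 4, a = rep(1, 4), gamma = rep(0.75, 4))
  psi2 <- psi; psi2[, 2] <- 10 * psi2[, 2]
  f1 <- fit_colour(psi, chains = 2, iters = 2000, seed = 6)
  f2 <- fit_colour(psi2, chains = 2, iters = 2000, seed = 6)
  d_la <- colMeans(f2$samples$log_a) - colMeans(f1$samples$log_a)
  d_g <- colMeans(f2$samples$gamma) - colMeans(f1$samples$gamma)
  expect_equal(unname(d_la[2]), log(10), tolerance = 0.15)
  expect_lt(max(abs(d_g)), 0.1)
})

test_that("posterior-predictive bands are calibrated and match the LLN mean", {
  set.seed(44)
  psi <- rpsi(31, 6, a = rep(1, 6), gamma = rep(0.75, 6))
  f <- fit_colour(psi, chains = fast$chains, iters = fast$iters, seed = 7)
  band <- predict(f, n_reps = 10000, seed = 8)
  inside <- mean(as.vector(psi) >= band$lower & as.vector(psi) <= band$upper)
  expect_gte(inside, 0.90); expect_lte(inside, 1)
  # LLN: band mean converges to the posterior mean of a * f^(-gamma)
  lf <- log(seq_len(31))
  Ybar <- sapply(seq_len(6), function(n)
    colMeans(exp(matrix(f$samples$log_a[, n], ncol = 1) %*% rep(1, 31) -
                   outer(f$samples$gamma[, n], lf))))
  expect_equal(band$mean, as.vector(Ybar), tolerance = 0.04)
})

test_that("a degenerate posterior reproduces unit-exponential band quantiles", {
  fake <- structure(list(
    samples = list(gamma = matrix(0, 200, 3), log_a = matrix(0, 200, 3)),
    m = 4L, N = 3L, individual_ids = paste0("i", 1:3)),
    class = "colour_fit")
  band <- predict(fake, n_reps = 20000, seed = 9)
  expect_equal(mean(band$lower), qexp(0.025), tolerance = 0.01)
  expect_equal(mean(band$upper), qexp(0.975), tolerance = 0.06)
  expect_equal(mean(band$mean), 1, tolerance = 0.02)
})

test_that("residual diagnostics: nominal rates under the model, detection under structure", {
  set.seed(45)
  psi <- rpsi(31, 4, a = rep(1, 4), gamma = rep(0.75, 4))
  f <- fit_colour(psi, chains = fast$chains, iters = fast$iters, seed = 10)
  rep_ok <- residual_diagnostics(f, n_realizations = 300, seed = 11)
  expect_true(all(!rep_ok$verdicts))
  expect_true(all(rep_ok$proportions <= 0.10))
  # residuals at the posterior mean are roughly unit exponential
  Z <- residuals(f)
  expect_equal(mean(Z), 1, tolerance = 0.15)
  # deterministic slow sinusoid in f: strong lag-1 structure must be flagged
  fr <- seq_len(31)
  s <- 1 + 0.9 * sin(2 * pi * fr / 31)
  psi_bad <- sweep(matrix(fr^(-0.75), 31, 4), 1, s, "*")
  fb <- fit_colour(psi_bad, chains = 2, iters = 1500, seed = 12)
  rep_bad <- residual_diagnostics(fb, n_realizations = 150, seed = 13)
  expect_true(all(rep_bad$verdicts[, "lag1"]))
  expect_error(residual_diagnostics(f, n_realizations = 300, lags = 31),
               "lag")
  expect_error(residual_diagnostics(f, n_realizations = 50), "100")
})

test_that("the population posterior tightens as more individuals are added", {
  width <- function(N, seed) {
    set.seed(seed)
    psi <- rpsi(31, N, a = rep(1, N), gamma = rnorm(N, 0.75, 0.25))
    f <- fit_colour(psi, chains = 2, iters = 1500, seed = seed)
    gb <- f$summaries[f$summaries$parameter == "gamma_bar", ]
    gb$upper95 - gb$lower95
  }
  w_small <- mean(c(width(4, 61), width(4, 62)))
  w_big <- mean(c(width(16, 63), width(16, 64)))
  expect_lt(w_big, w_small)
})
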