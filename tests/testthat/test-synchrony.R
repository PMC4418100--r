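# Cutoff likelihood, DIC machinery, and the synchrony sampler.

test_that("cutoff likelihood matches brute-force summation and its limits", {
  set.seed(31)
  theta <- matrix(runif(2 * 2, -pi, pi), 2)
  mu <- c(0.3, -1); rho <- c(0.6, 0.2)
  # term-by-term oracle, straight from the density formula
  brute <- function(phi) {
    ll <- -2 * (2 - phi) * log(2 * pi)
    for (f in seq_len(phi)) for (n in 1:2) {
      d <- (1 / (2 * pi)) * (1 - rho[f]^2) /
        (1 + rho[f]^2 - 2 * rho[f] * cos(theta[f, n] - mu[f]))
      ll <- ll + log(d)
    }
    ll
  }
  for (phi in 0:2)
    expect_equal(synchrony_loglik(theta, mu, rho, phi), brute(phi),
                 tolerance = 1e-10)
  # phi = 0, and phi = l with all rho = 0, are the pure-uniform model
  expect_equal(synchrony_loglik(theta, mu, rho, 0), -2 * 2 * log(2 * pi))
  expect_equal(synchrony_loglik(theta, mu, c(0, 0), 2), -2 * 2 * log(2 * pi))
  expect_error(synchrony_loglik(theta, mu, rho, 3), "phi")
})

test_that("rotating every individual's phase at one frequency only shifts mu", {
  set.seed(32)
  theta <- matrix(rwrapcauchy(3 * 4, 0.5, 0.7), 3)
  mu <- c(0.5, -0.2, 1); rho <- c(0.7, 0.4, 0.1)
  delta <- 2.1
  theta2 <- theta; theta2[2, ] <- theta2[2, ] + delta
  mu2 <- mu; mu2[2] <- mu2[2] + delta
  expect_equal(synchrony_loglik(theta2, mu2, rho, 3),
               synchrony_loglik(theta, mu, rho, 3), tolerance = 1e-12)
})

test_that("DIC machinery: degenerate posterior, wraparound mean, definitional recompute", {
  expect_equal(circular_mean(c(-3, 3)), pi, tolerance = 1e-10)
  theta <- matrix(rwrapcauchy(2 * 5, 0, 0.5), 2)
  ll <- function(mu, rho) synchrony_loglik(theta, mu, rho, 2)
  same <- list(mu = matrix(0.4, 200, 2), rho = matrix(0.3, 200, 2))
  d <- compute_dic(same, ll)
  expect_equal(d$p_D, 0, tolerance = 1e-10)
  expect_equal(d$dic, d$deviance_at_mean, tolerance = 1e-10)
  expect_equal(d$deviance_at_mean, -2 * ll(c(0.4, 0.4), c(0.3, 0.3)))
  expect_error(compute_dic(list(mu = matrix(0, 0, 2), rho = matrix(0, 0, 2)),
                           ll), "empty")
})

test_that("the phi = 0 null model is analytic: p_D = 0, deviance 2*N*l*log(2*pi)", {
  dec <- sim_dec(N = 6, L = 64, seed = 33)$dec
  f0 <- fit_synchrony(dec, phi = 0)
  expect_identical(f0$p_D, 0)
  expect_equal(f0$deviance_at_mean, 2 * 6 * 31 * log(2 * pi), tolerance = 0)
  expect_equal(f0$dic, 2 * f0$p_D + f0$deviance_at_mean)
})

test_that("stored DIC components recompute from the stored samples", {
  dec <- sim_dec(N = 8, L = 32, phi = 2, rho = 0.8, seed = 34)$dec
  f <- fit_synchrony(dec, phi = 2, chains = fast$chains, iters = fast$iters,
                     seed = 2)
  re <- compute_dic(f$samples[c("mu", "rho")],
                    function(mu, rho) synchrony_loglik(dec$phases, mu, rho, 2))
  expect_equal(re$p_D, f$p_D, tolerance = 1e-8)
  expect_equal(re$dic, f$dic, tolerance = 1e-8)
  expect_equal(re$mean_params$rho, f$mean_params$rho, tolerance = 1e-12)
  # dic = 2 p_D + D(mean) holds by construction
  expect_equal(f$dic, 2 * f$p_D + f$deviance_at_mean)
})

test_that("prior-only sampling recovers the uniform prior on M", {
  dec <- sim_dec(N = 4, L = 16, seed = 35)$dec
  f <- fit_synchrony(dec, phi = 5, chains = 2, iters = 15000, seed = 9,
                     use_likelihood = FALSE)
  M <- f$samples$M
  expect_equal(mean(M), 0.5, tolerance = 0.1)
  expect_equal(unname(quantile(M, c(0.25, 0.75))), c(0.25, 0.75),
               tolerance = 0.12)
})

test_that("posterior credible intervals for rho cover a strong truth", {
  hits <- 0; total <- 0
  for (rep in 1:10) {
    dec <- sim_dec(N = 20, L = 64, phi = 3, rho = 0.9, seed = 100 + rep)$dec
    f <- fit_synchrony(dec, phi = 3, chains = fast$chains, iters = fast$iters,
                       seed = rep)
    for (ff in 1:3) {
      ci <- quantile(f$samples$rho[, ff], c(0.025, 0.975))
      hits <- hits + (ci[1] <= 0.9 && 0.9 <= ci[2])
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("scan table structure: length l + 1, a single zero delta, parsimony ties", {
  dec <- sim_dec(N = 5, L = 12, phi = 0, seed = 36)$dec
  sc <- suppressWarnings(scan_cutoff(dec, chains = 2, iters = 600, seed = 4))
  expect_equal(nrow(sc$table), dec$l + 1)
  expect_true(all(sc$table$delta_dic >= 0))
  expect_identical(sum(sc$table$delta_dic == 0), 1L)
  expect_identical(sc$selected, sc$table$phi[which.min(sc$table$dic)])
})
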