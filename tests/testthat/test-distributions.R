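# Wrapped Cauchy, mode/shape beta, and scaled inverse chi-squared.

test_that("wrapped Cauchy density: uniform limit, mode value, normalisation", {
  expect_equal(dwrapcauchy(1.3, mu = 0.2, rho = 0), 1 / (2 * pi))
  # at the mode, (1 - rho^2)/(1 - rho)^2 = (1 + rho)/(1 - rho) = 3 for rho = 0.5
  expect_equal(dwrapcauchy(0.4, mu = 0.4, rho = 0.5), 3 / (2 * pi))
  for (rho in c(0, 0.3, 0.9)) {
    z <- integrate(dwrapcauchy, -pi, pi, mu = 0.7, rho = rho,
                   rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
  # 2*pi-periodic in theta and mu
  expect_equal(dwrapcauchy(1 + 2 * pi, 0.3, 0.8), dwrapcauchy(1, 0.3, 0.8))
  expect_equal(dwrapcauchy(1, 0.3 - 2 * pi, 0.8), dwrapcauchy(1, 0.3, 0.8))
  expect_error(dwrapcauchy(0, 0, 1), "rho")
})

test_that("wrapped Cauchy draws live on (-pi, pi] with resultant length rho", {
  set.seed(21)
  for (rho in c(0.3, 0.7)) {
    th <- rwrapcauchy(1e5, mu = 1.1, rho = rho)
    expect_true(all(th > -pi & th <= pi))
    r <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
    expect_equal(r, rho, tolerance = 0.01)
  }
  # rho = 0 is the uniform circle: KS rejects at roughly the nominal rate
  pvals <- replicate(40, ks.test(rwrapcauchy(200, 0.5, 0),
                                 punif, -pi, pi)$p.value)
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_error(rwrapcauchy(1, 0, 1.2), "rho")
})

test_that("mode/shape beta: shapes, argmax, normalisation", {
  # M = 0.5, nu = 4 is Beta(2, 2); density at the mode is 1.5
  expect_equal(dbetamode(0.5, 0.5, 4), dbeta(0.5, 2, 2))
  expect_equal(dbetamode(0.5, 0.5, 4), 1.5)
  # argmax over rho equals M, and matches the (alpha-1)/(alpha+beta-2) rule
  M <- 0.2; nu <- 10
  opt <- optimize(function(x) dbetamode(x, M, nu), c(0, 1), maximum = TRUE,
                  tol = 1e-10)
  expect_equal(opt$maximum, M, tolerance = 1e-5)
  a <- M * (nu - 2) + 1; b <- (1 - M) * (nu - 2) + 1
  expect_equal((a - 1) / (a + b - 2), M)
  for (p in list(c(0.2, 10), c(0.5, 4), c(0.8, 50))) {
    z <- integrate(dbetamode, 0, 1, mode = p[1], shape = p[2],
                   rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
  expect_error(dbetamode(0.5, 0.5, 2), "shape")
})

test_that("scaled inverse chi-squared functions are mutually consistent", {
  nu <- 4.2; s2 <- 0.3
  z <- integrate(dsinvchisq, 0, Inf, nu = nu, s2 = s2, rel.tol = 1e-10)$value
  expect_equal(z, 1, tolerance = 1e-8)
  for (q in c(0.05, 0.2, 1)) {
    num <- integrate(dsinvchisq, 0, q, nu = nu, s2 = s2, rel.tol = 1e-10)$value
    expect_equal(psinvchisq(q, nu, s2), num, tolerance = 1e-8)
  }
  expect_equal(psinvchisq(qsinvchisq(0.8, nu, s2), nu, s2), 0.8)
  # mode identity: nu*s2/(nu + 2)
  opt <- optimize(function(x) dsinvchisq(x, nu, s2), c(1e-4, 5), maximum = TRUE,
                  tol = 1e-10)
  expect_equal(opt$maximum, nu * s2 / (nu + 2), tolerance = 1e-5)
  set.seed(2)
  draws <- rsinvchisq(2e5, nu, s2)
  expect_equal(mean(draws < qsinvchisq(0.5, nu, s2)), 0.5, tolerance = 0.005)
})
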