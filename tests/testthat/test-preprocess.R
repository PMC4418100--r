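# Displacement panels and the skewness-minimising power transform.

test_that("displacements are Euclidean steps between consecutive daily fixes", {
  panel <- compute_displacements(toy_tracks())
  # individual a: stationary day 1, then a 3-4-5 step, then stationary
  expect_equal(unname(panel$distances["a", ]), c(0, 5, 0))
  expect_equal(unname(panel$distances["b", ]), c(5, 0, 6))
  expect_equal(ncol(panel$distances), 4 - 1)  # L = #days - 1
  expect_s3_class(panel, "displacement_panel")
})

test_that("gaps and duplicate fixes are hard errors naming the culprit", {
  tr <- toy_tracks()
  expect_error(compute_displacements(tr[-2, ]),
               "missing fix for individual a on 2006-02-04")
  tr2 <- rbind(tr, tr[1, ])
  expect_error(compute_displacements(tr2),
               "duplicate fix for individual a on 2006-02-03")
  expect_error(displacement_panel(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("sample skewness matches the moment definition and its symmetries", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  expect_equal(sample_skewness(c(0, 0, 3)), 1 / sqrt(2))  # m3/m2^1.5 by hand
  set.seed(4)
  for (i in 1:5) {
    x <- rlnorm(30)
    expect_equal(sample_skewness(x), oracle_skewness(x))
    # mirror flips the sign, scaling leaves it untouched
    expect_equal(sample_skewness(2 * mean(x) - x), -sample_skewness(x))
    expect_equal(sample_skewness(17.3 * x), sample_skewness(x))
  }
  expect_error(sample_skewness(rep(2, 5)), "zero variance")
  expect_error(sample_skewness(c(1, 2)), "at least 3")
})

test_that("an exactly symmetrisable panel yields c = 0.5 with zero objective", {
  s <- c(1, 2, 3, 4, 5, 6, 7)           # symmetric, positive
  panel <- displacement_panel(matrix(s^2, 1), dates = as.Date("2006-02-03") + 0:6)
  tp <- power_transform(panel)
  expect_lt(abs(tp$exponent - 0.5), 1e-4)
  expect_lt(tp$objective_value, 1e-8)
  expect_equal(tp$values, panel$distances^tp$exponent)
})

test_that("estimated exponent agrees with an exhaustive fine-grid search", {
  set.seed(7)
  panel <- displacement_panel(matrix(rlnorm(4 * 40, sdlog = 1.2), 4))
  tp <- power_transform(panel)
  grid <- seq(0.001, 1, by = 0.001)
  obj <- vapply(grid, function(c)
    sum(abs(apply(panel$distances^c, 1, oracle_skewness))), numeric(1))
  c_star <- grid[which.min(obj)]
  expect_lt(abs(tp$exponent - c_star), 0.0011)  # within one fine-grid step
  # recomputed objective agrees with the stored one
  expect_equal(tp$objective_value,
               sum(abs(apply(panel$distances^tp$exponent, 1, oracle_skewness))),
               tolerance = 1e-10)
})

test_that("transform objective is invariant to relabelling and rescaling", {
  set.seed(11)
  d <- matrix(rlnorm(3 * 30), 3)
  p1 <- displacement_panel(d)
  p2 <- displacement_panel(d[c(3, 1, 2), ])
  p3 <- displacement_panel(1000 * d)
  t1 <- power_transform(p1)
  expect_equal(t1$exponent, power_transform(p2)$exponent)
  expect_equal(t1$exponent, power_transform(p3)$exponent)
  # monotone: ordering of distances preserved under the transform
  expect_equal(order(t1$values[1, ]), order(d[1, ]))
})

test_that("constant-distance individuals are rejected", {
  d <- rbind(rlnorm(10), rep(3, 10))
  expect_error(power_transform(displacement_panel(d)), "constant")
})
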