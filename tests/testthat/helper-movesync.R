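# Shared fixtures.  All simulated fixtures are generated in code; MCMC
# settings are reduced relative to the 4 x 20000 defaults to keep the suite
# fast (the posteriors involved are low-dimensional and mix quickly).

fast <- list(chains = 2, iters = 1500, burn = 0.5)

# Decomposition of a synthetic panel with known truth.
sim_dec <- function(..., seed = 1) {
  sim <- simulate_panel(synthetic_config(..., seed = seed))
  list(dec = spectral_decompose(sim$X), truth = sim$truth)
}

# Independent skewness oracle: direct moment evaluation.
oracle_skewness <- function(x) {
  xc <- x - mean(x)
  mean(xc^3) / mean(xc^2)^1.5
}

# Periodogram matrix drawn directly from the 1/f exponential model.
rpsi <- function(m, N, a, gamma) {
  Y <- exp(matrix(log(a), m, N, byrow = TRUE) - outer(log(seq_len(m)), gamma))
  matrix(stats::rexp(m * N), m, N) * Y
}

# Small relocation-fix table: one fix per day, planar coordinates.
toy_tracks <- function() {
  data.frame(
    individual = rep(c("a", "b"), each = 4),
    date = rep(as.Date("2006-02-03") + 0:3, 2),
    easting = c(0, 0, 3, 3, 10, 13, 13, 13),
    northing = c(0, 0, 4, 4, 20, 24, 24, 30))
}
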