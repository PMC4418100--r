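# Small numerical helpers shared by the samplers.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles congruent to `x` modulo 2*pi, in (-pi, pi].
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Circular mean of angles
#'
#' Direction of the mean resultant vector; used for the posterior mean of
#' phase parameters, where the arithmetic mean is meaningless across the
#' -pi/pi discontinuity.
#'
#' @param x numeric vector of angles in radians.
#' @return a single angle in (-pi, pi].
#' @export
circular_mean <- function(x) {
  s <- sum(sin(x))
  c <- sum(cos(x))
  if (s == 0 && c == 0) return(0)
  a <- atan2(s, c)
  if (a <= -pi) a <- pi
  a
}

# Mean resultant length; equals rho in expectation for wrapped-Cauchy draws.
resultant_length <- function(x) {
  sqrt(mean(sin(x))^2 + mean(cos(x))^2)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Deterministic child seeds for independent stochastic stages/chains.
# Keeps every derived seed a valid 32-bit integer.
seed_streams <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Split-chain potential scale reduction factor (Gelman-Rubin R-hat).
# x: iterations x chains matrix of a scalar quantity.
rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  x <- cbind(x[seq_len(half), , drop = FALSE],
             x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x)
  n <- nrow(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Short deterministic hash of a configuration object, embedded in report
# output so results can be matched to the settings that produced them.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
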