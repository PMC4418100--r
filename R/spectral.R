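# Fourier decomposition of each individual's series into phases and
# periodogram ordinates.
#
# Frequency f is indexed in whole cycles per record of length L, so f
# corresponds to a time scale of L/f days.  For even L the record has L/2
# wave components; the Nyquist component (f = L/2) has a degenerate phase
# (0 or pi) and a non-exponential ordinate distribution, so phases and
# ordinates are both kept only for f = 1 .. L/2 - 1.

#' Spectral decomposition of a transformed panel
#'
#' Per individual, subtracts the series mean and computes the discrete
#' Fourier transform.  The periodogram ordinate at frequency f is
#' `|F_f|^2 / L` and the phase is the complex argument of `F_f`, in
#' (-pi, pi].  Frequencies run f = 1 .. L/2 - 1 (zero frequency and Nyquist
#' excluded).
#'
#' @param x a `transformed_panel`, `displacement_panel`, or numeric N x L
#'   matrix (individuals in rows).
#' @return an object of class `spectral_decomp` with elements `phases`
#'   (l x N), `ordinates` (m x N, m = l = L/2 - 1), `nyquist` (the excluded
#'   Nyquist ordinate per individual), `L`, `N`, `l`, `m`, and `frequency`
#'   (1..l, cycles per record).
#' @export
spectral_decompose <- function(x) {
  if (inherits(x, "transformed_panel")) {
    X <- x$values; ids <- x$individual_ids
  } else if (inherits(x, "displacement_panel")) {
    X <- x$distances; ids <- x$individual_ids
  } else {
    X <- as.matrix(x)
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(X)))
  }
  N <- nrow(X); L <- ncol(X)
  if (L < 4) stop("series length must be at least 4")
  if (L %% 2 != 0) stop("series length must be even")
  if (any(apply(X, 1, stats::var) == 0))
    stop("zero-variance series: spectral decomposition undefined")
  Xc <- X - rowMeans(X)
  Fmat <- stats::mvfft(t(Xc))            # L x N, series in columns
  l <- L / 2 - 1
  sel <- 2:(L / 2)                       # rows for f = 1..l
  coef <- Fmat[sel, , drop = FALSE]
  psi <- Mod(coef)^2 / L
  theta <- Arg(coef)
  theta[theta <= -pi] <- pi
  nyq <- Mod(Fmat[L / 2 + 1, ])^2 / L
  dimnames(psi) <- dimnames(theta) <- list(seq_len(l), ids)
  structure(list(phases = theta, ordinates = psi, nyquist = nyq,
                 L = L, N = N, l = l, m = l,
                 frequency = seq_len(l), individual_ids = ids),
            class = "spectral_decomp")
}

#' @export
print.spectral_decomp <- function(x, ...) {
  cat("Spectral decomposition:", x$N, "individuals, L =", x$L,
      "days,", x$l, "frequencies (f = 1 ..", x$l, "cycles/record)\n")
  cat("Time scales: ", round(x$L / x$l, 1), "to", x$L, "days\n")
  invisible(x)
}
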