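# Displacement panels and the skewness-minimising power transform.
#
# Daily displacement distances of tracked animals are strongly right-skewed;
# the spectral models downstream assume approximately symmetric marginal
# fluctuations, so the panel is analysed on the scale X = D^c with the
# exponent c chosen to minimise the summed absolute skewness across
# individuals.

#' Construct a displacement panel
#'
#' A displacement panel holds daily displacement distances (metres) for N
#' individuals over L consecutive days.  All individuals must share the same
#' contiguous date range; the spectral analysis requires continuous series.
#'
#' @param distances numeric matrix, N individuals (rows) x L days (columns),
#'   all values non-negative.
#' @param individual_ids character vector of length N; defaults to rownames
#'   or `ind1..indN`.
#' @param dates `Date` vector of length L giving the day each displacement
#'   was made (consecutive calendar days).
#' @return an object of class `displacement_panel`.
#' @export
displacement_panel <- function(distances, individual_ids = NULL, dates = NULL) {
  distances <- as.matrix(distances)
  if (!is.numeric(distances)) stop("distances must be numeric")
  if (anyNA(distances)) stop("distances contain NA; the analysis requires continuous series")
  if (any(distances < 0)) stop("distances must be non-negative")
  N <- nrow(distances)
  L <- ncol(distances)
  if (is.null(individual_ids)) {
    individual_ids <- rownames(distances)
    if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(N))
  }
  if (length(individual_ids) != N) stop("individual_ids must have one entry per row")
  if (is.null(dates)) dates <- as.Date("2006-02-03") + seq_len(L) - 1L
  dates <- as.Date(dates)
  if (length(dates) != L) stop("dates must have one entry per column")
  if (L > 1 && any(diff(dates) != 1)) stop("dates must be consecutive calendar days")
  dimnames(distances) <- list(individual_ids, as.character(dates))
  structure(list(distances = distances, individual_ids = individual_ids,
                 dates = dates),
            class = "displacement_panel")
}

#' @export
print.displacement_panel <- function(x, ...) {
  cat("Displacement panel:", nrow(x$distances), "individuals x",
      ncol(x$distances), "days\n")
  cat("Dates:", format(x$dates[1]), "to", format(x$dates[length(x$dates)]), "\n")
  cat("Mean daily displacement (m):",
      paste(sprintf("%s=%.1f", x$individual_ids, rowMeans(x$distances)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Daily displacements from relocation fixes
#'
#' Converts one-fix-per-day telemetry relocations in planar metric
#' coordinates (e.g. UTM) into a panel of daily displacement distances.  The
#' displacement on day t is the Euclidean distance between the fixes of days
#' t and t+1, so a record of d days yields L = d - 1 displacements.
#'
#' @param tracks data frame with columns `individual`, `date`, `easting`,
#'   `northing`.  Every individual must have exactly one fix per day over the
#'   same contiguous date range; missing or duplicated days are an error
#'   (the method requires continuous contemporaneous series).
#' @return a [displacement_panel()].
#' @export
compute_displacements <- function(tracks) {
  need <- c("individual", "date", "easting", "northing")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns: ", paste(need, collapse = ", "))
  tracks$date <- as.Date(tracks$date)
  tracks$individual <- as.character(tracks$individual)
  ids <- unique(tracks$individual)
  all_days <- seq(min(tracks$date), max(tracks$date), by = "day")
  xs <- matrix(NA_real_, length(ids), length(all_days))
  ys <- matrix(NA_real_, length(ids), length(all_days))
  for (i in seq_along(ids)) {
    sub <- tracks[tracks$individual == ids[i], , drop = FALSE]
    dup <- sub$date[duplicated(sub$date)]
    if (length(dup))
      stop(sprintf("duplicate fix for individual %s on %s", ids[i],
                   format(dup[1])))
    miss <- all_days[!all_days %in% sub$date]
    if (length(miss))
      stop(sprintf("missing fix for individual %s on %s", ids[i],
                   format(miss[1])))
    idx <- match(all_days, sub$date)
    xs[i, ] <- sub$easting[idx]
    ys[i, ] <- sub$northing[idx]
  }
  d <- ncol(xs)
  if (d < 2) stop("need at least two days of fixes")
  dist <- sqrt((xs[, -1, drop = FALSE] - xs[, -d, drop = FALSE])^2 +
               (ys[, -1, drop = FALSE] - ys[, -d, drop = FALSE])^2)
  displacement_panel(dist, individual_ids = ids, dates = all_days[-d])
}

#' Moment-based sample skewness
#'
#' The biased moment estimator g1 = m3 / m2^(3/2), where mk is the k-th
#' central sample moment with divisor n.  Scale-invariant: skewness(k*x) =
#' skewness(x) for k > 0.
#'
#' @param x numeric vector, length >= 3, non-zero variance.
#' @return the sample skewness (a single number).
#' @export
sample_skewness <- function(x) {
  if (length(x) < 3) stop("need at least 3 observations")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop("zero variance: skewness undefined")
  mean(xc^3) / m2^1.5
}

# Summed absolute skewness of the panel raised to exponent c.
transform_objective <- function(distances, c) {
  sum(abs(apply(distances^c, 1, sample_skewness)))
}

#' Skewness-minimising power transform
#'
#' Estimates the exponent c in X = D^c that minimises the summed absolute
#' sample skewness over individuals, then returns the transformed panel.
#' The exponent is restricted to (0, 1]: a grid of step `step` is scanned
#' and the best cell is refined by golden-section search (the objective can
#' be non-smooth because of the absolute values).
#'
#' @param panel a [displacement_panel()].
#' @param step grid resolution for the initial scan (default 0.01).
#' @param tol absolute tolerance of the golden-section refinement.
#' @return an object of class `transformed_panel` with elements `values`
#'   (the N x L matrix D^c), `exponent` (c), and `objective_value` (the
#'   summed absolute skewness at c).
#' @export
power_transform <- function(panel, step = 0.01, tol = 1e-6) {
  stopifnot(inherits(panel, "displacement_panel"))
  D <- panel$distances
  v <- apply(D, 1, stats::var)
  if (any(v == 0))
    stop("individual(s) with constant distances: ",
         paste(panel$individual_ids[v == 0], collapse = ", "))
  grid <- seq(step, 1, by = step)
  obj <- vapply(grid, function(c) transform_objective(D, c), numeric(1))
  i <- which.min(obj)
  lo <- max(step / 100, grid[i] - step)
  hi <- min(1, grid[i] + step)
  c_hat <- golden_section(function(c) transform_objective(D, c), lo, hi, tol)
  if (transform_objective(D, grid[i]) < transform_objective(D, c_hat))
    c_hat <- grid[i]
  structure(list(values = D^c_hat,
                 exponent = c_hat,
                 objective_value = transform_objective(D, c_hat),
                 individual_ids = panel$individual_ids,
                 dates = panel$dates),
            class = "transformed_panel")
}

golden_section <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

#' Build a transformed panel at a known exponent
#'
#' Used when the exponent is fixed externally (e.g. by the synthetic
#' generator) rather than estimated.
#'
#' @param values numeric N x L matrix on the transformed scale.
#' @param exponent the power-transform exponent c.
#' @param individual_ids,dates optional metadata.
#' @param objective_value optional; recomputed skewness objective if known.
#' @return a `transformed_panel`.
#' @export
transformed_panel <- function(values, exponent = 1, individual_ids = NULL,
                              dates = NULL, objective_value = NA_real_) {
  values <- as.matrix(values)
  N <- nrow(values); L <- ncol(values)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(N))
  if (is.null(dates)) dates <- as.Date("2006-02-03") + seq_len(L) - 1L
  structure(list(values = values, exponent = exponent,
                 objective_value = objective_value,
                 individual_ids = individual_ids, dates = as.Date(dates)),
            class = "transformed_panel")
}

#' @export
print.transformed_panel <- function(x, ...) {
  cat("Power-transformed displacement panel:", nrow(x$values),
      "individuals x", ncol(x$values), "days\n")
  cat(sprintf("Exponent c = %.4f; summed |skewness| = %s\n", x$exponent,
              format(x$objective_value)))
  invisible(x)
}
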