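#' Normalize an RR series by its record average
#'
#' Divides every interval by the grand mean of the record (the circadian
#' filtration level), yielding a dimensionless series with mean exactly 1.
#' All downstream geometry is invariant under a global rescaling of the raw
#' intervals, so units cancel here.
#'
#' @param rr an [rr_series], or a numeric vector of intervals.
#' @return An object of class `rr_normalized`: list with `x` (dimensionless
#'   series of length M), `global_mean` (seconds) and `M`.
#' @examples
#' nx <- normalize_global(rr_series(c(0.6, 0.9, 0.9, 1.2)))
#' nx$x  # 2/3, 1, 1, 4/3
#' @export
normalize_global <- function(rr) {
  rr <- as_rr_series(rr)
  xbar <- mean(rr$intervals)
  structure(list(x = rr$intervals / xbar, global_mean = xbar, M = rr$M),
            class = "rr_normalized")
}

#' @export
print.rr_normalized <- function(x, ...) {
  cat("Normalized RR series: ", x$M, " beats, record mean ",
      format(x$global_mean, digits = 4), " s\n", sep = "")
  invisible(x)
}

as_rr_normalized <- function(x) {
  if (inherits(x, "rr_normalized")) return(x)
  normalize_global(x)
}

check_order <- function(N, M) {
  if (length(N) != 1L || !is.finite(N) || N != round(N))
    stop("order N must be a single integer")
  if (N < 2) stop("order N must be >= 2, got ", N)
  if (N > M) stop("order N = ", N, " exceeds series length M = ", M)
  as.integer(N)
}

#' Forward moving averages of a normalized RR series
#'
#' The N-th order local filtration level: `avg[i]` is the mean of
#' `x[i..i+N-1]`, giving `M - N + 1` window averages.
#'
#' @param x an `rr_normalized` (or anything coercible to one).
#' @param N window order, an integer >= 2 and <= M.
#' @return Object of class `rr_moving_avg`: list with `avg` and `N`.
#' @export
moving_average <- function(x, N) {
  x <- as_rr_normalized(x)
  N <- check_order(N, x$M)
  # direct convolution: each window mean is a fresh N-term sum, so rounding
  # stays at N*eps per window instead of accumulating along the record as a
  # running-sum implementation would
  n_win <- x$M - N + 1L
  avg <- as.numeric(stats::filter(x$x, rep(1, N), sides = 1))[N:x$M] / N
  structure(list(avg = avg, N = N), class = "rr_moving_avg")
}

#' Distance-to-identity-line vector field
#'
#' For each of the `M - N + 1` forward windows, the vector of deviations of
#' the N consecutive normalized intervals from the window's moving average:
#' `Delta[i, k] = x[i + k] - avg[i]` (global normalization), or the same
#' divided elementwise by `avg[i]` (local normalization, the delta field).
#' Each row is the residual of the orthogonal projection of the window onto
#' the identity line `{1, ..., 1} t`, hence sums to zero (closure); the field
#' lives in the zero-sum hyperplane and its informative dimension is `N - 1`.
#'
#' Closure is checked after construction rather than enforced by
#' re-projection: the formula guarantees it analytically, and the assertion
#' catches implementation drift.
#'
#' @param x an `rr_normalized` (or coercible).
#' @param N window order (integer >= 2).
#' @param normalization `"global"` for the Delta field, `"local"` for delta.
#' @return Object of class `delta_field`: list with `vectors`
#'   ((M - N + 1) x N matrix), `N`, `normalization`, `M` and `avg`.
#' @examples
#' f <- delta_field(c(1, 1, 0.8, 1.2, 1), N = 5)
#' f$vectors  # single row (0, 0, -0.2, 0.2, 0)
#' @export
delta_field <- function(x, N, normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  x <- as_rr_normalized(x)
  ma <- moving_average(x, N)
  N <- ma$N
  n_win <- x$M - N + 1L
  # column k of the matrix holds x[i + k] for all window starts i
  vec <- matrix(0, nrow = n_win, ncol = N)
  for (k in 0:(N - 1L)) vec[, k + 1L] <- x$x[(1L + k):(n_win + k)] - ma$avg
  if (normalization == "local") vec <- vec / ma$avg
  worst <- max(abs(rowSums(vec)))
  if (worst > 1e-12 * max(1, max(abs(vec))) * N)
    stop("closure violated: a row of the field sums to ", worst)
  structure(list(vectors = vec, N = N, normalization = normalization,
                 M = x$M, avg = ma$avg),
            class = "delta_field")
}

#' @export
print.delta_field <- function(x, ...) {
  cat(if (x$normalization == "global") "Delta" else "delta",
      " field: order N = ", x$N, ", ", nrow(x$vectors),
      " windows from M = ", x$M, " beats\n", sep = "")
  invisible(x)
}

#' Truncate a field to its informative N - 1 components
#'
#' Drops the last component of every row. Because rows sum to zero, the
#' dropped component is recoverable as the negative sum of the kept ones;
#' the truncated rows are the coordinates used for the 3D + hue graph.
#'
#' @param field a [delta_field].
#' @return Numeric matrix with `N - 1` columns.
#' @export
truncate_for_graph <- function(field) {
  stopifnot(inherits(field, "delta_field"))
  field$vectors[, -field$N, drop = FALSE]
}
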