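#' Primary variability Phi_N
#'
#' Norm of the center of mass of the stride-N subset of the Delta field,
#' scaled to a percent-like magnitude. The full overlapping set of windows
#' over-compensates, because each interval appears as a component of N - 1
#' consecutive vectors; taking window starts in steps of N
#' (i = 1, 1 + N, 1 + 2N, ...) uses each interval exactly once, so the
#' surviving displacement of the center of mass measures genuine uncompensated
#' N-th order structure.
#'
#' @param field a [delta_field] with global normalization.
#' @param scale_factor multiplier applied to the norm (default 100, reporting
#'   on a percent-like scale).
#' @param truncated if `TRUE` use only the first N - 1 components of each
#'   vector; the default uses the full N-component Euclidean norm, which is
#'   well defined on the zero-sum hyperplane.
#' @return Object of class `primary_variability`: list with `phi`, `N`,
#'   `subset_size`, `M_used` and `scale_factor`.
#' @examples
#' rr <- rr_series(rep(0.8, 50))
#' primary_variability(delta_field(normalize_global(rr), 5))$phi  # 0
#' @export
primary_variability <- function(field, scale_factor = 100, truncated = FALSE) {
  stopifnot(inherits(field, "delta_field"))
  if (field$normalization != "global")
    stop("primary variability is defined on the globally normalized field")
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be a positive number")
  N <- field$N
  if (field$M < 2L * N)
    stop("series too short for a stride-", N, " subset: need M >= ", 2L * N,
         " beats, got ", field$M)
  idx <- seq.int(1L, nrow(field$vectors), by = N)
  vec <- field$vectors[idx, , drop = FALSE]
  if (truncated) vec <- vec[, -N, drop = FALSE]
  com <- colMeans(vec)
  structure(list(phi = scale_factor * sqrt(sum(com^2)), N = N,
                 subset_size = length(idx), M_used = field$M,
                 scale_factor = scale_factor),
            class = "primary_variability")
}

#' @export
print.primary_variability <- function(x, ...) {
  cat("Phi_", x$N, " = ", format(x$phi, digits = 6),
      "  (stride subset of ", x$subset_size, " windows, M = ", x$M_used,
      ")\n", sep = "")
  invisible(x)
}

#' Scan primary variability across window orders
#'
#' Computes Phi_N independently for each requested order on the same
#' (optionally length-capped) series. Healthy sinus rhythm typically shows a
#' minimum near N = 5, the cardiac/respiratory frequency ratio in humans.
#'
#' @param x an `rr_normalized`, [rr_series] or numeric vector.
#' @param orders integer vector of orders to evaluate (default 2:20).
#' @param M_cap if given, only the first `M_cap` beats are used; shorter
#'   records are used whole with a message.
#' @param scale_factor passed to [primary_variability].
#' @return A data frame of class `order_scan` with columns `order`, `phi`,
#'   `subset_size`, `M_used`; attribute `argmin_order` holds the order
#'   attaining the minimum phi (ties broken toward the smallest order).
#' @export
order_scan <- function(x, orders = 2:20, M_cap = NULL, scale_factor = 100) {
  x <- as_rr_normalized(x)
  if (!is.null(M_cap)) {
    if (M_cap < x$M) {
      x <- structure(list(x = x$x[seq_len(M_cap)] / mean(x$x[seq_len(M_cap)]),
                          global_mean = x$global_mean, M = as.integer(M_cap)),
                     class = "rr_normalized")
    } else if (M_cap > x$M) {
      message("record has only ", x$M, " beats (< M_cap = ", M_cap,
              "); using the whole record")
    }
  }
  orders <- as.integer(orders)
  keep <- orders >= 2L & 2L * orders <= x$M
  if (any(!keep))
    warning("skipping orders outside [2, M/2]: ",
            paste(orders[!keep], collapse = ", "))
  orders <- orders[keep]
  if (!length(orders)) stop("no valid orders to scan")
  rows <- lapply(orders, function(N) {
    pv <- primary_variability(delta_field(x, N), scale_factor = scale_factor)
    data.frame(order = N, phi = pv$phi, subset_size = pv$subset_size,
               M_used = pv$M_used)
  })
  out <- do.call(rbind, rows)
  attr(out, "argmin_order") <- out$order[which.min(out$phi)]
  attr(out, "scale_factor") <- scale_factor
  class(out) <- c("order_scan", "data.frame")
  out
}
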