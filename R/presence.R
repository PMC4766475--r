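#' Generalized angle between a window and an arrhythmic line
#'
#' Cosine of the angle between the truncated (first N - 1 components) window
#' deviation vector and the correspondingly truncated, renormalized line
#' direction. Orientation-sensitive: no absolute value is taken, so a line
#' and its negation score +1 and -1 respectively. Windows with truncated norm
#' at or below the quiescence threshold have no meaningful direction and
#' return `NA` (never matched).
#'
#' @param window numeric vector: either a truncated row (length N - 1) or a
#'   full row (length N) of a [delta_field].
#' @param line an [arrhythmia_line] of order N.
#' @param quiescence norm threshold below which the window is non-evaluable.
#' @return Cosine in [-1, 1], or `NA_real_` for a quiescent window.
#' @export
cos_theta <- function(window, line, quiescence = 1e-6) {
  stopifnot(inherits(line, "arrhythmia_line"))
  N <- line$N
  if (length(window) == N) window <- window[-N]
  if (length(window) != N - 1L)
    stop("window has ", length(window), " components; line of order ", N,
         " needs ", N - 1L, " (truncated) or ", N)
  d <- line$direction[-N]
  d <- d / sqrt(sum(d^2))
  wn <- sqrt(sum(window^2))
  if (wn <= quiescence) return(NA_real_)
  sum(window * d) / wn
}

# Vectorized matching of all windows of a truncated field against one or more
# truncated unit directions. Returns the greedy, left-to-right match set:
# after a match at window i, windows i+1..i+N-1 are ineligible (an isolated
# event smears across N - 1 overlapping windows; suppression makes m count
# events, which the (N - 1) factor in the presence formula then converts to
# beat coverage).
match_windows <- function(trunc, dirs, tol_cos, suppress, N,
                          quiescence = 1e-6, amplitude_min = 0) {
  wn <- sqrt(rowSums(trunc^2))
  evaluable <- wn > quiescence
  best_cos <- rep(-Inf, nrow(trunc))
  best_amp <- numeric(nrow(trunc))
  for (d in dirs) {
    proj <- as.numeric(trunc %*% d)          # amplitude t along the line
    cth <- ifelse(evaluable, proj / wn, NA_real_)
    upd <- evaluable & cth > best_cos
    best_cos[upd] <- cth[upd]
    best_amp[upd] <- proj[upd]
  }
  cand <- which(evaluable & best_cos >= tol_cos &
                  abs(best_amp) >= amplitude_min)
  if (suppress && length(cand)) {
    kept <- integer(0)
    last <- -Inf
    for (i in cand) {
      if (i > last + N - 1L) {
        kept <- c(kept, i)
        last <- i
      }
    }
    cand <- kept
  }
  data.frame(window = cand, cos_theta = best_cos[cand],
             amplitude = best_amp[cand], window_norm = wn[cand])
}

#' Presence of an arrhythmic line in a record
#'
#' Scans every window of the field, counts the number m of windows whose
#' generalized angle to the line is within tolerance, and reports the
#' percentage of presence `100 * m * (N - 1) / (M - N)` — the fraction of the
#' record's beats covered by matching windows.
#'
#' @param field a [delta_field].
#' @param line an [arrhythmia_line] whose order equals the field's, or a list
#'   of same-order lines treated as one detector (a window matching any member
#'   counts once; used for fragment-based B2).
#' @param tolerance_cos cosine threshold; a window matches when
#'   `cos(theta) >= tolerance_cos`. Default 0.98.
#' @param suppress_overlap after a match at window i, skip windows
#'   i+1..i+N-1 for this line so m counts events rather than overlapping
#'   views of one event (default `TRUE`; `FALSE` gives the literal
#'   every-window count).
#' @param amplitude_min optional floor on the matched amplitude |t| (default
#'   0 = off).
#' @param quiescence norm threshold for non-evaluable windows.
#' @return Object of class `presence_result`: list with `line_name`, `m`,
#'   `presence_percent`, `tolerance` (radians), `tolerance_cos`, `M`, `N`
#'   and `matches` (data frame: window, cos_theta, amplitude, window_norm;
#'   window indices are 1-based beat positions of the window start).
#' @examples
#' rr <- c(rep(0.8, 40), 0.64, 0.96, rep(0.8, 40))
#' f <- delta_field(normalize_global(rr_series(rr)), 5)
#' presence(f, make_b1(5))$m  # 1
#' @export
presence <- function(field, line, tolerance_cos = 0.98,
                     suppress_overlap = TRUE, amplitude_min = 0,
                     quiescence = 1e-6) {
  stopifnot(inherits(field, "delta_field"))
  lines <- if (inherits(line, "arrhythmia_line")) list(line) else line
  stopifnot(length(lines) >= 1L,
            all(vapply(lines, inherits, TRUE, "arrhythmia_line")))
  N <- field$N
  for (ln in lines)
    if (ln$N != N)
      stop("line ", ln$name, " has order ", ln$N, " but the field has order ",
           N, "; rebuild the field at the line's native order")
  if (tolerance_cos <= -1 || tolerance_cos >= 1)
    stop("tolerance_cos must be in (-1, 1)")
  trunc <- truncate_for_graph(field)
  dirs <- lapply(lines, function(ln) {
    d <- ln$direction[-N]
    d / sqrt(sum(d^2))
  })
  matches <- match_windows(trunc, dirs, tolerance_cos, suppress_overlap, N,
                           quiescence = quiescence,
                           amplitude_min = amplitude_min)
  m <- nrow(matches)
  nm <- paste(vapply(lines, `[[`, "", "name"), collapse = "|")
  structure(list(line_name = nm, m = m,
                 presence_percent = 100 * m * (N - 1) / (field$M - N),
                 tolerance = acos(tolerance_cos),
                 tolerance_cos = tolerance_cos,
                 M = field$M, N = N, matches = matches),
            class = "presence_result")
}

#' @export
print.presence_result <- function(x, ...) {
  cat("Presence of ", x$line_name, ": ", x$m, " matches, ",
      format(x$presence_percent, digits = 5), "% of beats (N = ", x$N,
      ", M = ", x$M, ", cos tol = ", x$tolerance_cos, ")\n", sep = "")
  invisible(x)
}

#' Per-record arrhythmic signature
#'
#' Computes the presence of every default-catalog line plus the primary
#' variability Phi_N for one record. B2 is evaluated at its native order
#' (a second field of order N + 1 is built from the same record) unless
#' `b2_order = "fragments"` selects the order-N fragment detector; presences
#' from different orders are reported side by side without rescaling.
#'
#' @param rr an [rr_series] (or numeric vector of intervals).
#' @param N base window order (default 5).
#' @param tolerance_cos cosine tolerance for matching (default 0.98).
#' @param M_cap if given, only the first `M_cap` beats are analyzed
#'   (e.g. 4200 for standardized comparisons across records).
#' @param b2_order `"native6"` or `"fragments"`; see [default_catalog].
#' @param scale_factor scale for Phi (default 100).
#' @param suppress_overlap passed to [presence].
#' @return Object of class `signature_vector`: list with `presences` (named
#'   numeric: A1+, A1-, A2+, A2-, B1, B2), `phi`, `N`, `M_used`, `config`
#'   and `details` (per-line presence_result objects).
#' @export
signature <- function(rr, N = 5, tolerance_cos = 0.98, M_cap = NULL,
                      b2_order = c("native6", "fragments"),
                      scale_factor = 100, suppress_overlap = TRUE) {
  b2_order <- match.arg(b2_order)
  rr <- as_rr_series(rr)
  if (!is.null(M_cap) && M_cap < rr$M)
    rr <- rr_series(rr$intervals[seq_len(M_cap)], unit = "seconds",
                    source_id = rr$source_id)
  need <- if (b2_order == "native6") 2L * (N + 1L) else 2L * N
  if (rr$M < need)
    stop("record too short for a signature: need at least ", need,
         " beats, got ", rr$M)
  x <- normalize_global(rr)
  field <- delta_field(x, N)
  cat_lines <- default_catalog(N, b2_order = b2_order)
  details <- list()
  for (nm in setdiff(names(cat_lines), "B2"))
    details[[nm]] <- presence(field, cat_lines[[nm]],
                              tolerance_cos = tolerance_cos,
                              suppress_overlap = suppress_overlap)
  b2_field <- if (b2_order == "native6") delta_field(x, N + 1L) else field
  details[["B2"]] <- presence(b2_field, cat_lines[["B2"]],
                              tolerance_cos = tolerance_cos,
                              suppress_overlap = suppress_overlap)
  presences <- vapply(details, `[[`, 0, "presence_percent")
  pv <- primary_variability(field, scale_factor = scale_factor)
  structure(list(presences = presences, phi = pv$phi, N = N, M_used = rr$M,
                 config = list(tolerance_cos = tolerance_cos,
                               M_cap = M_cap, b2_order = b2_order,
                               scale_factor = scale_factor,
                               suppress_overlap = suppress_overlap),
                 details = details),
            class = "signature_vector")
}

#' @export
print.signature_vector <- function(x, ...) {
  cat("Arrhythmic signature (N = ", x$N, ", M = ", x$M_used, "):\n", sep = "")
  for (nm in names(x$presences))
    cat(sprintf("  %-4s %9.5f %%\n", nm, x$presences[[nm]]))
  cat(sprintf("  Phi_%d %8.5f\n", x$N, x$phi))
  invisible(x)
}

#' Signature-space coordinates
#'
#' The 3-coordinate point (A1+ presence, B1 presence, Phi) used for cohort
#' scatter plots: A1+ and B1 are the antagonistic healthy/pathological axes,
#' and Phi separates conditions of similar B1 load.
#'
#' @param sig a `signature_vector`.
#' @return Named numeric vector `c(a1_plus, b1, phi)`.
#' @export
signature_space_point <- function(sig) {
  stopifnot(inherits(sig, "signature_vector"))
  c(a1_plus = unname(sig$presences[["A1+"]]),
    b1 = unname(sig$presences[["B1"]]),
    phi = sig$phi)
}
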