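#' Arrhythmic line directions
#'
#' Every universal arrhythmic sequence is represented as a ray through the
#' origin of the order-N variability field: a unit direction vector `d` such
#' that windows realizing the sequence sit on `d * t` for some amplitude
#' `t > 0`. A line is *compensated* when its components sum to zero (the
#' event's deviations cancel over the window) and *terminated* when its last
#' component is zero (the final beat already matches the local moving
#' average). Matching is orientation-sensitive: a line and its negation are
#' distinct physiological events.
#'
#' @param name line label, e.g. `"A1+"`, `"B1"`, `"B2"`, `"B3_4_2"`.
#' @param direction numeric vector; normalized to unit Euclidean norm.
#' @param compensated logical, components sum to zero.
#' @param terminated logical, last component is zero.
#' @param family_index,position_index optional integers identifying the member
#'   within a generalized family.
#' @return Object of class `arrhythmia_line` with fields `name`, `N`,
#'   `direction`, `compensated`, `terminated`, `family_index`,
#'   `position_index`.
#' @export
arrhythmia_line <- function(name, direction, compensated = FALSE,
                            terminated = FALSE, family_index = NA_integer_,
                            position_index = NA_integer_) {
  direction <- as.numeric(direction)
  if (length(direction) < 2L) stop("a line direction needs at least 2 components")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction vector for line ", name)
  direction <- direction / nrm
  if (compensated && abs(sum(direction)) > 1e-12)
    stop("line ", name, " declared compensated but components sum to ",
         sum(direction))
  if (terminated && abs(direction[length(direction)]) > 1e-12)
    stop("line ", name, " declared terminated but last component is nonzero")
  structure(list(name = name, N = length(direction), direction = direction,
                 compensated = compensated, terminated = terminated,
                 family_index = family_index, position_index = position_index),
            class = "arrhythmia_line")
}

#' @export
print.arrhythmia_line <- function(x, ...) {
  cat(x$name, " (order ", x$N, "): (",
      paste(format(x$direction, digits = 4), collapse = ", "), ")",
      if (x$compensated) " compensated", if (x$terminated) " terminated",
      "\n", sep = "")
  invisible(x)
}

#' Linear-ramp line A1
#'
#' The simplest form of variability: a steady acceleration or deceleration of
#' the beat rate across the window, i.e. a zero-mean arithmetic ramp of the RR
#' deviations. `A1+` is the accelerating form (intervals shrinking: components
#' run from positive to negative); `A1-` is its negation (decelerating). This
#' is the dominant pattern in healthy sinus rhythm — the basic adaptability
#' degree of freedom.
#'
#' @param N window order (>= 2).
#' @param sign `"+"` (accelerating) or `"-"` (decelerating).
#' @return An [arrhythmia_line]; for N = 5, `A1+` is proportional to
#'   (2, 1, 0, -1, -2).
#' @export
make_a1 <- function(N, sign = c("+", "-")) {
  sign <- match.arg(sign)
  if (N < 2) stop("A1 requires N >= 2")
  ramp <- (N - 1) / 2 - (0:(N - 1))       # zero-mean, decreasing
  if (sign == "-") ramp <- -ramp
  arrhythmia_line(paste0("A1", sign), ramp, compensated = TRUE)
}

#' Respiratory sinusoid line A2
#'
#' A full-period sinusoidal modulation of the beat rate over the window,
#' the signature of cardiac-respiratory tuning (most common at N = 5, the
#' typical heartbeat/breath frequency ratio). A full period sums to zero for
#' any phase, so the line is compensated.
#'
#' @param N window order (>= 3; a sinusoid over fewer points degenerates).
#' @param sign `"+"` or `"-"` (the negated phase).
#' @param phase phase offset in radians added to the sampled sine (default 0).
#' @return An [arrhythmia_line] proportional to `sin(2*pi*k/N + phase)`,
#'   k = 0..N-1.
#' @export
make_a2 <- function(N, sign = c("+", "-"), phase = 0) {
  sign <- match.arg(sign)
  if (N < 3) stop("A2 requires N >= 3")
  s <- sin(2 * pi * (0:(N - 1)) / N + phase)
  s <- s - mean(s)  # exact zero-sum against floating-point residue
  if (sign == "-") s <- -s
  arrhythmia_line(paste0("A2", sign), s, compensated = TRUE)
}

#' Compensated ectopic-beat line B1
#'
#' A premature beat immediately followed by a compensatory pause: -1 then +1
#' at consecutive positions, zeros elsewhere. The canonical member (the one
#' with clear ubiquity in heart-failure records) places the pair at the
#' interior positions (N - 3, N - 2) in 0-based terms — (2, 3) for N = 5 —
#' so the window is terminated. The `"edge"` variant is the wrap-around
#' pattern (+1 first, -1 last) which does not clearly appear in real records
#' and is excluded from the default signature.
#'
#' @param N window order (>= 3).
#' @param position 0-based index of the premature beat, `0 <= position <= N-3`;
#'   default is the canonical interior position `N - 3`.
#' @param variant `"pair"` (default) or `"edge"`.
#' @return An [arrhythmia_line]; for N = 5 the canonical B1 is proportional to
#'   (0, 0, -1, 1, 0).
#' @export
make_b1 <- function(N, position = NULL, variant = c("pair", "edge")) {
  variant <- match.arg(variant)
  if (N < 3) stop("B1 requires N >= 3")
  d <- numeric(N)
  if (variant == "edge") {
    d[1L] <- 1; d[N] <- -1
    return(arrhythmia_line("B1_edge", d, compensated = TRUE,
                           position_index = 0L))
  }
  if (is.null(position)) position <- N - 3L
  if (position < 0 || position > N - 3L)
    stop("B1 position must be in [0, ", N - 3L, "], got ", position)
  d[position + 1L] <- -1
  d[position + 2L] <- 1
  nm <- if (position == N - 3L) "B1" else paste0("B1_p", position)
  arrhythmia_line(nm, d, compensated = TRUE,
                  terminated = (position + 1L) < (N - 1L),
                  position_index = as.integer(position))
}

#' Pause-tachycardia line family B2
#'
#' A noticeable pause followed by a proportional run of m faster beats that
#' exactly compensate it, then a terminating beat back on the local average:
#' direction proportional to (m, -1, ..., -1, 0) at order m + 2. The
#' canonical member is m = 4, a sixth-order structure, called simply B2.
#'
#' @param m run length (>= 2).
#' @return An [arrhythmia_line] of order `m + 2`.
#' @export
make_b2_family <- function(m) {
  if (m < 2) stop("B2 family requires m >= 2")
  d <- c(m, rep(-1, m), 0)
  nm <- if (m == 4) "B2" else paste0("B2_m", m)
  arrhythmia_line(nm, d, compensated = TRUE, terminated = TRUE,
                  family_index = as.integer(m))
}

#' @rdname make_b2_family
#' @param N window order for [make_b2] (default 6, the canonical compensated
#'   form; the family member with `m = N - 2`).
#' @export
make_b2 <- function(N = 6) {
  if (N < 4) stop("B2 requires order N >= 4")
  make_b2_family(N - 2L)
}

#' Fifth-order fragments of the B2 event
#'
#' An order-6 pause-plus-run event scanned by order-5 windows produces two
#' off-phase directions: the pause-leading window, proportional to
#' (4, -1, -1, -1, -1), and the run-trailing window, proportional to
#' (-1, -1, -1, -1, 4). As raw beat sequences neither fragment is
#' compensated (the underlying event completes only at order 6), so both are
#' flagged uncompensated even though their field directions, like every
#' window deviation vector, sum to zero.
#'
#' @param i fragment index, 1 (pause-leading) or 2 (run-trailing).
#' @return An [arrhythmia_line] of order 5.
#' @export
make_b2_fragment <- function(i) {
  if (!i %in% 1:2) stop("B2 fragment index must be 1 or 2")
  d <- if (i == 1) c(4, -1, -1, -1, -1) else c(-1, -1, -1, -1, 4)
  arrhythmia_line(paste0("B2_", i), d, compensated = FALSE,
                  family_index = 4L, position_index = as.integer(i))
}

#' Displaced pause-tachycardia line B3
#'
#' A variant of the B2 family in which the pause sits at an interior position
#' of the compensating run instead of leading it: at order m + 2 the direction
#' has +m at position i, -1 at the other m run positions, and a terminating 0.
#' It joins two consecutive paroxysmal-tachycardia runs with a relative pause
#' in between.
#'
#' @param m run length (>= 2); the line has order `m + 2`.
#' @param i 0-based interior pause position, `1 <= i <= m` (i = 0 is B2
#'   itself).
#' @return An [arrhythmia_line] of order `m + 2`.
#' @export
make_b3 <- function(m, i) {
  if (m < 2) stop("B3 requires m >= 2")
  if (i < 1 || i > m)
    stop("B3 pause position i must be in [1, ", m, "], got ", i)
  d <- c(rep(-1, m + 1), 0)
  d[i + 1L] <- m
  arrhythmia_line(paste0("B3_", m, "_", i), d, compensated = TRUE,
                  terminated = TRUE, family_index = as.integer(m),
                  position_index = as.integer(i))
}

#' Shadow lines of the B2 family
#'
#' When a pause-plus-run B2 event is scanned by windows offset by i beats
#' from its onset, the partial view lands on a complementary step-shaped
#' direction: (m - i + 1) components equal to -(i + 1) followed by (i + 1)
#' components equal to (m - i + 1), at order m + 2. These faint companions
#' appear alongside B2 in heart-failure graphs; they are catalogued for
#' overlay and exploration but excluded from the default signature, since
#' their quantitative behavior is not yet characterized.
#'
#' @param m run length of the parent B2 event (>= 2).
#' @param i window offset, `1 <= i <= m`.
#' @return An [arrhythmia_line] of order `m + 2`.
#' @export
make_shadow <- function(m, i) {
  if (m < 2) stop("shadow requires m >= 2")
  if (i < 1 || i > m)
    stop("shadow offset i must be in [1, ", m, "], got ", i)
  d <- c(rep(-(i + 1), m - i + 1), rep(m - i + 1, i + 1))
  arrhythmia_line(paste0("SHADOW_", m, "_", i), d, compensated = TRUE,
                  family_index = as.integer(m), position_index = as.integer(i))
}

#' Default line catalog
#'
#' The six named lines of the per-record signature, in fixed report order:
#' A1+, A1-, A2+, A2-, B1 (canonical interior position) and B2. B2 is built
#' at its native order `m + 2 = 6` when `N = 5` (flagged cross-order); for
#' other N it is the family member of order N + 1.
#'
#' @param N base window order (default 5).
#' @param b2_order `"native6"` (default; B2 at order N + 1, the compensated
#'   form) or `"fragments"` (the two order-N fragment lines).
#' @return Named list of [arrhythmia_line] objects.
#' @export
default_catalog <- function(N = 5, b2_order = c("native6", "fragments")) {
  b2_order <- match.arg(b2_order)
  lines <- list(
    "A1+" = make_a1(N, "+"),
    "A1-" = make_a1(N, "-"),
    "A2+" = make_a2(N, "+"),
    "A2-" = make_a2(N, "-"),
    "B1"  = make_b1(N)
  )
  if (b2_order == "native6") {
    lines[["B2"]] <- make_b2(N + 1L)
  } else {
    if (N != 5)
      stop("fragment-based B2 is defined for N = 5 only")
    lines[["B2"]] <- list(make_b2_fragment(1), make_b2_fragment(2))
  }
  lines
}

#' Export / import a line catalog as JSON
#'
#' Serializes name, order, direction and flags so alternative transcriptions
#' of the line equations can be loaded without code change.
#'
#' @param lines list of [arrhythmia_line] objects (members may themselves be
#'   lists of lines, as for fragment-based B2).
#' @param path file to write / read.
#' @return `catalog_to_json` returns `path` invisibly; `catalog_from_json`
#'   returns a named list of [arrhythmia_line].
#' @export
catalog_to_json <- function(lines, path) {
  flat <- list()
  for (nm in names(lines)) {
    entry <- lines[[nm]]
    members <- if (inherits(entry, "arrhythmia_line")) list(entry) else entry
    for (ln in members) {
      flat[[length(flat) + 1L]] <- list(
        name = ln$name, order = ln$N, direction = ln$direction,
        compensated = ln$compensated, terminated = ln$terminated,
        family_index = ln$family_index, position_index = ln$position_index,
        catalog_key = nm)
    }
  }
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname catalog_to_json
#' @export
catalog_from_json <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  out <- list()
  for (e in flat) {
    ln <- arrhythmia_line(e$name, unlist(e$direction),
                          compensated = isTRUE(e$compensated),
                          terminated = isTRUE(e$terminated),
                          family_index = if (is.null(e$family_index))
                            NA_integer_ else as.integer(e$family_index),
                          position_index = if (is.null(e$position_index))
                            NA_integer_ else as.integer(e$position_index))
    key <- e$catalog_key
    if (is.null(out[[key]])) {
      out[[key]] <- ln
    } else if (inherits(out[[key]], "arrhythmia_line")) {
      out[[key]] <- list(out[[key]], ln)
    } else {
      out[[key]] <- c(out[[key]], list(ln))
    }
  }
  out
}
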