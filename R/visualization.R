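#' Graph projection for the 3D + hue variability plot
#'
#' An order-5 field has four informative components per window; the graph
#' shows the first three (after a rigid rotation) as spatial coordinates and
#' maps the fourth to a 0-1 hue. The hue scaling clips the fourth component
#' to a symmetric range (default +/- its maximum absolute value) and maps it
#' affinely to [0, 1].
#'
#' @param rotation 3x3 rotation matrix applied to the first three truncated
#'   components (default identity); must be orthonormal with determinant +1.
#' @param hue_component 1-based index of the truncated component mapped to
#'   hue (default 4).
#' @param hue_range length-2 numeric `(lo, hi)` mapped to hue 0-1, or `NULL`
#'   to use the symmetric data range.
#' @return Object of class `graph_projection`.
#' @export
graph_projection <- function(rotation = diag(3), hue_component = 4L,
                             hue_range = NULL) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (a reflection); use a proper rotation")
  structure(list(rotation = rotation, hue_component = as.integer(hue_component),
                 hue_range = hue_range),
            class = "graph_projection")
}

#' Rotation from three Euler angles
#'
#' Composition of rotations about the z, y and x axes (in that order), the
#' parametrization exposed on the command line as `--rotation a,b,c`.
#'
#' @param a,b,c angles in radians about z, y, x.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(a, b, c) {
  rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
               byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3,
               byrow = TRUE)
  rx %*% ry %*% rz
}

#' View rotation separating the B1 line family
#'
#' Heart-failure graphs are dominated by the three interior ectopic-pair
#' lines of the order-5 field. This constructs a deterministic rotation that
#' maps their three spatial directions (the first three truncated components
#' of each line) as closely as possible onto three directions 120 degrees
#' apart in the viewing (x, y) plane, by solving the orthogonal Procrustes
#' problem and forcing determinant +1. Under this view the family opens into
#' three maximally separated chords instead of overlapping projections.
#'
#' @return A [graph_projection] carrying the constructed rotation.
#' @export
hf_view_projection <- function() {
  v <- vapply(0:2, function(i) {
    d <- make_b1(5, position = i)$direction[1:3]
    d / sqrt(sum(d^2))
  }, numeric(3))                    # 3 x 3, columns are spatial directions
  ang <- pi / 2 + c(0, 2, 4) * pi / 3
  targ <- rbind(cos(ang), sin(ang), 0)
  s <- svd(targ %*% t(v))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    r <- u %*% t(s$v)
  }
  graph_projection(rotation = r)
}

#' Point cloud of the 4D variability graph
#'
#' Rotated spatial coordinates plus hue for every window of an order-5 field.
#'
#' @param field a [delta_field] of order 5.
#' @param projection a [graph_projection].
#' @param drop_quiescent drop windows with truncated norm below `quiescence`.
#' @param quiescence norm threshold (default 1e-6).
#' @return Data frame with columns `x`, `y`, `z`, `hue` (in [0, 1]) and
#'   `window` (1-based window start).
#' @export
delta_graph_points <- function(field, projection = graph_projection(),
                               drop_quiescent = FALSE, quiescence = 1e-6) {
  stopifnot(inherits(field, "delta_field"),
            inherits(projection, "graph_projection"))
  if (field$N != 5)
    stop("the 3D + hue graph needs an order-5 field (got N = ", field$N,
         "); for other orders plot pairwise components directly")
  tr <- truncate_for_graph(field)
  idx <- seq_len(nrow(tr))
  if (drop_quiescent) idx <- idx[sqrt(rowSums(tr^2)) > quiescence]
  xyz <- tr[idx, 1:3, drop = FALSE] %*% t(projection$rotation)
  h4 <- tr[idx, projection$hue_component]
  rng <- projection$hue_range
  if (is.null(rng)) {
    mx <- max(abs(h4), 1e-15)
    rng <- c(-mx, mx)
  }
  hue <- pmin(pmax((h4 - rng[1]) / (rng[2] - rng[1]), 0), 1)
  data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], hue = hue,
             window = idx)
}

#' Render the 4D variability graph
#'
#' 3D scatter (lattice cloud) of the rotated first three truncated components,
#' colored by the hue-mapped fourth; catalog lines can be overlaid as chords
#' through the origin. The input field is not modified.
#'
#' @param field a [delta_field] of order 5.
#' @param projection a [graph_projection] (default [hf_view_projection()]).
#' @param out_path output PNG path.
#' @param overlay optional list of [arrhythmia_line] of order 5 drawn as
#'   segments through the origin.
#' @param drop_quiescent see [delta_graph_points].
#' @param width,height image size in pixels.
#' @return `out_path`, invisibly.
#' @export
plot_delta_graph <- function(field, projection = hf_view_projection(),
                             out_path, overlay = NULL,
                             drop_quiescent = FALSE,
                             width = 900, height = 900) {
  pts <- delta_graph_points(field, projection, drop_quiescent = drop_quiescent)
  cols <- grDevices::hsv(h = pts$hue, s = 0.9, v = 0.85)
  if (!is.null(overlay)) {
    # render each catalog line as a dense chord of black points through the
    # origin, in the same rotated frame as the data
    ext <- max(sqrt(pts$x^2 + pts$y^2 + pts$z^2), 0.05)
    t_samp <- seq(-ext, ext, length.out = 80)
    for (ln in overlay) {
      d3 <- ln$direction[1:3]
      d3 <- d3 / max(sqrt(sum(d3^2)), 1e-15)
      d3 <- as.numeric(projection$rotation %*% d3)
      chord <- data.frame(x = d3[1] * t_samp, y = d3[2] * t_samp,
                          z = d3[3] * t_samp, hue = 0, window = NA)
      pts <- rbind(pts, chord)
      cols <- c(cols, rep("black", length(t_samp)))
    }
  }
  grDevices::png(out_path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  p <- lattice::cloud(z ~ x * y, data = pts, col = cols, pch = 16, cex = 0.35,
                      main = "Order-5 variability graph (hue = 4th component)")
  print(p)
  invisible(out_path)
}

#' Signature-space scatter
#'
#' The cohort view of (A1+ presence, B1 presence, Phi): a 2D scatter of the
#' two antagonistic presences (percent units) with point size encoding Phi
#' and color encoding the group label.
#'
#' @param points data frame with columns `a1_plus`, `b1`, `phi` and `group`
#'   (rows typically from [signature_space_point]).
#' @param out_path output PNG path.
#' @param width,height image size in pixels.
#' @return `out_path`, invisibly.
#' @export
plot_signature_space <- function(points, out_path, width = 900, height = 700) {
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("a1_plus", "b1", "phi", "group") %in% names(points)))
  g <- ggplot2::ggplot(points, ggplot2::aes(
    x = .data$a1_plus, y = .data$b1,
    color = .data$group, size = .data$phi)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "A1+ presence (%)", y = "B1 presence (%)",
                  size = "Phi", color = "group") +
    ggplot2::theme_minimal()
  grDevices::png(out_path, width = width, height = height, res = 110,
                 type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  print(g)
  invisible(out_path)
}
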