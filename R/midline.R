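# Airway midline and measurement grid.

# do segments (p1,p2) and (p3,p4) properly intersect?
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polyline_self_intersects <- function(poly) {
  n <- nrow(poly) - 1L
  if (n < 3) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (segments_intersect(poly[i, ], poly[i + 1L, ],
                             poly[j, ], poly[j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

resample_polyline <- function(poly, step_mm) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  len <- arc[length(arc)]
  s_new <- seq(0, len, by = step_mm)
  if (s_new[length(s_new)] < len - 1e-9) s_new <- c(s_new, len)
  cbind(
    stats::approx(arc, poly[, 1], s_new)$y,
    stats::approx(arc, poly[, 2], s_new)$y
  )
}

#' Define the airway midline
#'
#' Takes a user-drawn polyline through the open vocal tract (lips to
#' larynx, mm coordinates) together with the three anatomical landmarks,
#' validates it, and resamples it to uniform arc-length vertices. When a
#' `vt_phantom` is supplied instead, its ground-truth midline and
#' landmarks are used.
#'
#' @param polyline An n x 2 matrix of mm coordinates (lips first), or NULL
#'   if `phantom` is given.
#' @param landmarks A list with `upper_lip`, `hard_palate_back`, `larynx`
#'   (each an xy pair in mm), or NULL if `phantom` is given.
#' @param phantom Optional `vt_phantom` supplying both.
#' @param step_mm Resampling step (default 1 mm).
#' @return An object of class `vt_midline`: uniformly resampled `vertices`,
#'   total `arc_length_mm`, and `landmarks`.
#' @export
define_midline <- function(polyline = NULL, landmarks = NULL,
                           phantom = NULL, step_mm = 1) {
  if (!is.null(phantom)) {
    stopifnot(inherits(phantom, "vt_phantom"))
    polyline <- phantom$midline
    landmarks <- phantom$landmarks
  }
  stopifnot(is.matrix(polyline), ncol(polyline) == 2, nrow(polyline) >= 2,
            all(is.finite(polyline)), is.list(landmarks))
  needed <- c("upper_lip", "hard_palate_back", "larynx")
  if (!all(needed %in% names(landmarks))) {
    stop("landmarks must contain upper_lip, hard_palate_back and larynx",
         call. = FALSE)
  }
  if (polyline_self_intersects(polyline)) {
    stop("midline polyline is self-intersecting", call. = FALSE)
  }
  vertices <- resample_polyline(polyline, step_mm)
  arc_len <- sum(sqrt(rowSums(diff(vertices)^2)))
  structure(
    list(vertices = vertices, arc_length_mm = arc_len,
         landmarks = landmarks, step_mm = step_mm),
    class = "vt_midline"
  )
}

#' @export
print.vt_midline <- function(x, ...) {
  cat(sprintf("vt_midline: %.1f mm arc length, %d vertices\n",
              x$arc_length_mm, nrow(x$vertices)))
  invisible(x)
}

#' Construct the measurement grid
#'
#' Places gridlines orthogonal to the midline at regular arc-length
#' intervals, centered on it. Gridline 1 sits at the lips (arc position
#' 0); the count is `floor(arc_length / spacing) + 1`. Each gridline
#' carries an origin on the midline and a unit normal; signed positions
#' along a gridline are measured from the origin, positive toward the
#' upper (superior/posterior) boundary.
#'
#' @param midline A `vt_midline`.
#' @param spacing_mm Arc-length spacing between gridlines (default 2 mm).
#' @param half_length_mm Half-length of each gridline (default 20 mm).
#' @return An object of class `vt_grid`: `origins` and `normals`
#'   (n x 2 matrices), `s` (arc positions), `spacing_mm`,
#'   `half_length_mm`, and the arc positions of the projected hard-palate
#'   and larynx landmarks (`s_palate`, `s_larynx`).
#' @export
construct_grid <- function(midline, spacing_mm = 2, half_length_mm = 20) {
  stopifnot(inherits(midline, "vt_midline"),
            spacing_mm > 0, half_length_mm > 0)
  len <- midline$arc_length_mm
  if (spacing_mm > len) {
    warning("spacing exceeds midline arc length; single gridline returned")
  }
  s <- seq(0, len, by = spacing_mm)
  v <- midline$vertices
  arc <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  ox <- stats::approx(arc, v[, 1], s)$y
  oy <- stats::approx(arc, v[, 2], s)$y
  # tangents by central differences on the resampled vertices
  tx <- c(diff(v[1:2, 1]), (v[-(1:2), 1] - v[1:(nrow(v) - 2), 1]) / 2,
          diff(v[(nrow(v) - 1):nrow(v), 1]))
  ty <- c(diff(v[1:2, 2]), (v[-(1:2), 2] - v[1:(nrow(v) - 2), 2]) / 2,
          diff(v[(nrow(v) - 1):nrow(v), 2]))
  tnorm <- sqrt(tx^2 + ty^2)
  tx <- tx / tnorm; ty <- ty / tnorm
  gx <- stats::approx(arc, tx, s)$y
  gy <- stats::approx(arc, ty, s)$y
  gn <- sqrt(gx^2 + gy^2)
  gx <- gx / gn; gy <- gy / gn
  normals <- cbind(gy, -gx)  # rotate tangent: points "up" for lips->larynx
  proj_s <- function(p) {
    pr <- project_points_polyline(p[1], p[2], v, arc)
    pr$s
  }
  structure(
    list(origins = cbind(ox, oy), normals = unname(normals),
         tangents = cbind(gx, gy), s = s,
         spacing_mm = spacing_mm, half_length_mm = half_length_mm,
         s_palate = proj_s(midline$landmarks$hard_palate_back),
         s_larynx = proj_s(midline$landmarks$larynx),
         arc_length_mm = len),
    class = "vt_grid"
  )
}

#' @export
print.vt_grid <- function(x, ...) {
  cat(sprintf("vt_grid: %d gridlines, %.1f mm spacing, +/- %.1f mm\n",
              nrow(x$origins), x$spacing_mm, x$half_length_mm))
  invisible(x)
}
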