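# Synthetic midsagittal vocal-tract phantom.
#
# Coordinate convention (documented in every exported object): x in mm
# increases rightward (anterior -> posterior), y in mm increases downward
# (superior -> inferior), matching image rows. Pixel (row r, col c) has its
# center at x = (c - 0.5) * pixel_size_mm, y = (r - 0.5) * pixel_size_mm.
#
# The airway is a tube around an L-shaped midline (horizontal oral cavity,
# quarter-circle bend, vertical pharynx). Local half-widths above (u) and
# below (l) the midline are modulated by three articulators:
#   - lip aperture: tract width at the anterior end equals the aperture,
#     tapering into the resting width over a short blend region;
#   - tongue body: a Gaussian bump subtracted from the lower half-width;
#   - velum: a Gaussian bump subtracted from the upper half-width
#     (a lowered velum descends into the tract).

smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Project points onto a polyline. Returns, per point, the arc-length
# position s of the nearest polyline point, the signed normal offset d
# (positive toward the rotated-left normal (ty, -tx), i.e. "up" along a
# lips->larynx midline), and whether the point overshoots the anterior
# (before_start) or posterior (past_end) end of the polyline. For
# overshooting points d is still the normal component relative to the
# end segment, so an open-ended tube can be extended beyond the lips.
project_points_polyline <- function(px, py, poly, arc) {
  n_seg <- nrow(poly) - 1L
  np <- length(px)
  best_d2 <- rep(Inf, np)
  best_s <- numeric(np)
  best_d <- numeric(np)
  before_start <- logical(np)
  past_end <- logical(np)
  for (i in seq_len(n_seg)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1L, 1]; by <- poly[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t_raw <- ((px - ax) * vx + (py - ay) * vy) / len2
    t <- pmin(pmax(t_raw, 0), 1)
    fx <- ax + t * vx; fy <- ay + t * vy
    dx <- px - fx; dy <- py - fy
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    if (any(upd)) {
      seg_len <- sqrt(len2)
      tx <- vx / seg_len; ty <- vy / seg_len
      # signed offset along the up-normal (ty, -tx)
      dsig <- dx * ty - dy * tx
      best_d2[upd] <- d2[upd]
      best_s[upd] <- arc[i] + t[upd] * seg_len
      best_d[upd] <- dsig[upd]
      before_start[upd] <- (i == 1L & t_raw < -1e-9)[upd]
      past_end[upd] <- (i == n_seg & t_raw > 1 + 1e-9)[upd]
    }
  }
  list(s = best_s, d = best_d, before_start = before_start,
       past_end = past_end, outside = before_start | past_end)
}

#' Build a synthetic vocal-tract phantom
#'
#' Constructs a planar (midsagittal) vocal-tract geometry: an L-shaped
#' airway midline from lips to larynx with resting half-widths, articulated
#' control regions for the lips, tongue body and velum, and the three
#' anatomical landmarks used to guide grid placement (lowest point of the
#' upper lip, back of the hard palate, larynx). Geometry is mildly
#' perturbed by `shape_seed` so different "participants" have different
#' anatomies; a fixed seed is fully deterministic.
#'
#' @param acq A `vt_acquisition`; the image must cover at least
#'   96 mm x 96 mm (48 x 48 px at 2 mm/px).
#' @param shape_seed Integer seed controlling anatomical perturbation.
#' @return An object of class `vt_phantom`.
#' @examples
#' ph <- build_phantom(acquisition_params(), shape_seed = 1)
#' ph$landmarks
#' @export
build_phantom <- function(acq = acquisition_params(), shape_seed = 0L) {
  stopifnot(inherits(acq, "vt_acquisition"))
  w_mm <- acq$image_width_px * acq$pixel_size_mm
  h_mm <- acq$image_height_px * acq$pixel_size_mm
  if (w_mm < 96 || h_mm < 96) {
    stop(sprintf(
      "image (%g x %g mm) too small to contain the vocal tract (needs >= 96 x 96 mm)",
      w_mm, h_mm
    ), call. = FALSE)
  }
  with_seed(shape_seed, {
    x_lip <- 0.11 * w_mm + runif(1, -2, 2)
    y_oral <- 0.40 * h_mm + runif(1, -3, 3)
    x_bend <- 0.60 * w_mm + runif(1, -3, 3)
    r_bend <- 0.11 * w_mm + runif(1, -2, 2)
    y_lar <- 0.84 * h_mm + runif(1, -2, 2)
    u0 <- 5 + runif(1, -0.5, 0.5)
    l0 <- 5 + runif(1, -0.5, 0.5)
    ds <- 0.5
    # straight oral segment
    xs1 <- seq(x_lip, x_bend, by = ds)
    seg1 <- cbind(xs1, y_oral)
    # quarter-circle bend
    th <- seq(0, pi / 2, length.out = max(8, ceiling(r_bend * pi / 2 / ds)))
    seg2 <- cbind(x_bend + r_bend * sin(th), y_oral + r_bend * (1 - cos(th)))
    # vertical pharyngeal segment
    ys3 <- seq(y_oral + r_bend, y_lar, by = ds)
    seg3 <- cbind(x_bend + r_bend, ys3)
    poly <- rbind(seg1, seg2[-1, , drop = FALSE], seg3[-1, , drop = FALSE])
    arc <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
    s_palate <- arc[length(xs1)] - 2  # just anterior to the bend
    tract_len <- arc[length(arc)]
    tongue_s <- 0.55 * s_palate + runif(1, -3, 3)
    velum_s <- s_palate + 6 + runif(1, -1.5, 1.5)
    landmarks <- list(
      upper_lip = c(x = x_lip, y = y_oral),
      hard_palate_back = c(x = x_bend - 2, y = y_oral - u0),
      larynx = c(x = x_bend + r_bend, y = y_lar)
    )
    ph <- list(
      midline = unname(poly), arc = arc, length_mm = tract_len,
      u0 = u0, l0 = l0, lip_taper_mm = 8,
      tongue_s = tongue_s, tongue_w = 9,
      velum_s = velum_s, velum_w = 5,
      s_palate = s_palate,
      landmarks = landmarks,
      acq = acq, shape_seed = as.integer(shape_seed)
    )
    class(ph) <- "vt_phantom"
    ph
  })
}

#' @export
print.vt_phantom <- function(x, ...) {
  cat(sprintf(
    "vt_phantom: tract length %.1f mm, resting width %.1f mm, seed %d\n",
    x$length_mm, x$u0 + x$l0, x$shape_seed
  ))
  invisible(x)
}

# Half-width profiles u(s), l(s) for one articulator state.
# state = c(aperture_mm, tongue_mm, velum_mm), all >= 0.
phantom_halfwidths <- function(phantom, state, s) {
  state <- phantom_clip_state(phantom, state)
  a <- state[1]; h <- state[2]; v <- state[3]
  ramp <- smoothstep(s / phantom$lip_taper_mm)
  u <- ramp * phantom$u0 + (1 - ramp) * (a / 2)
  l <- ramp * phantom$l0 + (1 - ramp) * (a / 2)
  u <- u - v * exp(-0.5 * ((s - phantom$velum_s) / phantom$velum_w)^2)
  l <- l - h * exp(-0.5 * ((s - phantom$tongue_s) / phantom$tongue_w)^2)
  list(u = u, l = l)
}

# Clip articulator excursions so the tract never seals mid-tract: the
# tongue and velum leave at least 1 mm of the opposing half-width.
phantom_clip_state <- function(phantom, state) {
  c(
    max(state[1], 0),
    min(max(state[2], 0), phantom$l0 - 1),
    min(max(state[3], 0), phantom$u0 - 1)
  )
}

# Cached projection of every pixel center onto the midline.
phantom_pixel_projection <- function(phantom) {
  acq <- phantom$acq
  px <- acq$pixel_size_mm
  cx <- ((seq_len(acq$image_width_px)) - 0.5) * px
  cy <- ((seq_len(acq$image_height_px)) - 0.5) * px
  g <- expand.grid(y = cy, x = cx)  # column-major: rows vary fastest
  project_points_polyline(g$x, g$y, phantom$midline, phantom$arc)
}
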