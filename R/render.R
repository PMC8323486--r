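# Rendering of phantom frames.
#
# Frames are rendered analytically: every pixel center is projected once
# onto the airway midline to obtain its arc position s and signed normal
# offset d. A pixel's intensity is the tissue level minus the blurred
# air-slab indicator: for local half-widths u(s), l(s) the air slab is
# -l < d < u, and convolving the 1-D slab profile with a Gaussian
# point-spread of width sigma gives
#   f(d) = pnorm((u - d)/sigma) - pnorm((-l - d)/sigma).
# The intensity mid-crossing therefore sits exactly on the true boundary,
# and blur acts along the tract normal (curvature and end effects are
# neglected; see the methods vignette).

#' Render phantom frames for a set of articulator trajectories
#'
#' @param phantom A `vt_phantom`.
#' @param trajectories A frames x 3 matrix (columns lips, tongue, velum, mm)
#'   or a repetition list from [synthesize_repetitions()] whose `traj`
#'   matrices are stacked in order.
#' @param blur_px Gaussian point-spread sigma in pixels (default 0.7).
#' @param noise_sd Additive Gaussian intensity noise SD (default 0.03).
#' @param tissue,air Intensity levels for tissue and air.
#' @param seed Optional seed for the noise draw.
#' @return An object of class `vt_framestack`: list with `frames`
#'   (H x W x T array, intensities in [0, 1]), `states` (the clipped
#'   articulator states actually rendered, T x 3), `phantom`, `acq`,
#'   `blur_px`, `noise_sd`.
#' @export
render_frames <- function(phantom, trajectories, blur_px = 0.7,
                          noise_sd = 0.03, tissue = 0.9, air = 0.1,
                          seed = NULL) {
  stopifnot(inherits(phantom, "vt_phantom"))
  if (is.list(trajectories) && !is.matrix(trajectories)) {
    trajectories <- do.call(rbind, lapply(trajectories, `[[`, "traj"))
  }
  stopifnot(is.matrix(trajectories), ncol(trajectories) == 3)
  acq <- phantom$acq
  h <- acq$image_height_px; w <- acq$image_width_px
  n_fr <- nrow(trajectories)
  sigma <- blur_px * acq$pixel_size_mm
  proj <- phantom_pixel_projection(phantom)
  # The tube is open at the lips: points anterior of the lip plane keep
  # the s = 0 half-widths (the mouth opening continues to the exterior),
  # while points past the larynx are tissue.
  inside <- !proj$past_end & proj$s <= phantom$length_mm
  bad <- which(!is.finite(trajectories) | trajectories < -1e-9, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid articulator value at frame %d", bad[1, 1]),
         call. = FALSE)
  }
  if (any(trajectories[, 1] > 2 * (phantom$u0 + phantom$l0))) {
    fr <- which(trajectories[, 1] > 2 * (phantom$u0 + phantom$l0))[1]
    stop(sprintf("articulator excursion outside the image at frame %d", fr),
         call. = FALSE)
  }
  frames <- array(0, dim = c(h, w, n_fr))
  states <- matrix(0, n_fr, 3, dimnames = list(NULL, c("lips", "tongue", "velum")))
  noise_fun <- function(n) {
    if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  }
  run <- function() {
    for (k in seq_len(n_fr)) {
      st <- phantom_clip_state(phantom, trajectories[k, ])
      states[k, ] <<- st
      hw <- phantom_halfwidths(phantom, st, proj$s)
      if (sigma > 0) {
        f <- stats::pnorm((hw$u - proj$d) / sigma) -
          stats::pnorm((-hw$l - proj$d) / sigma)
      } else {
        f <- as.numeric(proj$d < hw$u & proj$d > -hw$l)
      }
      f[!inside] <- 0
      img <- tissue - (tissue - air) * f + noise_fun(h * w)
      frames[, , k] <<- pmin(pmax(matrix(img, h, w), 0), 1)
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  structure(
    list(frames = frames, states = states, phantom = phantom, acq = acq,
         blur_px = blur_px, noise_sd = noise_sd),
    class = "vt_framestack"
  )
}

#' @export
print.vt_framestack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("vt_framestack: %d frames of %d x %d px (blur %.2f px, noise %.3f)\n",
              d[3], d[1], d[2], x$blur_px, x$noise_sd))
  invisible(x)
}

#' Ground-truth boundary crossings along a measurement grid
#'
#' Computes, independently of any rendered image, where the true air-tissue
#' boundaries of the phantom intersect each gridline in each frame, by
#' root-finding the phantom's implicit airway membership along the
#' gridline. This is the oracle against which image-based segmentation is
#' validated.
#'
#' @param phantom A `vt_phantom`.
#' @param states T x 3 matrix of (clipped) articulator states, e.g.
#'   `stack$states` from [render_frames()].
#' @param grid A `vt_grid` from [construct_grid()].
#' @param step_mm Sampling step along each gridline (default 0.1 mm).
#' @return A `vt_contours` object (see [detect_boundaries()]) holding the
#'   true signed crossing positions.
#' @export
true_boundaries <- function(phantom, states, grid, step_mm = 0.1) {
  stopifnot(inherits(phantom, "vt_phantom"), inherits(grid, "vt_grid"))
  if (is.null(dim(states))) states <- matrix(states, 1)
  tvals <- seq(-grid$half_length_mm, grid$half_length_mm, by = step_mm)
  ns <- length(tvals); ng <- nrow(grid$origins)
  # static sample-point projections, all gridlines at once
  pts_x <- outer(tvals, grid$normals[, 1]) +
    matrix(grid$origins[, 1], ns, ng, byrow = TRUE)
  pts_y <- outer(tvals, grid$normals[, 2]) +
    matrix(grid$origins[, 2], ns, ng, byrow = TRUE)
  proj <- project_points_polyline(as.vector(pts_x), as.vector(pts_y),
                                  phantom$midline, phantom$arc)
  s_m <- matrix(proj$s, ns, ng)
  d_m <- matrix(proj$d, ns, ng)
  ok_m <- matrix(!proj$past_end, ns, ng)
  i0 <- which.min(abs(tvals))
  n_fr <- nrow(states)
  upper <- matrix(NA_real_, n_fr, ng)
  lower <- matrix(NA_real_, n_fr, ng)
  status <- matrix("invalid", n_fr, ng)
  for (k in seq_len(n_fr)) {
    hw <- phantom_halfwidths(phantom, states[k, ], as.vector(s_m))
    g_up <- matrix(hw$u, ns, ng) - d_m      # > 0 below the upper boundary
    g_lo <- d_m + matrix(hw$l, ns, ng)      # > 0 above the lower boundary
    air <- g_up > 0 & g_lo > 0 & ok_m
    for (g in seq_len(ng)) {
      if (!air[i0, g]) { status[k, g] <- "closed"; next }
      up_idx <- which(!air[i0:ns, g])[1]
      lo_idx <- which(!air[i0:1, g])[1]
      if (is.na(up_idx) || is.na(lo_idx)) next
      ju <- i0 + up_idx - 1L
      jl <- i0 - lo_idx + 1L
      upper[k, g] <- interp_root(tvals[ju - 1L], tvals[ju],
                                 g_up[ju - 1L, g], g_up[ju, g])
      lower[k, g] <- interp_root(tvals[jl + 1L], tvals[jl],
                                 g_lo[jl + 1L, g], g_lo[jl, g])
      status[k, g] <- "ok"
    }
  }
  new_contours(upper, lower, status, grid, smoothed = FALSE,
               pixel_size_mm = phantom$acq$pixel_size_mm)
}

# linear-interpolated zero crossing of f between t1 (f1 > 0) and t2
interp_root <- function(t1, t2, f1, f2) {
  if (f1 == f2) return((t1 + t2) / 2)
  t1 + (t2 - t1) * f1 / (f1 - f2)
}
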