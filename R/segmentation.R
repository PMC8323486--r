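# Grid-based air-tissue boundary detection.

new_contours <- function(upper, lower, status, grid, smoothed,
                         pixel_size_mm = NULL) {
  structure(
    list(upper = upper, lower = lower, status = status, grid = grid,
         smoothed = smoothed, pixel_size_mm = pixel_size_mm),
    class = "vt_contours"
  )
}

#' @export
print.vt_contours <- function(x, ...) {
  cat(sprintf("vt_contours: %d frames x %d gridlines (%s)\n",
              nrow(x$upper), ncol(x$upper),
              if (x$smoothed) "smoothed" else "raw"))
  invisible(x)
}

# Otsu's 2-class threshold on a vector of intensities in [0, 1].
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  h <- tabulate(pmin(pmax(floor(v * n_bins), 0), n_bins - 1L) + 1L, n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b) - 0.5) / n_bins
}

# Bilinear interpolation of image values at continuous pixel coordinates
# (cx along columns, cy along rows; pixel centers at integer coordinates).
bilinear_sample <- function(img, cx, cy) {
  h <- nrow(img); w <- ncol(img)
  cx <- pmin(pmax(cx, 1), w)
  cy <- pmin(pmax(cy, 1), h)
  x0 <- pmin(floor(cx), w - 1L); y0 <- pmin(floor(cy), h - 1L)
  fx <- cx - x0; fy <- cy - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- img[i00];        v10 <- img[i00 + h]
  v01 <- img[i00 + 1L];   v11 <- img[i00 + h + 1L]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Detect raw air-tissue boundary crossings along each gridline
#'
#' For each frame and gridline, the image intensity is sampled along the
#' gridline by bilinear interpolation. Starting from the midline crossing
#' (assumed air when the tract is locally open) and walking outward in
#' both directions, the first air-to-tissue transition through the
#' threshold is localized with sub-pixel precision by linear interpolation
#' of the intensity profile. Gridlines whose midline sample is already at
#' tissue intensity are flagged `closed`; gridlines with no transition on
#' one side are flagged `invalid`.
#'
#' @param frames A `vt_framestack`, an H x W matrix (single frame), or an
#'   H x W x T array.
#' @param grid A `vt_grid`.
#' @param pixel_size_mm Pixel size in mm (taken from the framestack when
#'   available).
#' @param threshold `"otsu"` (per-frame 2-class Otsu on the grid-sampled
#'   intensities) or a fixed numeric threshold.
#' @param step_px Sampling step along gridlines in pixels (default 0.25).
#' @return A raw `vt_contours` object: matrices `upper`, `lower`
#'   (frames x gridlines, signed mm positions from the gridline origin,
#'   positive toward the upper boundary) and `status`
#'   (`"ok"`, `"closed"`, `"invalid"`).
#' @export
detect_boundaries <- function(frames, grid, pixel_size_mm = NULL,
                              threshold = "otsu", step_px = 0.25) {
  stopifnot(inherits(grid, "vt_grid"))
  if (inherits(frames, "vt_framestack")) {
    pixel_size_mm <- frames$acq$pixel_size_mm
    frames <- frames$frames
  }
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3, is.numeric(pixel_size_mm))
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  step_mm <- step_px * pixel_size_mm
  tvals <- seq(-grid$half_length_mm, grid$half_length_mm, by = step_mm)
  ns <- length(tvals); ng <- nrow(grid$origins)
  px_x <- (outer(tvals, grid$normals[, 1]) +
             matrix(grid$origins[, 1], ns, ng, byrow = TRUE)) / pixel_size_mm + 0.5
  px_y <- (outer(tvals, grid$normals[, 2]) +
             matrix(grid$origins[, 2], ns, ng, byrow = TRUE)) / pixel_size_mm + 0.5
  i0 <- which.min(abs(tvals))
  n_fr <- dim(frames)[3]
  upper <- matrix(NA_real_, n_fr, ng)
  lower <- matrix(NA_real_, n_fr, ng)
  status <- matrix("invalid", n_fr, ng)
  for (k in seq_len(n_fr)) {
    prof <- matrix(bilinear_sample(frames[, , k], as.vector(px_x),
                                   as.vector(px_y)), ns, ng)
    thr <- if (identical(threshold, "otsu")) otsu_threshold(prof) else threshold
    for (g in seq_len(ng)) {
      p <- prof[, g]
      if (p[i0] >= thr) { status[k, g] <- "closed"; next }
      iu <- which(p[i0:ns] >= thr)[1]
      il <- which(p[i0:1] >= thr)[1]
      if (is.na(iu) || is.na(il)) next
      ju <- i0 + iu - 1L
      jl <- i0 - il + 1L
      upper[k, g] <- tvals[ju - 1L] +
        (thr - p[ju - 1L]) / (p[ju] - p[ju - 1L]) * step_mm
      lower[k, g] <- tvals[jl + 1L] -
        (thr - p[jl + 1L]) / (p[jl] - p[jl + 1L]) * step_mm
      status[k, g] <- "ok"
    }
  }
  new_contours(upper, lower, status, grid, smoothed = FALSE,
               pixel_size_mm = pixel_size_mm)
}

# moving average of window 3 with replicated ends
ma3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xp <- c(x[1], x, x[n])
  (xp[1:n] + xp[2:(n + 1)] + xp[3:(n + 2)]) / 3
}

#' Interpolate and smooth raw boundary contours
#'
#' Per frame, gridlines without a detected crossing (closed or invalid)
#' are filled by linear interpolation over gridline index from their valid
#' neighbors, then a moving-average filter of window 3 is applied along
#' the gridline index (no temporal smoothing). Where smoothing would make
#' the lower boundary exceed the upper, both are clipped to their midpoint
#' and the gridline is flagged `clipped`. Original `closed`/`invalid`
#' flags are retained so downstream measurements can honor them. Frames
#' with fewer than 3 valid gridlines are flagged unusable.
#'
#' @param raw A raw `vt_contours` from [detect_boundaries()].
#' @return A smoothed `vt_contours`; element `frame_usable` is a logical
#'   vector over frames.
#' @export
smooth_contours <- function(raw) {
  stopifnot(inherits(raw, "vt_contours"))
  if (raw$smoothed) warning("contours already smoothed; smoothing again")
  n_fr <- nrow(raw$upper); ng <- ncol(raw$upper)
  upper <- raw$upper; lower <- raw$lower
  status <- raw$status
  usable <- rep(TRUE, n_fr)
  idx <- seq_len(ng)
  for (k in seq_len(n_fr)) {
    ok <- status[k, ] == "ok"
    if (sum(ok) < 3) { usable[k] <- FALSE; next }
    u <- upper[k, ]; l <- lower[k, ]
    if (any(!ok)) {
      u[!ok] <- stats::approx(idx[ok], u[ok], idx[!ok], rule = 2)$y
      l[!ok] <- stats::approx(idx[ok], l[ok], idx[!ok], rule = 2)$y
    }
    u <- ma3(u); l <- ma3(l)
    bad <- l > u
    if (any(bad)) {
      mid <- (u[bad] + l[bad]) / 2
      u[bad] <- mid; l[bad] <- mid
      status[k, bad][status[k, bad] == "ok"] <- "clipped"
    }
    upper[k, ] <- u; lower[k, ] <- l
  }
  out <- new_contours(upper, lower, status, raw$grid, smoothed = TRUE,
                      pixel_size_mm = raw$pixel_size_mm)
  out$frame_usable <- usable
  out
}

#' Validate segmented contours against ground truth
#'
#' Root-mean-square error of the distances between detected and true
#' boundary crossings at each gridline, in mm and pixels, overall and by
#' tract region (anterior / mid / posterior thirds of the grid). Only
#' gridline-frames where both the detection and the truth are open
#' (`"ok"`) enter the RMSE.
#'
#' @param contours A `vt_contours` (raw or smoothed) from image-based
#'   detection.
#' @param truth A `vt_contours` of true crossings from
#'   [true_boundaries()].
#' @param pixel_size_mm Pixel size used for the px-scale report (taken
#'   from `contours` when available).
#' @return A list: `rmse_mm`, `rmse_px`, `n_points`, `by_region`
#'   (data.frame), `by_frame` (vector of per-frame RMSE in mm).
#' @export
validate_segmentation <- function(contours, truth, pixel_size_mm = NULL) {
  stopifnot(inherits(contours, "vt_contours"), inherits(truth, "vt_contours"))
  if (!all(dim(contours$upper) == dim(truth$upper))) {
    stop("contours and truth are not frame-aligned", call. = FALSE)
  }
  if (is.null(pixel_size_mm)) pixel_size_mm <- contours$pixel_size_mm
  stopifnot(is.numeric(pixel_size_mm))
  use <- contours$status %in% c("ok", "clipped") & truth$status == "ok"
  use <- matrix(use, nrow(contours$upper))
  err2 <- (contours$upper - truth$upper)^2
  err2l <- (contours$lower - truth$lower)^2
  sq <- c(err2[use], err2l[use])
  ng <- ncol(contours$upper)
  region <- cut(seq_len(ng), breaks = 3,
                labels = c("anterior", "mid", "posterior"))
  by_region <- do.call(rbind, lapply(levels(region), function(rg) {
    cols <- which(region == rg)
    m <- use[, cols, drop = FALSE]
    s <- c(err2[, cols, drop = FALSE][m], err2l[, cols, drop = FALSE][m])
    data.frame(region = rg, rmse_mm = sqrt(mean(s)),
               rmse_px = sqrt(mean(s)) / pixel_size_mm,
               n_points = length(s))
  }))
  by_frame <- vapply(seq_len(nrow(use)), function(k) {
    m <- use[k, ]
    if (!any(m)) return(NA_real_)
    sqrt(mean(c(err2[k, m], err2l[k, m])))
  }, numeric(1))
  list(
    rmse_mm = sqrt(mean(sq)),
    rmse_px = sqrt(mean(sq)) / pixel_size_mm,
    n_points = length(sq),
    by_region = by_region,
    by_frame = by_frame
  )
}
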