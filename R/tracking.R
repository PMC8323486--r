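# Articulator trajectories from boundary contours, and utterance
# segmentation from the bilabial release/closure rule.

#' Lip aperture trajectory
#'
#' Per frame, the Euclidean distance in mm between the upper and lower
#' boundary points on the most anterior gridline (at the lips). Since both
#' points lie on the same gridline this is the difference of their signed
#' positions. Frames where the lip gridline is flagged closed have
#' aperture exactly 0. Frames where the gridline is invalid (undetectable
#' but not closed) are returned as NA; if more than `max_invalid_frac` of
#' frames are invalid the trace is flagged unusable.
#'
#' @param contours A `vt_contours`.
#' @param gridline Gridline index at the lips (default 1).
#' @param max_invalid_frac Tolerated fraction of invalid frames
#'   (default 0.1).
#' @return Numeric vector of apertures (mm) with attributes `articulator`
#'   ("lips") and `usable` (logical).
#' @export
lip_aperture_trace <- function(contours, gridline = 1L,
                               max_invalid_frac = 0.1) {
  stopifnot(inherits(contours, "vt_contours"))
  st <- contours$status[, gridline]
  ap <- contours$upper[, gridline] - contours$lower[, gridline]
  ap[st == "closed"] <- 0
  ap[st == "invalid"] <- NA_real_
  ap[ap < 0 & !is.na(ap)] <- 0
  usable <- mean(is.na(ap)) <= max_invalid_frac
  structure(ap, articulator = "lips", usable = usable)
}

#' Segment one utterance from a lip-aperture trace
#'
#' Implements the bilabial release/closure rule: the utterance is the
#' longest run of frames with aperture above `eps_mm` (at least
#' `min_open_frames` long). Its start is the last frame at or below
#' `eps_mm` immediately before the run (the release of the initial /m/
#' closure) and its end the first frame at or below `eps_mm` after it
#' (the final stop closure). The window is invalid -- with a
#' machine-readable reason -- when no qualifying run exists or when the
#' run touches the trial boundary so that no flanking closure was
#' observed.
#'
#' @param aperture Numeric vector of lip apertures (mm); NAs are treated
#'   as closed.
#' @param eps_mm Zero-aperture tolerance in mm (default 1, half a pixel at
#'   2 mm/px).
#' @param min_open_frames Minimum open-run length (default 3).
#' @return A list with `start`, `end` (1-based inclusive frame indices),
#'   `valid`, and `reason` (empty string when valid).
#' @examples
#' segment_utterance(c(0, 0, 0, 5, 8, 5, 0, 0))  # start 3, end 7
#' @export
segment_utterance <- function(aperture, eps_mm = 1, min_open_frames = 3L) {
  stopifnot(is.numeric(aperture), eps_mm >= 0, min_open_frames >= 1)
  ap <- ifelse(is.na(aperture), 0, aperture)
  open <- ap > eps_mm
  invalid <- function(reason) {
    list(start = NA_integer_, end = NA_integer_, valid = FALSE,
         reason = reason)
  }
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_open_frames)
  if (!length(cand)) return(invalid("no opening"))
  best <- cand[which.max(r$lengths[cand])]
  if (starts[best] == 1L) return(invalid("no initial closure"))
  if (ends[best] == length(ap)) return(invalid("no final closure"))
  list(start = starts[best] - 1L, end = ends[best] + 1L,
       valid = TRUE, reason = "")
}

# boundary point coordinates (mm) for one gridline over frames
boundary_points <- function(contours, gridline, side = c("lower", "upper")) {
  side <- match.arg(side)
  pos <- contours[[side]][, gridline]
  o <- contours$grid$origins[gridline, ]
  n <- contours$grid$normals[gridline, ]
  cbind(x = o[1] + pos * n[1], y = o[2] + pos * n[2])
}

#' Select the tongue-body measurement gridline
#'
#' Finds, within the reference-word frames, the frame where the dorsal
#' (lower) air-tissue boundary in the oral region is most superior
#' (smallest image y), and selects the gridline nearest that point. The
#' reference position is the lowest tongue-body position (minimum signed
#' position) on that gridline over the entire scan. When
#' `reference_frames` is NULL the fallback is the global maximum tongue
#' height over all frames (intended for scans lacking the reference word);
#' a message notes the fallback.
#'
#' @param contours A `vt_contours` over the whole scan.
#' @param reference_frames Frame indices of the reference-word trials
#'   (canonically the word "mabteebeebee"), or NULL for fallback mode.
#' @param fallback Allow fallback when `reference_frames` is NULL
#'   (default TRUE).
#' @return An object of class `vt_selection`: `articulator`, `gridline`,
#'   `reference_mm` (signed position), `reference_frame`, and
#'   `diagnostics` (per-candidate range of motion).
#' @export
select_tongue_gridline <- function(contours, reference_frames = NULL,
                                   fallback = TRUE) {
  stopifnot(inherits(contours, "vt_contours"))
  grid <- contours$grid
  if (is.null(reference_frames)) {
    if (!fallback) {
      stop("reference word frames absent and fallback disabled", call. = FALSE)
    }
    message("tongue gridline selection: reference word absent, ",
            "using global maximum tongue height")
    reference_frames <- seq_len(nrow(contours$lower))
  }
  # oral-cavity candidates: past the lip taper, anterior to the hard palate
  cand <- which(grid$s > 6 & grid$s <= grid$s_palate)
  if (!length(cand)) stop("no oral-region gridlines", call. = FALSE)
  best_y <- Inf; best_g <- NA_integer_
  for (g in cand) {
    pts <- boundary_points(contours, g, "lower")
    ok <- contours$status[, g] == "ok"
    ok[setdiff(seq_along(ok), reference_frames)] <- FALSE
    if (!any(ok)) next
    k <- which(ok)[which.min(pts[ok, "y"])]
    y <- unname(pts[k, "y"])
    if (y < best_y) { best_y <- y; best_g <- g }
  }
  if (is.na(best_g)) stop("tongue selection failed: no open frames")
  g <- best_g
  pos <- contours$lower[, g]
  ok <- contours$status[, g] == "ok"
  ref <- min(pos[ok])
  diag <- vapply(cand, function(gc) {
    p <- contours$lower[contours$status[, gc] == "ok", gc]
    if (length(p) < 2) return(NA_real_)
    diff(range(p))
  }, numeric(1))
  structure(
    list(articulator = "tongue", gridline = g, reference_mm = ref,
         reference_frame = which(ok)[which.min(pos[ok])],
         diagnostics = data.frame(gridline = cand, range_mm = diag)),
    class = "vt_selection"
  )
}

#' Select the velum measurement gridline
#'
#' Among gridlines in the velar region -- between the hard-palate landmark
#' and 40% of the remaining arc toward the larynx -- selects the one whose
#' upper-boundary position has the largest range of motion over the scan
#' (the middle of the velum, where it bends when raised). The reference is
#' the highest upper-boundary position (maximum signed position) on that
#' gridline in the entire scan.
#'
#' @param contours A `vt_contours` over the whole scan.
#' @param region_frac Fraction of the post-palatal arc included in the
#'   velar region (default 0.4).
#' @return A `vt_selection` (as [select_tongue_gridline()]).
#' @export
select_velum_gridline <- function(contours, region_frac = 0.4) {
  stopifnot(inherits(contours, "vt_contours"))
  grid <- contours$grid
  s_end <- grid$s_palate + region_frac * (grid$arc_length_mm - grid$s_palate)
  cand <- which(grid$s > grid$s_palate & grid$s <= s_end)
  if (!length(cand)) stop("empty velar region", call. = FALSE)
  rng <- vapply(cand, function(g) {
    p <- contours$upper[contours$status[, g] == "ok", g]
    if (length(p) < 2) return(0)
    diff(range(p))
  }, numeric(1))
  if (max(rng) < 1e-9) {
    warning("no velum movement detected; selecting first velar gridline")
  }
  g <- cand[which.max(rng)]
  pos <- contours$upper[, g]
  ok <- contours$status[, g] == "ok"
  ref <- max(pos[ok])
  structure(
    list(articulator = "velum", gridline = g, reference_mm = ref,
         reference_frame = which(ok)[which.max(pos[ok])],
         diagnostics = data.frame(gridline = cand, range_mm = rng)),
    class = "vt_selection"
  )
}

#' @export
print.vt_selection <- function(x, ...) {
  cat(sprintf("vt_selection: %s at gridline %d (reference %.2f mm, frame %d)\n",
              x$articulator, x$gridline, x$reference_mm, x$reference_frame))
  invisible(x)
}

trace_along_gridline <- function(contours, sel, side) {
  pos <- contours[[side]][, sel$gridline]
  ok <- contours$status[, sel$gridline] == "ok"
  if (!any(ok)) stop("no valid frames on the selected gridline")
  if (any(!ok)) {
    idx <- seq_along(pos)
    pos[!ok] <- stats::approx(idx[ok], pos[ok], idx[!ok], rule = 2)$y
  }
  list(pos = pos, interpolated = !ok)
}

#' Tongue-body trajectory
#'
#' Distance in mm along the selected gridline from the reference point
#' (the lowest tongue-body position over the scan) to the lower boundary
#' in each frame; non-negative by construction of the reference. Invalid
#' frames are interpolated from temporal neighbors and flagged.
#'
#' @param contours A `vt_contours`.
#' @param sel A `vt_selection` from [select_tongue_gridline()].
#' @return Numeric vector (mm) with attributes `articulator`,
#'   `interpolated` (logical vector).
#' @export
tongue_trace <- function(contours, sel) {
  stopifnot(inherits(sel, "vt_selection"), sel$articulator == "tongue")
  tr <- trace_along_gridline(contours, sel, "lower")
  structure(pmax(tr$pos - sel$reference_mm, 0),
            articulator = "tongue", interpolated = tr$interpolated)
}

#' Velum trajectory
#'
#' Distance in mm along the selected gridline from the reference point
#' (the highest velum position over the scan) down to the upper boundary
#' in each frame; 0 when the velum is fully raised.
#'
#' @inheritParams tongue_trace
#' @param sel A `vt_selection` from [select_velum_gridline()].
#' @export
velum_trace <- function(contours, sel) {
  stopifnot(inherits(sel, "vt_selection"), sel$articulator == "velum")
  tr <- trace_along_gridline(contours, sel, "upper")
  structure(pmax(sel$reference_mm - tr$pos, 0),
            articulator = "velum", interpolated = tr$interpolated)
}
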