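#' Acquisition parameters for a vocal-tract rtMRI recording
#'
#' Bundles the imaging metadata the pipeline needs: frame rate, in-plane
#' pixel size, trial duration and image dimensions. Defaults match a
#' midsagittal rtMRI protocol reconstructed at 33.3 frames per second
#' (100/3 fps exactly) with 2 mm x 2 mm pixels and 3.5-s trials.
#'
#' @param frame_rate Frames per second. Default `100/3` (printed as 33.3).
#' @param pixel_size_mm Isotropic pixel size in mm. Default 2.
#' @param trial_duration_s Duration of one trial in seconds. Default 3.5.
#' @param image_height_px,image_width_px Image dimensions in pixels.
#'
#' @return An object of class `vt_acquisition`.
#' @examples
#' acq <- acquisition_params()
#' frames_per_trial(acq)  # 116
#' @export
acquisition_params <- function(frame_rate = 100 / 3,
                               pixel_size_mm = 2.0,
                               trial_duration_s = 3.5,
                               image_height_px = 64L,
                               image_width_px = 64L) {
  stopifnot(
    is.numeric(frame_rate), length(frame_rate) == 1, frame_rate > 0,
    is.numeric(pixel_size_mm), pixel_size_mm > 0,
    is.numeric(trial_duration_s), trial_duration_s > 0,
    image_height_px >= 1, image_width_px >= 1
  )
  acq <- list(
    frame_rate = frame_rate,
    pixel_size_mm = pixel_size_mm,
    trial_duration_s = trial_duration_s,
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px)
  )
  class(acq) <- "vt_acquisition"
  if (frames_per_trial(acq) < 1) {
    stop("trial window shorter than one frame", call. = FALSE)
  }
  acq
}

#' Number of complete frames in one trial
#'
#' @param acq A `vt_acquisition` object.
#' @return Integer frame count, `floor(trial_duration_s * frame_rate)`.
#' @export
frames_per_trial <- function(acq) {
  stopifnot(inherits(acq, "vt_acquisition"))
  as.integer(floor(acq$trial_duration_s * acq$frame_rate + 1e-9))
}

#' Complete frames spanned by an articulatory event
#'
#' How many complete frame intervals fit inside an event of the given
#' duration, e.g. a brief bilabial closure. At 33.3 fps a 60-ms closure
#' spans 2 complete frames and a 200-ms closure spans 6, which bounds the
#' temporal precision of closure-duration measurement.
#'
#' @param duration_s Event duration in seconds.
#' @param frame_rate Frames per second (default 100/3).
#' @return Integer number of complete frames.
#' @export
closure_frame_span <- function(duration_s, frame_rate = 100 / 3) {
  stopifnot(duration_s >= 0, frame_rate > 0)
  as.integer(floor(duration_s * frame_rate + 1e-9))
}

#' @export
print.vt_acquisition <- function(x, ...) {
  cat(sprintf(
    "vt_acquisition: %.1f fps, %.1f mm/px, %.2f s/trial (%d frames), %dx%d px\n",
    x$frame_rate, x$pixel_size_mm, x$trial_duration_s, frames_per_trial(x),
    x$image_height_px, x$image_width_px
  ))
  invisible(x)
}
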