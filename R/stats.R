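# Movement-size, duration and variability statistics.

#' Movement size of one utterance
#'
#' The sum of the per-frame articulator measurement (mm) over the
#' utterance window, inclusive of both endpoints, in units of mm frames.
#' Size captures amplitude and duration jointly.
#'
#' @param values Numeric per-frame trajectory (mm).
#' @param window A window list from [segment_utterance()].
#' @return Size in mm frames, or NA (with attribute `reason`) for an
#'   invalid window.
#' @examples
#' w <- segment_utterance(c(0, 5, 8, 5, 0), min_open_frames = 3)
#' movement_size(c(0, 5, 8, 5, 0), w)  # 18
#' @export
movement_size <- function(values, window) {
  if (!isTRUE(window$valid)) {
    return(structure(NA_real_, reason = window$reason))
  }
  stopifnot(window$start >= 1, window$end <= length(values))
  sum(values[window$start:window$end])
}

#' Coefficient of variation of movement sizes
#'
#' Sample standard deviation (n - 1 denominator) of the per-repetition
#' movement sizes divided by their mean. Dimensionless and invariant to
#' rescaling of the sizes.
#'
#' @param sizes Numeric vector of per-repetition sizes (NAs dropped).
#' @return The CoV, or NA (with attribute `reason`) when fewer than 2
#'   sizes remain or the mean is not positive.
#' @examples
#' size_cov(c(8, 10, 12))  # 0.2
#' @export
size_cov <- function(sizes) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 sizes"))
  }
  m <- mean(sizes)
  if (m <= 0) return(structure(NA_real_, reason = "non-positive mean"))
  stats::sd(sizes) / m
}

#' Per-repetition durations and their mean
#'
#' Duration of each utterance is the total number of frames from start to
#' end of the window, inclusive (`end - start + 1`), converted to ms via
#' the frame rate.
#'
#' @param windows A list of window lists from [segment_utterance()].
#' @param frame_rate Frames per second.
#' @return A list with `frames` (per-repetition counts, NA when invalid),
#'   `ms`, `mean_frames`, `mean_ms`, `n_valid`.
#' @export
duration_stats <- function(windows, frame_rate = 100 / 3) {
  frames <- vapply(windows, function(w) {
    if (isTRUE(w$valid)) as.numeric(w$end - w$start + 1L) else NA_real_
  }, numeric(1))
  ms <- frames * 1000 / frame_rate
  list(
    frames = frames, ms = ms,
    mean_frames = mean(frames, na.rm = TRUE),
    mean_ms = mean(ms, na.rm = TRUE),
    n_valid = sum(!is.na(frames))
  )
}

#' Apply the fluency inclusion rule
#'
#' A pseudoword is included for a participant only when at least
#' `min_included` of its repetitions were produced fluently and with a
#' valid (accurate) utterance window; otherwise all repetitions of that
#' word are excluded for that participant. Every exclusion carries a
#' machine-readable reason.
#'
#' @param trials A data.frame with columns `participant`, `word`,
#'   `repetition`, `fluent` (logical) and `valid_window` (logical).
#' @param min_included Minimum usable repetitions (default 6, out of 10).
#' @return A list: `trials` (input plus logical `used`), `words`
#'   (per participant x word: `n_usable`, `included`, `reason`).
#' @export
apply_fluency_filter <- function(trials, min_included = 6L) {
  needed <- c("participant", "word", "repetition", "fluent", "valid_window")
  stopifnot(all(needed %in% names(trials)))
  usable <- trials$fluent & trials$valid_window
  key <- paste(trials$participant, trials$word, sep = "\r")
  first <- !duplicated(key)
  n_usable <- as.vector(tapply(usable, key, sum)[key[first]])
  n_total <- as.vector(tapply(usable, key, length)[key[first]])
  included <- n_usable >= min_included
  words <- data.frame(
    participant = trials$participant[first],
    word = trials$word[first],
    n_usable = n_usable,
    included = included,
    reason = ifelse(included, "",
                    sprintf("only %d of %d fluent and accurate",
                            n_usable, n_total)),
    stringsAsFactors = FALSE
  )
  trials$used <- usable & included[match(key, key[first])]
  list(trials = trials, words = words)
}

#' Spatiotemporal index of a set of repeated trajectories
#'
#' The classical STI: each windowed trajectory is amplitude-normalized by
#' z-scoring (mean 0, SD 1), time-normalized by linear resampling to
#' 1,000 points, the across-repetition standard deviation is computed at
#' 50 equally spaced of those points (every 20th, centered: indices 10,
#' 30, ..., 990), and the 50 SDs are summed. Repetitions with zero
#' variance cannot be z-scored and are dropped with a warning.
#'
#' @param trajectories A list of numeric vectors, each one windowed
#'   repetition (>= 2 frames).
#' @param n_resample Resampling grid size (default 1000).
#' @param n_points Number of SD sample points (default 50).
#' @return The STI value (>= 0), with attribute `n_used`.
#' @export
sti <- function(trajectories, n_resample = 1000L, n_points = 50L) {
  stopifnot(is.list(trajectories), length(trajectories) >= 2)
  keep <- vapply(trajectories, function(x) {
    length(x) >= 2 && stats::sd(x) > 0
  }, logical(1))
  if (!all(keep)) {
    warning(sprintf("%d zero-variance repetition(s) dropped from STI",
                    sum(!keep)))
  }
  trajectories <- trajectories[keep]
  if (length(trajectories) < 2) {
    return(structure(NA_real_, n_used = length(trajectories)))
  }
  grid <- seq(0, 1, length.out = n_resample)
  z <- vapply(trajectories, function(x) {
    zx <- (x - mean(x)) / stats::sd(x)
    stats::approx(seq(0, 1, length.out = length(zx)), zx, grid)$y
  }, numeric(n_resample))
  step <- n_resample / n_points
  idx <- as.integer(seq(step / 2, n_resample - step / 2, by = step))
  sds <- apply(z[idx, , drop = FALSE], 1, stats::sd)
  structure(sum(sds), n_used = length(trajectories))
}
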