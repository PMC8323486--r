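# Gestural scores for the five pseudoword stimuli.
#
# Each pseudoword is a sequence of gesture segments. Lip aperture is
# exactly zero during the word-initial /m/ closure and the word-final stop
# closure, and positive in between; word-medial bilabials are rendered as
# partial constrictions (the aperture dips but stays open), which is how
# brief medial closures appear at a 33.3-fps sampling rate. The velum
# lowers only for the initial nasal /m/; the tongue body rises for high
# vowels, maximally during the first /i/ of "mabteebeebee". Segment shapes
# are library constants; only their presence and ordering is
# phonotactically constrained.

#' The pseudoword stimulus set
#'
#' Five pseudowords: one to three syllables of increasing length plus two
#' four-syllable words contrasting phonological complexity.
#'
#' @return Character vector of the five pseudoword labels.
#' @export
pseudoword_set <- function() {
  c("mab", "mabshibe", "mabfieshabe", "mabshaytiedoib", "mabteebeebee")
}

#' Pseudoword metadata
#'
#' @return A data.frame with word label, syllable count, complexity class
#'   (`1syl`, `2syl`, `3syl`, `4simple`, `4complex`) and a monotone
#'   complexity index used for group-specific duration scaling.
#' @export
word_info <- function() {
  data.frame(
    word = pseudoword_set(),
    syllables = c(1L, 2L, 3L, 4L, 4L),
    complexity_class = c("1syl", "2syl", "3syl", "4complex", "4simple"),
    complexity_index = c(0L, 1L, 2L, 4L, 3L),
    stringsAsFactors = FALSE
  )
}

# segment builder: type in closure / vowel / partial / cons
seg <- function(type, w, lip = 0, tongue = 0.3, velum = 0) {
  list(type = type, w = w, lip = lip, tongue = tongue, velum = velum)
}

word_segments <- function(word) {
  switch(word,
    mab = list(
      seg("closure", 0.13), seg("vowel", 0.20, 12, 0.8), seg("closure", 0.12)
    ),
    mabshibe = list(
      seg("closure", 0.13), seg("vowel", 0.17, 12, 0.8),
      seg("partial", 0.06, 3, 1.2), seg("cons", 0.07, 8, 2.0),
      seg("vowel", 0.20, 10, 2.2), seg("closure", 0.12)
    ),
    mabfieshabe = list(
      seg("closure", 0.13), seg("vowel", 0.17, 12, 0.8),
      seg("partial", 0.06, 3, 1.2), seg("cons", 0.06, 6, 1.5),
      seg("vowel", 0.19, 10, 2.4), seg("cons", 0.07, 8, 2.0),
      seg("vowel", 0.19, 10, 2.2), seg("closure", 0.12)
    ),
    mabshaytiedoib = list(
      seg("closure", 0.13), seg("vowel", 0.16, 12, 0.8),
      seg("partial", 0.06, 3, 1.2), seg("cons", 0.07, 8, 2.0),
      seg("vowel", 0.17, 10, 2.3), seg("cons", 0.06, 9, 2.6),
      seg("vowel", 0.17, 10, 2.4), seg("cons", 0.06, 9, 2.4),
      seg("vowel", 0.17, 11, 2.2), seg("closure", 0.12)
    ),
    mabteebeebee = list(
      seg("closure", 0.13), seg("vowel", 0.16, 12, 0.8),
      seg("partial", 0.06, 3, 1.5), seg("cons", 0.06, 9, 3.0),
      seg("vowel", 0.17, 7, 3.5), seg("partial", 0.06, 3, 2.5),
      seg("vowel", 0.17, 7, 3.2), seg("partial", 0.06, 3, 2.5),
      seg("vowel", 0.17, 7, 3.2), seg("closure", 0.12)
    ),
    stop(sprintf("unknown pseudoword '%s'", word), call. = FALSE)
  )
}

nominal_durations <- function() {
  c(mab = 0.45, mabshibe = 0.75, mabfieshabe = 1.05,
    mabshaytiedoib = 1.35, mabteebeebee = 1.20)
}

#' Gestural score for a pseudoword
#'
#' Builds per-articulator target trajectories (lip aperture, tongue-body
#' height, velum opening, all in mm) over the word's nominal duration, as
#' piecewise-linear keyframe tracks. Lip aperture is exactly 0 throughout
#' the initial and final bilabial closure segments and positive elsewhere;
#' the velum-opening track peaks during the initial /m/.
#'
#' @param word One of [pseudoword_set()].
#' @return An object of class `vt_score` with elements `word`,
#'   `nominal_duration_s`, `keyframes` (list of two-column time/value
#'   matrices for `lips`, `tongue`, `velum`) and `closure_segments`
#'   (matrix of start/end times of the exact-zero closures).
#' @examples
#' sc <- gestural_score("mab")
#' sc$nominal_duration_s
#' @export
gestural_score <- function(word) {
  word <- match.arg(word, pseudoword_set())
  segs <- word_segments(word)
  dur <- unname(nominal_durations()[word])
  w <- vapply(segs, function(s) s$w, numeric(1))
  w <- w / sum(w) * dur
  t1 <- cumsum(w)
  t0 <- c(0, t1[-length(t1)])
  mid <- (t0 + t1) / 2

  lips <- list(); tongue <- list(); closures <- list()
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (s$type == "closure") {
      lips[[length(lips) + 1L]] <- rbind(c(t0[i], 0), c(t1[i], 0))
      closures[[length(closures) + 1L]] <- c(t0[i], t1[i])
    } else {
      lips[[length(lips) + 1L]] <- rbind(c(mid[i], s$lip))
    }
    tongue[[length(tongue) + 1L]] <- rbind(c(mid[i], s$tongue))
  }
  lips_k <- do.call(rbind, lips)
  tongue_k <- rbind(c(0, 0.3), do.call(rbind, tongue), c(dur, 0.3))
  # velum: lowered only during the initial /m/, decaying into the vowel
  m_end <- t1[1]
  velum_k <- rbind(
    c(0, 2.0), c(mid[1], 3.5), c(min(m_end + 0.08, dur), 0), c(dur, 0)
  )
  score <- list(
    word = word,
    syllables = word_info()$syllables[word_info()$word == word],
    nominal_duration_s = dur,
    keyframes = list(lips = lips_k, tongue = tongue_k, velum = velum_k),
    closure_segments = do.call(rbind, closures)
  )
  class(score) <- "vt_score"
  score
}

# Sample a score at absolute times (s) with amplitude and time scaling.
# Returns an n x 3 matrix (lips, tongue, velum). Times outside the scaled
# word hold the resting posture (lips closed, tongue at baseline, velum
# raised).
sample_score <- function(score, t, amplitude = 1, time_scale = 1) {
  tau <- t / time_scale
  k <- score$keyframes
  out <- cbind(
    lips = stats::approx(k$lips[, 1], k$lips[, 2], tau, rule = 2)$y,
    tongue = stats::approx(k$tongue[, 1], k$tongue[, 2], tau, rule = 2)$y,
    velum = stats::approx(k$velum[, 1], k$velum[, 2], tau, rule = 2)$y
  )
  out * amplitude
}

#' Repetition-to-repetition jitter specification
#'
#' Per-repetition amplitude and time-scale multipliers are drawn from
#' lognormal distributions with unit mean and the requested coefficients
#' of variation; lognormal draws are positive by construction. For small
#' CVs the implied CV of movement size (sum of aperture over the
#' utterance) is approximately `sqrt(amplitude_cv^2 + duration_cv^2)`,
#' since size scales as amplitude x duration.
#'
#' @param amplitude_cv CV of the amplitude multiplier (>= 0).
#' @param duration_cv CV of the time-scale multiplier (>= 0).
#' @return An object of class `vt_jitter`.
#' @export
repetition_jitter <- function(amplitude_cv = 0, duration_cv = 0) {
  stopifnot(amplitude_cv >= 0, duration_cv >= 0)
  structure(list(amplitude_cv = amplitude_cv, duration_cv = duration_cv),
            class = "vt_jitter")
}

# lognormal multiplier with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthesize jittered repetitions of a pseudoword
#'
#' Draws per-repetition amplitude and time-scale multipliers from the
#' jitter distributions and samples the gestural score on the trial's
#' frame grid. Closure segments remain exactly zero aperture for every
#' draw. Repetitions are placed in the trial window at a jittered onset
#' after a closed-lips rest posture.
#'
#' @param score A `vt_score`.
#' @param jitter A `vt_jitter`.
#' @param n_reps Number of repetitions (default 10).
#' @param acq A `vt_acquisition` defining frame rate and trial window.
#' @param onset_s,onset_jitter_s Utterance onset: fixed part plus a
#'   uniform jitter (s).
#' @param disfluency_prob Probability that a repetition is marked
#'   disfluent (excluded downstream); default 0.
#' @param amplitude_scale,duration_scale Additional deterministic
#'   multipliers (e.g. per-participant or per-word scaling).
#' @return A list of repetitions. Each element has `traj` (frames x 3
#'   matrix, columns `lips`, `tongue`, `velum`, in mm), the drawn
#'   `amplitude` and `time_scale` multipliers, `onset_s`, and `truth`
#'   (true start/end frame of the utterance, true movement size in
#'   mm frames, and the fluency flag).
#' @export
synthesize_repetitions <- function(score, jitter = repetition_jitter(),
                                   n_reps = 10L,
                                   acq = acquisition_params(),
                                   onset_s = 0.3, onset_jitter_s = 0.15,
                                   disfluency_prob = 0,
                                   amplitude_scale = 1, duration_scale = 1) {
  stopifnot(inherits(score, "vt_score"), inherits(jitter, "vt_jitter"),
            n_reps >= 1, disfluency_prob >= 0, disfluency_prob < 1)
  n_fr <- frames_per_trial(acq)
  t_frame <- (seq_len(n_fr) - 0.5) / acq$frame_rate
  a <- rlnorm_cv(n_reps, jitter$amplitude_cv)
  d <- rlnorm_cv(n_reps, jitter$duration_cv)
  onsets <- onset_s + stats::runif(n_reps, 0, onset_jitter_s)
  fluent <- stats::runif(n_reps) >= disfluency_prob
  max_end <- max(onsets + score$nominal_duration_s * d * duration_scale)
  if (max_end > acq$trial_duration_s) {
    stop("scaled utterance exceeds the trial window", call. = FALSE)
  }
  # normalized times for all repetitions at once (one interpolation per
  # articulator channel instead of one per repetition)
  tau <- outer(t_frame, onsets, "-") /
    matrix(d * duration_scale, n_fr, n_reps, byrow = TRUE)
  k <- score$keyframes
  ch <- lapply(k, function(kf) {
    matrix(stats::approx(kf[, 1], kf[, 2], as.vector(tau), rule = 2)$y,
           n_fr, n_reps)
  })
  lapply(seq_len(n_reps), function(i) {
    amp <- a[i] * amplitude_scale
    traj <- cbind(lips = ch$lips[, i], tongue = ch$tongue[, i],
                  velum = ch$velum[, i]) * amp
    ap <- traj[, "lips"]
    open <- which(ap > 0)
    truth <- if (length(open)) {
      r <- longest_run(ap > 0)
      start <- r[1] - 1L; end <- r[2] + 1L
      list(start = start, end = end,
           size = sum(ap[start:end]), fluent = fluent[i])
    } else {
      list(start = NA_integer_, end = NA_integer_,
           size = NA_real_, fluent = fluent[i])
    }
    list(traj = traj, amplitude = a[i], time_scale = d[i],
         onset_s = onsets[i], truth = truth)
  })
}

# first longest TRUE run; returns c(first, last) indices or NULL
longest_run <- function(x) {
  r <- rle(x)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(starts[best], ends[best])
}
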