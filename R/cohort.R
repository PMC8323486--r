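# Cohort simulation: two groups of synthetic participants, each producing
# 5 pseudowords x 10 repetitions with programmable variability.

#' Specify a synthetic cohort
#'
#' Defines the study conditions for a two-group cohort: group sizes,
#' baseline repetition jitter, per-group variability multipliers, a
#' group-specific duration scaling that grows with word complexity (the
#' group x complexity duration interaction), per-group disfluency
#' probabilities, between-participant heterogeneity, and severity scores
#' for the stuttering-like group.
#'
#' Defaults emulate the study design this pipeline targets: 28
#' stuttering-like (pws) vs 20 control-like participants, a baseline
#' movement-size CV near 0.13 (amplitude CV 0.10, duration CV 0.08), a
#' 1.5x variability multiplier in the pws-like group, mild extra
#' utterance lengthening in the pws-like group for complex words, and
#' disfluency rates that leave at least 6 of 10 repetitions usable for
#' almost all words.
#'
#' @param n_per_group Named vector, participants per group.
#' @param amplitude_cv,duration_cv Baseline jitter CVs.
#' @param group_cv_multiplier Named vector multiplying both jitter CVs per
#'   group.
#' @param group_duration_slope Named vector: per unit of word complexity
#'   index (0-4), the proportional utterance lengthening in that group.
#' @param disfluency_prob Named vector of per-trial disfluency
#'   probabilities (each < 0.4).
#' @param participant_cv_sdlog Lognormal sdlog of a per-participant
#'   multiplier on both jitter CVs (between-participant heterogeneity of
#'   variability).
#' @param participant_rate_sdlog Lognormal sdlog of a per-participant
#'   speaking-rate (duration) multiplier.
#' @param severity_mean,severity_sd,severity_range Severity (SSI-like)
#'   score distribution for the pws-like group; drawn independently of
#'   the programmed variability.
#' @param n_reps Repetitions per word (default 10).
#' @param seed Master seed.
#' @return An object of class `vt_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(pws = 28L, control = 20L),
                        amplitude_cv = 0.10,
                        duration_cv = 0.08,
                        group_cv_multiplier = c(pws = 1.5, control = 1),
                        group_duration_slope = c(pws = 0.05, control = 0),
                        disfluency_prob = c(pws = 0.10, control = 0.04),
                        participant_cv_sdlog = 0.25,
                        participant_rate_sdlog = 0.07,
                        severity_mean = 28, severity_sd = 6,
                        severity_range = c(16, 40),
                        n_reps = 10L,
                        seed = 1L) {
  groups <- names(n_per_group)
  stopifnot(
    length(groups) == 2, all(n_per_group >= 1),
    amplitude_cv >= 0, duration_cv >= 0,
    all(groups %in% names(group_cv_multiplier)),
    all(groups %in% names(group_duration_slope)),
    all(groups %in% names(disfluency_prob)),
    all(disfluency_prob >= 0), all(disfluency_prob < 0.4),
    participant_cv_sdlog >= 0, participant_rate_sdlog >= 0,
    n_reps >= 1
  )
  structure(
    list(n_per_group = n_per_group, groups = groups,
         amplitude_cv = amplitude_cv, duration_cv = duration_cv,
         group_cv_multiplier = group_cv_multiplier,
         group_duration_slope = group_duration_slope,
         disfluency_prob = disfluency_prob,
         participant_cv_sdlog = participant_cv_sdlog,
         participant_rate_sdlog = participant_rate_sdlog,
         severity_mean = severity_mean, severity_sd = severity_sd,
         severity_range = severity_range,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "vt_cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' For each participant: a randomized 50-trial schedule (5 pseudowords x
#' `n_reps` repetitions), per-trial articulator trajectories with the
#' programmed jitter, ground truth (drawn multipliers, true utterance
#' windows and movement sizes, fluency flags) and, in `"frames"` mode, a
#' rendered frame stack per participant with their own phantom anatomy.
#' `"trajectories"` mode skips rendering and is the fast path for
#' statistics-stage work.
#'
#' @param spec A `vt_cohort_spec`.
#' @param acq A `vt_acquisition`.
#' @param mode `"trajectories"` (fast) or `"frames"` (adds rendered
#'   stacks; slow, intended for small cohorts).
#' @param words Pseudowords to include (default all five).
#' @return An object of class `vt_cohort`: list of participants, each
#'   with `id`, `group`, `severity`, `schedule` (data.frame trial / word /
#'   repetition), `reps` (list parallel to the schedule, as
#'   [synthesize_repetitions()] elements) and optionally `stack`.
#' @export
generate_cohort <- function(spec, acq = acquisition_params(),
                            mode = c("trajectories", "frames"),
                            words = pseudoword_set()) {
  stopifnot(inherits(spec, "vt_cohort_spec"))
  mode <- match.arg(mode)
  words <- match.arg(words, pseudoword_set(), several.ok = TRUE)
  scores <- lapply(words, gestural_score)
  names(scores) <- words
  winfo <- word_info()
  with_seed(spec$seed, {
    participants <- list()
    pid <- 0L
    for (grp in spec$groups) {
      mult <- spec$group_cv_multiplier[[grp]]
      dslope <- spec$group_duration_slope[[grp]]
      dprob <- spec$disfluency_prob[[grp]]
      for (i in seq_len(spec$n_per_group[[grp]])) {
        pid <- pid + 1L
        p_cv <- stats::rlnorm(1, -spec$participant_cv_sdlog^2 / 2,
                              spec$participant_cv_sdlog)
        p_rate <- stats::rlnorm(1, -spec$participant_rate_sdlog^2 / 2,
                                spec$participant_rate_sdlog)
        severity <- if (grp == spec$groups[1]) {
          min(max(round(stats::rnorm(1, spec$severity_mean,
                                     spec$severity_sd)),
                  spec$severity_range[1]), spec$severity_range[2])
        } else NA_real_
        jit <- repetition_jitter(spec$amplitude_cv * mult * p_cv,
                                 spec$duration_cv * mult * p_cv)
        # synthesize all repetitions of each word in one batch, then
        # shuffle into a randomized trial order
        by_word <- lapply(words, function(wd) {
          cx <- winfo$complexity_index[winfo$word == wd]
          synthesize_repetitions(
            scores[[wd]], jit, n_reps = spec$n_reps, acq = acq,
            disfluency_prob = dprob,
            duration_scale = p_rate * (1 + dslope * cx)
          )
        })
        names(by_word) <- words
        ord <- sample(length(words) * spec$n_reps)
        word_seq <- rep(words, each = spec$n_reps)[ord]
        repetition <- rep(seq_len(spec$n_reps), length(words))[ord]
        reps <- lapply(seq_along(ord), function(tr) {
          by_word[[word_seq[tr]]][[repetition[tr]]]
        })
        part <- list(
          id = sprintf("p%02d", pid), group = grp, severity = severity,
          cv_multiplier = p_cv, rate_multiplier = p_rate,
          schedule = data.frame(trial = seq_along(word_seq),
                                word = word_seq,
                                repetition = repetition,
                                stringsAsFactors = FALSE),
          reps = reps
        )
        if (mode == "frames") {
          phantom <- build_phantom(acq, shape_seed = spec$seed * 1000L + pid)
          part$phantom <- phantom
          part$stack <- render_frames(phantom, reps)
        }
        participants[[pid]] <- part
      }
    }
    structure(list(participants = participants, spec = spec, acq = acq,
                   words = words, mode = mode),
              class = "vt_cohort")
  })
}

#' @export
print.vt_cohort <- function(x, ...) {
  cat(sprintf("vt_cohort: %d participants (%s), %d trials each, mode %s\n",
              length(x$participants),
              paste(sprintf("%s=%d", x$spec$groups,
                            x$spec$n_per_group), collapse = ", "),
              nrow(x$participants[[1]]$schedule), x$mode))
  invisible(x)
}

#' Measure a trajectory-mode cohort
#'
#' Runs the measurement stages on a cohort's articulator trajectories:
#' utterance windows from the lip-aperture trace (bilabial release /
#' closure rule), movement sizes for lips, tongue and velum over the
#' shared window (tongue and velum measured from their scanwise extremum,
#' mirroring the reference-point rule used on segmented contours),
#' per-repetition durations, the fluency/accuracy inclusion rule, and
#' per-participant x word x articulator CoV.
#'
#' @param cohort A `vt_cohort`.
#' @param eps_mm,min_open_frames Utterance-segmentation parameters
#'   (see [segment_utterance()]).
#' @param min_included Inclusion threshold (see [apply_fluency_filter()]).
#' @return A list: `cov_table` (participant, group, word, articulator,
#'   cov, n_used, included), `duration_table` (participant, group, word,
#'   mean_frames, mean_ms, n_valid), `trial_table`, `exclusions`,
#'   `severity` (per-participant data.frame).
#' @export
measure_cohort <- function(cohort, eps_mm = 1, min_open_frames = 3L,
                           min_included = 6L) {
  stopifnot(inherits(cohort, "vt_cohort"))
  fps <- cohort$acq$frame_rate
  arts <- c("lips", "tongue", "velum")
  parts <- cohort$participants
  n_tr <- vapply(parts, function(p) nrow(p$schedule), integer(1))
  pid <- rep(vapply(parts, `[[`, character(1), "id"), n_tr)
  grp <- rep(vapply(parts, `[[`, character(1), "group"), n_tr)
  word <- unlist(lapply(parts, function(p) p$schedule$word))
  trial <- unlist(lapply(parts, function(p) p$schedule$trial))
  repetition <- unlist(lapply(parts, function(p) p$schedule$repetition))
  total <- sum(n_tr)
  fluent <- logical(total); valid <- logical(total)
  dur <- rep(NA_real_, total)
  sizes <- matrix(NA_real_, total, 3, dimnames = list(NULL, arts))
  i <- 0L
  for (p in parts) {
    # scanwise reference for tongue/velum: extremum over the whole session
    ref_t <- min(vapply(p$reps, function(r) min(r$traj[, 2]), numeric(1)))
    ref_v <- min(vapply(p$reps, function(r) min(r$traj[, 3]), numeric(1)))
    for (r in p$reps) {
      i <- i + 1L
      fluent[i] <- r$truth$fluent
      w <- segment_utterance(r$traj[, 1], eps_mm, min_open_frames)
      if (w$valid) {
        valid[i] <- TRUE
        len <- w$end - w$start + 1L
        dur[i] <- len
        idx <- w$start:w$end
        sizes[i, 1] <- sum(r$traj[idx, 1])
        sizes[i, 2] <- sum(r$traj[idx, 2]) - ref_t * len
        sizes[i, 3] <- sum(r$traj[idx, 3]) - ref_v * len
      }
    }
  }
  trial_table <- data.frame(
    participant = pid, group = grp, trial = trial, word = word,
    repetition = repetition, fluent = fluent, valid_window = valid,
    duration_frames = dur, stringsAsFactors = FALSE
  )
  trial_table <- cbind(trial_table, sizes)
  filt <- apply_fluency_filter(trial_table, min_included = min_included)
  trial_table$used <- filt$trials$used
  # per participant x word aggregates over the used repetitions
  wtab <- filt$words
  wkey <- paste(trial_table$participant, trial_table$word, sep = "\r")
  ukey <- paste(wtab$participant, wtab$word, sep = "\r")
  used <- trial_table$used
  agg <- function(v, f) {
    out <- rep(NA_real_, nrow(wtab))
    a <- tapply(v[used], wkey[used], f)
    out[match(names(a), ukey)] <- as.vector(a)
    out
  }
  n_used <- agg(used, length); n_used[is.na(n_used)] <- 0
  cov_table <- do.call(rbind, lapply(seq_along(arts), function(j) {
    data.frame(
      participant = wtab$participant, group = grp[match(ukey, wkey)],
      word = wtab$word, articulator = arts[j],
      cov = agg(sizes[, j], function(x) {
        if (length(x) >= 2) as.numeric(size_cov(x)) else NA_real_
      }),
      n_used = n_used, included = wtab$included,
      stringsAsFactors = FALSE
    )
  }))
  duration_table <- data.frame(
    participant = wtab$participant, group = grp[match(ukey, wkey)],
    word = wtab$word,
    mean_frames = agg(dur, mean),
    mean_ms = agg(dur, mean) * 1000 / fps,
    n_valid = n_used, included = wtab$included,
    stringsAsFactors = FALSE
  )
  exclusions <- unique(trial_table[!trial_table$used,
                                   c("participant", "word", "trial",
                                     "fluent", "valid_window")])
  severity <- data.frame(
    participant = vapply(cohort$participants, `[[`, character(1), "id"),
    group = vapply(cohort$participants, `[[`, character(1), "group"),
    severity = vapply(cohort$participants, function(p) as.numeric(p$severity),
                      numeric(1)),
    stringsAsFactors = FALSE
  )
  list(cov_table = cov_table, duration_table = duration_table,
       trial_table = trial_table, exclusions = exclusions,
       severity = severity)
}
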