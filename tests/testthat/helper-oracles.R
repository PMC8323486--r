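# Independent oracles and shared fixtures for the test suite.

# Brute-force utterance-window finder: enumerates every run of
# above-threshold frames with explicit loops, then applies the
# longest-run / flanking-closure definition directly.
oracle_window <- function(ap, eps = 1, min_open = 3L) {
  ap[is.na(ap)] <- 0
  n <- length(ap)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (ap[i] > eps) {
      j <- i
      while (j < n && ap[j + 1L] > eps) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  lens <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
  keep <- which(lens >= min_open)
  if (!length(keep)) {
    return(list(start = NA_integer_, end = NA_integer_, valid = FALSE))
  }
  best <- runs[[keep[which.max(lens[keep])]]]
  if (best[1] == 1L || best[2] == n) {
    return(list(start = NA_integer_, end = NA_integer_, valid = FALSE))
  }
  list(start = best[1] - 1L, end = best[2] + 1L, valid = TRUE)
}

# Random aperture-like traces: runs of zeros and positive bumps with
# occasional sub-threshold noise openings.
random_trace <- function(n = 60L) {
  x <- numeric(n)
  k <- sample(0:3, 1)
  if (k > 0) {
    for (b in seq_len(k)) {
      len <- sample(1:12, 1)
      start <- sample(seq_len(max(n - len, 1)), 1)
      x[start:(start + len - 1L)] <- runif(len, 0.2, 12)
    }
  }
  x
}

# A small rendered phantom session reused by segmentation/tracking tests:
# two repetitions each of "mab" and "mabteebeebee", default blur/noise.
make_session <- function(noise_sd = 0.03, seed = 404L) {
  acq <- acquisition_params()
  phantom <- build_phantom(acq, shape_seed = 2L)
  reps <- vtkin:::with_seed(seed, c(
    synthesize_repetitions(gestural_score("mab"),
                           repetition_jitter(0.1, 0.08), 2L, acq),
    synthesize_repetitions(gestural_score("mabteebeebee"),
                           repetition_jitter(0.1, 0.08), 2L, acq)
  ))
  stack <- render_frames(phantom, reps, noise_sd = noise_sd, seed = seed + 1L)
  grid <- construct_grid(define_midline(phantom = phantom))
  n_fr <- frames_per_trial(acq)
  list(
    acq = acq, phantom = phantom, reps = reps, stack = stack, grid = grid,
    truth_traj = do.call(rbind, lapply(reps, `[[`, "traj")),
    frames_of_trial = function(tr) ((tr - 1L) * n_fr + 1L):(tr * n_fr)
  )
}

session_cache <- new.env(parent = emptyenv())

cached_session <- function() {
  if (is.null(session_cache$s)) {
    s <- make_session()
    s$raw <- detect_boundaries(s$stack, s$grid)
    s$smooth <- smooth_contours(s$raw)
    s$truth <- true_boundaries(s$phantom, s$stack$states, s$grid)
    session_cache$s <- s
  }
  session_cache$s
}
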