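test_that("movement size sums the trace over the inclusive window", {
  w <- segment_utterance(c(0, 5, 8, 5, 0), min_open_frames = 3)
  expect_equal(w[c("start", "end")], list(start = 1L, end = 5L))
  expect_equal(movement_size(c(0, 5, 8, 5, 0), w), 18)
  # linear in the trace
  expect_equal(movement_size(2 * c(0, 5, 8, 5, 0), w), 36)
  bad <- segment_utterance(rep(0, 5))
  expect_true(is.na(movement_size(rep(0, 5), bad)))
  expect_equal(attr(movement_size(rep(0, 5), bad), "reason"), "no opening")
})

test_that("the CoV is sample SD over mean and scale invariant", {
  expect_equal(size_cov(c(8, 10, 12)), 0.2)
  expect_equal(size_cov(rep(7, 10)), 0)
  vtkin:::with_seed(5, {
    for (i in 1:50) {
      x <- runif(sample(3:20, 1), 1, 100)
      c1 <- size_cov(x)
      expect_equal(size_cov(x * runif(1, 0.01, 100)), c1, tolerance = 1e-12)
      expect_gte(c1, 0)
    }
  })
  expect_true(is.na(size_cov(c(5))))
  expect_true(is.na(size_cov(c(-3, 1))))  # non-positive mean
})

test_that("durations count frames inclusively and convert to ms", {
  w <- list(start = 2L, end = 6L, valid = TRUE, reason = "")
  d <- duration_stats(list(w), frame_rate = 33.3)
  expect_equal(d$frames, 5)
  expect_equal(d$ms, 5 * 1000 / 33.3, tolerance = 1e-9)  # 150.15 ms
  many <- duration_stats(rep(list(w), 8), frame_rate = 100 / 3)
  expect_equal(many$mean_frames, 5)
  expect_equal(many$n_valid, 8)
})

test_that("the fluency rule excludes words below 6 usable repetitions", {
  mk <- function(n_ok) data.frame(
    participant = "p1", word = "mab", repetition = 1:10,
    fluent = c(rep(TRUE, n_ok), rep(FALSE, 10 - n_ok)),
    valid_window = TRUE
  )
  f5 <- apply_fluency_filter(mk(5))
  expect_false(f5$words$included)
  expect_match(f5$words$reason, "only 5 of 10")
  expect_false(any(f5$trials$used))
  f6 <- apply_fluency_filter(mk(6))
  expect_true(f6$words$included)
  expect_equal(sum(f6$trials$used), 6)
  f10 <- apply_fluency_filter(mk(10))
  expect_true(all(f10$trials$used))
  # an accurate window is required, not just fluency
  t2 <- mk(10); t2$valid_window[1:5] <- FALSE
  expect_false(apply_fluency_filter(t2)$words$included)
})

test_that("exclusion bookkeeping is complete", {
  trials <- expand.grid(repetition = 1:10, word = c("mab", "mabshibe"),
                        participant = c("p1", "p2"),
                        stringsAsFactors = FALSE)
  vtkin:::with_seed(8, {
    trials$fluent <- runif(nrow(trials)) > 0.3
    trials$valid_window <- runif(nrow(trials)) > 0.2
  })
  f <- apply_fluency_filter(trials)
  expect_equal(nrow(f$words), 4)
  expect_equal(sum(f$words$included) + sum(!f$words$included), 4)
  expect_true(all(nchar(f$words$reason[!f$words$included]) > 0))
})

test_that("the STI is zero for identical and affine-equivalent repetitions", {
  x <- sin(seq(0, pi, length.out = 40))
  expect_equal(as.numeric(sti(list(x, x, x))), 0)
  expect_lt(as.numeric(sti(list(x, 3 * x + 2, 0.5 * x - 1))), 1e-10)
})

test_that("time normalization matches an independent oracle on rescaled pairs", {
  # two repetitions of one shape at different durations: after z-scoring
  # and 1000-point resampling the only residual is the finite-sample
  # dependence of the z-transform, computed here by an independent
  # step-by-step oracle
  f <- function(n) sin(pi * seq(0, 1, length.out = n))
  reps <- list(f(51), f(101))
  grid <- seq(0, 1, length.out = 1000)
  z <- vapply(reps, function(x) {
    zx <- (x - mean(x)) / sd(x)
    approx(seq(0, 1, length.out = length(zx)), zx, grid)$y
  }, numeric(1000))
  idx <- seq(10, 990, by = 20)
  want <- sum(apply(z[idx, ], 1, sd))
  val <- as.numeric(sti(reps))
  expect_equal(val, want, tolerance = 1e-12)
  # and it is far below the STI of genuinely different repetitions
  g <- sin(2 * pi * seq(0, 1, length.out = 70))
  expect_lt(val, 0.1 * as.numeric(sti(list(f(60), g))))
})

test_that("zero-variance repetitions are dropped from the STI with a warning", {
  x <- sin(seq(0, pi, length.out = 30))
  expect_warning(v <- sti(list(x, x, rep(1, 30))), "zero-variance")
  expect_equal(attr(v, "n_used"), 2)
  expect_warning(v2 <- sti(list(rep(1, 30), rep(2, 30))), "zero-variance")
  expect_true(is.na(v2))
})

test_that("STI and CoV rank participants concordantly on well-resolved traces", {
  # the two indices measure related constructs, but the STI needs a
  # sampling rate that resolves the trajectory shape: trajectories are
  # synthesized at 250 Hz (the rate of the point-tracking literature the
  # STI comes from); at 33.3 fps the STI is dominated by frame-phase
  # noise, which is the stated reason for preferring the CoV there
  acq <- acquisition_params(frame_rate = 250)
  sc <- gestural_score("mabshaytiedoib")
  cvs <- seq(0.03, 0.3, length.out = 40)
  vtkin:::with_seed(21, {
    est <- t(vapply(cvs, function(cv) {
      reps <- synthesize_repetitions(sc, repetition_jitter(cv, cv / 2),
                                     n_reps = 10, acq = acq)
      wins <- lapply(reps, function(r) segment_utterance(r$traj[, "lips"]))
      sizes <- mapply(function(r, w) movement_size(r$traj[, "lips"], w),
                      reps, wins)
      segs <- mapply(function(r, w) {
        if (w$valid) r$traj[w$start:w$end, "lips"] else NULL
      }, reps, wins, SIMPLIFY = FALSE)
      segs <- Filter(Negate(is.null), segs)
      c(cov = as.numeric(size_cov(sizes)), sti = as.numeric(sti(segs)))
    }, numeric(2)))
  })
  expect_gt(cor(est[, "cov"], est[, "sti"], method = "spearman"), 0.7)
})
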