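lip_contours <- function(upper, lower, status) {
  ng <- 3
  n <- length(upper)
  vtkin:::new_contours(
    cbind(upper, matrix(5, n, ng - 1)), cbind(lower, matrix(-5, n, ng - 1)),
    cbind(status, matrix("ok", n, ng - 1)),
    structure(list(
      origins = cbind(c(10, 12, 14), 30), normals = cbind(0, c(-1, -1, -1)),
      tangents = cbind(1, c(0, 0, 0)), s = c(0, 2, 4),
      spacing_mm = 2, half_length_mm = 12, s_palate = Inf, s_larynx = Inf,
      arc_length_mm = 4), class = "vt_grid"),
    smoothed = TRUE, pixel_size_mm = 2
  )
}

test_that("lip aperture is the distance between the boundary points", {
  # upper point at (x, y0 - 3), lower at (x, y0 + 3): aperture 6 mm
  ct <- lip_contours(upper = 3, lower = -3, status = "ok")
  expect_equal(as.numeric(lip_aperture_trace(ct)), 6)
  ct0 <- lip_contours(upper = NA_real_, lower = NA_real_, status = "closed")
  expect_equal(as.numeric(lip_aperture_trace(ct0)), 0)
})

test_that("mostly-undetectable lip gridlines flag the trace unusable", {
  st <- rep("ok", 10); st[1:2] <- "invalid"
  ct <- lip_contours(upper = rep(3, 10), lower = rep(-3, 10), status = st)
  tr <- lip_aperture_trace(ct)
  expect_false(attr(tr, "usable"))
  expect_true(attr(lip_aperture_trace(ct, max_invalid_frac = 0.3), "usable"))
})

test_that("utterance segmentation follows the release/closure definition", {
  w <- segment_utterance(c(0, 0, 0, 5, 8, 5, 0, 0))
  expect_equal(w[c("start", "end", "valid")],
               list(start = 3L, end = 7L, valid = TRUE))
  expect_false(segment_utterance(rep(0, 20))$valid)
  expect_equal(segment_utterance(rep(0, 20))$reason, "no opening")
  expect_equal(segment_utterance(c(0, 0, 2, 5, 8, 9, 9))$reason,
               "no final closure")
  expect_equal(segment_utterance(c(5, 8, 5, 0, 0))$reason,
               "no initial closure")
  # sub-threshold wiggles and too-short openings are not utterances
  expect_false(segment_utterance(c(0, 0.9, 0, 0, 5, 8, 0, 0),
                                 min_open_frames = 3)$valid)
  w2 <- segment_utterance(c(0, 5, 5, 0, 0, 5, 8, 5, 5, 0),
                          min_open_frames = 3)
  expect_equal(c(w2$start, w2$end), c(5L, 10L))  # longest run wins
})

test_that("segmentation agrees with a brute-force oracle on random traces", {
  vtkin:::with_seed(31, {
    for (i in 1:300) {
      x <- random_trace()
      got <- segment_utterance(x)
      want <- oracle_window(x)
      expect_identical(got$valid, want$valid)
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
    }
  })
})

test_that("window start/end semantics hold on measured phantom traces", {
  s <- cached_session()
  ap <- lip_aperture_trace(s$smooth)
  for (tr in 1:4) {
    idx <- s$frames_of_trial(tr)
    w <- segment_utterance(ap[idx])
    expect_true(w$valid)
    expect_lte(ap[idx][w$start], 1)
    expect_gt(ap[idx][w$start + 1L], 1)
    expect_lte(ap[idx][w$end], 1)
    # within a frame of the generator's ground truth
    expect_lte(abs(w$start - s$reps[[tr]]$truth$start), 1)
    expect_lte(abs(w$end - s$reps[[tr]]$truth$end), 1)
  }
})

test_that("measured lip aperture tracks the ground truth", {
  s <- cached_session()
  ap <- lip_aperture_trace(s$smooth)
  expect_lt(max(abs(ap - s$truth_traj[, "lips"]), na.rm = TRUE), 1.5)
  stack0 <- render_frames(s$phantom, s$reps[[1]]$traj, noise_sd = 0)
  ap0 <- lip_aperture_trace(smooth_contours(detect_boundaries(stack0, s$grid)))
  expect_lt(max(abs(ap0 - s$reps[[1]]$traj[, "lips"]), na.rm = TRUE), 1)
})

test_that("tongue and velum gridlines are selected at the articulator centers", {
  s <- cached_session()
  ref_frames <- c(s$frames_of_trial(3), s$frames_of_trial(4))  # mabteebeebee
  selt <- select_tongue_gridline(s$smooth, ref_frames)
  selv <- select_velum_gridline(s$smooth)
  expect_lte(abs(s$grid$s[selt$gridline] - s$phantom$tongue_s), 4)
  expect_lte(abs(s$grid$s[selv$gridline] - s$phantom$velum_s), 4)
  # fallback mode is deterministic and announces itself
  expect_message(sel_fb <- select_tongue_gridline(s$smooth),
                 "global maximum")
  sel_fb2 <- suppressMessages(select_tongue_gridline(s$smooth))
  expect_identical(sel_fb$gridline, sel_fb2$gridline)
  expect_error(select_tongue_gridline(s$smooth, NULL, fallback = FALSE),
               "fallback disabled")
})

test_that("tongue and velum traces recover the programmed movements", {
  s <- cached_session()
  ref_frames <- c(s$frames_of_trial(3), s$frames_of_trial(4))
  tt <- tongue_trace(s$smooth, select_tongue_gridline(s$smooth, ref_frames))
  vv <- velum_trace(s$smooth, select_velum_gridline(s$smooth))
  expect_true(all(tt >= 0))
  expect_true(all(vv >= 0))
  expect_gt(cor(tt, s$truth_traj[, "tongue"]), 0.95)
  expect_gt(cor(vv, s$truth_traj[, "velum"]), 0.95)
})

test_that("the velum opens for the nasal and stays raised for oral vowels", {
  s <- cached_session()
  vv <- velum_trace(s$smooth, select_velum_gridline(s$smooth))
  r <- s$reps[[1]]; idx <- s$frames_of_trial(1)
  nasal <- idx[r$truth$start + 0:1]          # just after the /m/ release
  vowel <- idx[(r$truth$start + r$truth$end) %/% 2]  # mid-vowel
  expect_gt(mean(vv[nasal]), vv[vowel] + 0.5)
})

test_that("degenerate static articulators are handled explicitly", {
  n <- 6; ng <- 12
  grid <- structure(list(
    origins = cbind(seq_len(ng) * 4, 30), normals = cbind(0, rep(-1, ng)),
    tangents = cbind(1, rep(0, ng)), s = (seq_len(ng) - 1) * 4,
    spacing_mm = 4, half_length_mm = 12, s_palate = 20, s_larynx = 44,
    arc_length_mm = 44), class = "vt_grid")
  ct <- vtkin:::new_contours(matrix(5, n, ng), matrix(-5, n, ng),
                             matrix("ok", n, ng), grid,
                             smoothed = TRUE, pixel_size_mm = 2)
  expect_warning(sel <- select_velum_gridline(ct), "no velum movement")
  expect_equal(sel$gridline, which(grid$s > 20)[1])
  expect_equal(as.numeric(velum_trace(ct, sel)), rep(0, n))
  selt <- suppressMessages(select_tongue_gridline(ct))
  expect_equal(as.numeric(tongue_trace(ct, selt)), rep(0, n))
})
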