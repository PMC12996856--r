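test_that("build_series applies the placeholder and window rules", {
  seg <- toy_segments()
  frm <- toy_frames(seg, frame_rate = 4, value_fun = function(t) t)
  ds <- build_series(seg, frm, silence_profile = -4)
  expect_s3_class(ds, "dyad_series")
  expect_equal(nrow(ds$child), 20)  # ceil(10 / 0.5)
  expect_equal(dim(ds$child), dim(ds$adult))
  # adult silent during seconds 0-5: windows 1-10 hold the placeholder
  expect_equal(unname(ds$adult[1:10, 1]), rep(-4, 10))
  expect_equal(unname(ds$child[11:20, 1]), rep(-4, 10))
  # window value = mean of the frames in [t, t+0.5): frames at t, t+.25
  expect_equal(unname(ds$child[1, 1]), mean(c(0, 0.25)))
  expect_equal(unname(ds$child[2, 1]), mean(c(0.5, 0.75)))
})

test_that("concurrent vocalization assigns the same frames to both speakers", {
  seg <- data.frame(session_id = "s", t_start_s = 0, t_end_s = 1,
                    label = "BOTH", stringsAsFactors = FALSE)
  v <- c(1, 2, 3, 4)
  frm <- data.frame(session_id = "s", t_s = c(0, 0.25, 0.5, 0.75),
                    speaker = "BOTH", f1 = v, stringsAsFactors = FALSE)
  ds <- build_series(seg, frm)
  expect_equal(unname(ds$child[, 1]), c(mean(v[1:2]), mean(v[3:4])))
  expect_equal(ds$child, ds$adult)
})

test_that("frame counts per window follow the frame rate", {
  seg <- data.frame(session_id = "s", t_start_s = 0:1, t_end_s = 1:2,
                    label = "CHI", stringsAsFactors = FALSE)
  frm <- toy_frames(seg, frame_rate = 100, value_fun = function(t) t * 0 + 7)
  ds <- build_series(seg, frm)
  expect_equal(nrow(ds$child), 4)
  expect_equal(unname(ds$child[, 1]), rep(7, 4))  # 50 frames averaged each
})

test_that("segment validation catches gaps and unknown labels", {
  seg <- toy_segments()
  frm <- toy_frames(seg)
  bad_label <- seg; bad_label$label[3] <- "CHILD"
  expect_error(build_series(bad_label, frm), "unknown segment label.*CHILD")
  gap <- seg[-4, ]
  expect_error(build_series(gap, frm), "gap in segment coverage")
})

test_that("remove_long_silence deletes only supra-threshold joint silences", {
  # 120 s session with a 30 s joint silence in the middle
  lab <- c(rep("CHI", 40), rep("SIL", 30), rep("ADU", 50))
  seg <- data.frame(session_id = "s", t_start_s = 0:119, t_end_s = 1:120,
                    label = lab, stringsAsFactors = FALSE)
  ds <- build_series(seg, toy_frames(seg))
  out <- remove_long_silence(ds, threshold_s = 25)
  expect_equal(nrow(ds$child) - nrow(out$child), 60)
  expect_false(out$degenerate)

  # a 10 s silence is below threshold and kept
  lab2 <- c(rep("CHI", 50), rep("SIL", 10), rep("ADU", 60))
  seg2 <- data.frame(session_id = "s", t_start_s = 0:119, t_end_s = 1:120,
                     label = lab2, stringsAsFactors = FALSE)
  ds2 <- build_series(seg2, toy_frames(seg2))
  expect_equal(nrow(remove_long_silence(ds2, 25)$child), 240)

  # an entirely silent session degenerates to an empty flagged series
  seg3 <- data.frame(session_id = "s", t_start_s = 0:59, t_end_s = 1:60,
                     label = "SIL", stringsAsFactors = FALSE)
  frm3 <- data.frame(session_id = character(0), t_s = numeric(0),
                     speaker = character(0), f1 = numeric(0))
  empty <- remove_long_silence(build_series(seg3, frm3), 25)
  expect_true(empty$degenerate)
  expect_equal(nrow(empty$child), 0)

  expect_error(remove_long_silence(ds, threshold_s = 0), "threshold_s")
})

test_that("silence removal preserves window pairing and order", {
  set.seed(21)
  st <- simulate_study(tiny_config(seed = 5))
  s <- st$sessions[[1]]
  ds <- build_series(s$segments, s$frames)
  marked <- ds
  marked$child[, 1] <- seq_len(nrow(ds$child))      # index tracer
  marked$adult[, 1] <- seq_len(nrow(ds$adult)) + 0.5
  out <- remove_long_silence(marked, 5)
  expect_equal(out$adult[, 1], out$child[, 1] + 0.5)  # pairing intact
  expect_true(all(diff(out$child[, 1]) > 0))          # order intact
})

test_that("robust scaling matches the hand-computed example and is idempotent", {
  expect_equal(robust_scale(c(1, 2, 3, 4, 5)), c(-1, -0.5, 0, 0.5, 1))
  expect_error(robust_scale(rep(3, 10)), "zero IQR")
  expect_error(robust_scale(c(1, 2)), "at least 4")

  set.seed(2)
  x <- rlnorm(51)
  z <- robust_scale(x)
  expect_equal(median(z), 0)
  expect_equal(IQR(z, type = 7), 1)
})

test_that("dyad series scaling is per speaker and flags constant features", {
  seg <- toy_segments()
  frm <- toy_frames(seg, value_fun = function(t) t^1.5)
  frm$f2 <- 5  # constant during speech -> unscalable
  ds <- robust_scale(build_series(seg, frm))
  expect_true(ds$scaled)
  expect_equal(ds$unstable_features, "f2")
  spoken <- ds$child[ds$speaking_child, "f1"]
  expect_equal(median(spoken), 0)
  expect_equal(IQR(spoken, type = 7), 1)
  # silent windows keep the placeholder after scaling
  expect_equal(unname(ds$child[!ds$speaking_child, "f1"]),
               rep(-4, sum(!ds$speaking_child)))

  # child scaling never reads adult values: perturbing the adult's frames
  # leaves the child series bit-identical
  frm2 <- frm
  adu <- frm2$speaker == "ADU"
  frm2$f1[adu] <- exp(frm2$f1[adu] / 10)  # nonlinear: survives rescaling
  ds2 <- robust_scale(build_series(seg, frm2))
  expect_identical(ds$child, ds2$child)
  expect_false(isTRUE(all.equal(ds$adult, ds2$adult)))
})
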