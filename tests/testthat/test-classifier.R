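# Classifier ground truth on synthetic rotating phase fields.

test_that("a synthetic spiral yields exactly one singularity per frame", {
  run <- synthetic_spiral_run(nx = 40, ny = 40, n_frames = 40, period = 120)
  s <- find_phase_singularities(run)
  expect_gt(nrow(s), 0)
  per_frame <- table(s$t)
  expect_true(all(per_frame == 1))
  # singularity sits at the prescribed core (grid center), within one node
  expect_lt(mean(abs(s$ix - 20)), 1.5)
  expect_lt(mean(abs(s$iy - 20)), 1.5)
})

test_that("two prescribed cores yield two singularities per frame", {
  r1 <- synthetic_spiral_run(nx = 50, ny = 50, core = c(15, 25))
  r2 <- synthetic_spiral_run(nx = 50, ny = 50, core = c(35, 25))
  run <- r1
  # superpose phases by taking fields side by side: build a two-core field
  ix <- rep(seq_len(50), times = 50); iy <- rep(seq_len(50), each = 50)
  az <- atan2(iy - 25, ix - 15) + atan2(iy - 25, ix - 35)
  tt <- run$final$frame_times
  run$final$frames <- t(vapply(tt, function(t)
    -40 + 45 * cos(az - 2 * pi * t / 120), numeric(2500)))
  s <- find_phase_singularities(run)
  expect_true(all(table(s$t) == 2))
})

test_that("quiescent and uniformly paced fields contain no singularities", {
  run <- synthetic_spiral_run(nx = 30, ny = 30)
  tt <- run$final$frame_times
  run$final$frames <- t(vapply(tt, function(t)
    rep(-40 + 45 * cos(2 * pi * t / 120), 900), numeric(900)))  # uniform
  expect_equal(nrow(find_phase_singularities(run)), 0)
  expect_false(detect_wavebreak(run))
})

test_that("activation bookkeeping: no events in a quiescent run, stimulus count otherwise", {
  run <- synthetic_spiral_run(nx = 20, ny = 20)
  run$final$frames <- matrix(-88, nrow(run$final$frames),
                             ncol(run$final$frames))
  expect_equal(nrow(find_phase_singularities(run)), 0)
  acts <- detect_activations(run)
  expect_true(all(lengths(acts) == 0))
  expect_equal(count_extra_beats(run), 0)
})
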