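# Single-cell ionic model: gating curves, resting behavior, Euler updates.

test_that("tau_h has the required voltage structure and scales exactly", {
  p <- ctl()
  v_plateau <- seq(-30, 40, by = 5)
  expect_true(all(tau_h(v_plateau, p) < 1))
  v_all <- seq(-110, 60, by = 0.5)
  t0 <- tau_h(v_all, p)
  expect_true(all(t0 > 0))
  v_peak <- v_all[which.max(t0)]
  expect_gt(v_peak, -90)
  expect_lt(v_peak, -60)
  expect_gt(max(t0), 5)          # control peak about 7 ms
  expect_lt(max(t0), 9)
  # scaling identity: tauh_scale = 2 doubles the curve everywhere
  p2 <- model_params(c(tauh_scale = 2), base = p)
  expect_equal(tau_h(v_all, p2), 2 * t0, tolerance = 1e-12)
})

test_that("ionic currents respect reversal potentials and gating zeros", {
  p <- ctl()
  s <- cell_state(v = p[["e_na"]], h = 0.7, w = 0.9)
  expect_equal(ionic_currents(s, p)[["i_na"]], 0)
  s0 <- cell_state(v = -20, h = 0, w = 0.9)
  expect_equal(ionic_currents(s0, p)[["i_na"]], 0)
  cur <- ionic_currents(cell_state(-20, 0.5, 0.9), p)
  expect_equal(cur[["i_total"]],
               sum(cur[c("i_na", "i_cal", "i_kr", "i_ks", "i_k1", "i_to")]))
  # I_Ca,L activation window: negligible outside roughly (-30, -5) mV
  d <- vapply(c(-60, -40, 10, 30), function(v)
    abs(ionic_currents(cell_state(v, 0.5, 1), p)[["i_cal"]]), numeric(1))
  d_in <- abs(ionic_currents(cell_state(-17, 0.5, 1), p)[["i_cal"]])
  expect_true(all(d < 0.15 * d_in))
})

test_that("initial state is the standard initial condition", {
  p <- ctl()
  s <- initial_state(p)
  expect_identical(s[["v"]], -88)
  expect_equal(s[["h"]], h_inf(-88, p))
  expect_identical(s[["ca_d"]], 0)
  expect_true(s[["h"]] >= 0 && s[["h"]] <= 1)
  expect_true(s[["w"]] >= 0 && s[["w"]] <= 1)
})

test_that("rest is a fixed point and is stable over 10 s", {
  p <- ctl()
  s <- initial_state(p)
  s1 <- step_cell(s, p, i_stim = 0, dt = 0.001)
  expect_lt(abs(s1[["v"]] - s[["v"]]), 1e-9)
  long <- cardpes:::cell_run(p, s, stim_times = numeric(0), t_end = 10000,
                             dt = 0.005)
  expect_lt(abs(long$state[["v"]] + 88), 0.5)
})

test_that("step_cell matches halved-step integration to O(dt^2) and clips gates", {
  p <- ctl()
  s <- cell_state(-50, 0.4, 0.8, 0.1)
  one <- step_cell(s, p, i_stim = -30, dt = 0.002)
  half <- step_cell(step_cell(s, p, i_stim = -30, dt = 0.001), p,
                    i_stim = -30, dt = 0.001)
  expect_lt(abs(one[["v"]] - half[["v"]]), 5e-4)
  # forward-Euler overshoot of gates is clipped into [0, 1]
  fast <- model_params(c(th_floor = 1e-4, th_amp = 1e-4), base = p)
  s2 <- step_cell(cell_state(0, 0.9, 0.5), fast, dt = 0.01)
  expect_true(s2[["h"]] >= 0 && s2[["h"]] <= 1)
})

test_that("gates stay within [0, 1] along a paced trajectory", {
  st <- paced(ctl(), 400)
  tr <- steady_state_pace(ctl(), bcl = 400, n_beats = 2, record_dt = 0.5)$trace
  expect_true(all(tr[, "h"] >= 0 & tr[, "h"] <= 1))
  expect_true(all(tr[, "w"] >= 0 & tr[, "w"] <= 1))
  expect_true(all(tr[, "ca_d"] >= 0))
})

test_that("Euler APD converges: dt 0.001 vs 0.0005 within 0.5 ms", {
  p <- ctl()
  a1 <- cardpes:::cell_run(p, stim_times = 0, t_end = 500,
                           dt = 0.001)$beats$apd[1]
  a2 <- cardpes:::cell_run(p, stim_times = 0, t_end = 500,
                           dt = 0.0005)$beats$apd[1]
  expect_lt(abs(a1 - a2), 0.5)
})
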