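# PES engine: trace measurements, capture criterion, ERP search, beat
# structure.

test_that("measure_apd handles synthetic traces and degenerate inputs", {
  t <- seq(0, 200, by = 0.5)
  v <- ifelse(t >= 10 & t < 110, 0, -88)     # square pulse, 100 ms
  expect_equal(measure_apd(cbind(t = t, v = v)), 100, tolerance = 0.01)
  expect_error(measure_apd(cbind(t = t, v = rep(-88, length(t)))),
               "never crosses")
  v2 <- ifelse(t >= 10, 0, -88)              # depolarizes, never repolarizes
  expect_error(measure_apd(cbind(t = t, v = v2)), "repolarization")
})

test_that("capture criterion is strict at -100 uA/cm^2", {
  expect_true(capture_test_cell(-322))
  expect_false(capture_test_cell(-62))
  expect_false(capture_test_cell(-100))       # boundary: not captured
  expect_true(capture_test_cell(-100.0001))
})

test_that("no stimulus means no capture", {
  p <- ctl()
  r <- cardpes:::cell_run(p, stim_times = 0, t_end = 100, stim_amp = 0)
  expect_false(capture_test_cell(r$beats$peak_i_na[1]))
  proto0 <- protocol_spec(stim_amp = -1e-6)
  expect_error(run_pes_cell(p, proto0), "capture")
})

test_that("cell PES: beat ordering, APD restitution, ERP correctness", {
  pes <- pes_cell_of(ctl())
  expect_equal(pes$beat, c("S1", "S2", "S3", "S4"))
  # APD decreases from S1 and does not rebound beyond the 1-ms ERP grid
  expect_lt(pes$apd[2], pes$apd[1] - 5)
  expect_true(all(diff(pes$apd) < 0.5))
  expect_true(all(is.finite(pes$erp[-1])))

  # ERP search correctness against direct re-simulation: the interval one
  # increment below the ERP does not capture, the ERP does
  p <- ctl()
  proto <- protocol_spec()
  train <- cardpes:::cell_run(p, stim_times = seq(0, by = 400,
                                                  length.out = 7),
                              t_end = 7 * 400)
  branch <- train$state
  erp2 <- pes$erp[2]
  for (ci in c(erp2 - proto$erp_increment, erp2)) {
    r <- cardpes:::cell_run(p, branch, stim_times = c(0, ci),
                            t_end = ci + 60)
    got <- capture_test_cell(r$beats$peak_i_na[2])
    expect_identical(got, ci == erp2)
  }
})

test_that("premature peak I_Na is non-decreasing in coupling interval", {
  p <- ctl()
  train <- cardpes:::cell_run(p, stim_times = seq(0, by = 400,
                                                  length.out = 7),
                              t_end = 7 * 400)
  branch <- train$state
  cis <- seq(240, 360, by = 20)
  peaks <- vapply(cis, function(ci) {
    r <- cardpes:::cell_run(p, branch, stim_times = c(0, ci),
                            t_end = ci + 60)
    r$beats$peak_i_na[2]
  }, numeric(1))
  # larger DI -> larger |peak I_Na| (peaks are negative); a 0.5 uA/cm^2
  # allowance covers the slow diastolic-calcium drift between branches
  expect_true(all(diff(peaks) < 0.5))
  expect_lt(peaks[2] - peaks[1], -50)   # the refractory recovery step
})

test_that("takeoff-potential and upstroke measures work on sampled traces", {
  r <- cardpes:::cell_run(ctl(), stim_times = 0, t_end = 400,
                          record_dt = 0.05)
  tr <- r$trace
  expect_equal(measure_top(tr, 0), -88, tolerance = 0.01)
  # beat from full rest: delta TOP = 0 by construction
  dv <- measure_dvdt_max(tr, stim_onset = 0, stim_dur = 2)
  expect_gt(dv, 50)
})
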