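# Calibration machinery: fixed points, recovery, residual reporting.

test_that("calibrate_k_scale returns s = 1 when the target is the model's own APD", {
  p <- ctl()
  own <- cardpes:::steady_apd(p, bcl = 400)
  q <- calibrate_k_scale(p, affected = c("g_ks", "g_kr"), target_apd = own,
                         bcl = 400, tol = 0.5, bracket = c(0.7, 1.5))
  cal <- attr(q, "calibration")
  expect_lt(abs(cal$scale - 1), 0.02)
  expect_lt(abs(cal$apd_residual), 0.5)
})

test_that("calibrate_gna_dvdt recovers a perturbed g_na within 2 percent", {
  p <- ctl()
  target <- cardpes:::steady_dvdt(p, bcl = 400)
  pert <- cardpes:::scale_par(p, g_na = 1.10)
  q <- calibrate_gna_dvdt(pert, dvdt_target = target, bcl = 400, tol = 0.5)
  expect_lt(abs(q[["g_na"]] - p[["g_na"]]) / p[["g_na"]], 0.02)
})

test_that("bracket failures are reported with endpoint values", {
  p <- ctl()
  expect_error(
    calibrate_k_scale(p, affected = "g_ks", target_apd = 1000, bcl = 400,
                      bracket = c(0.9, 1.2)),
    "bracket")
})

test_that("calibration reports carry residuals and iteration counts", {
  p <- ctl()
  q <- calibrate_gna_dvdt(p, dvdt_target = 245, bcl = 400)
  cal <- attr(q, "calibration")
  expect_true(all(c("gna_factor", "dvdt_target", "dvdt_residual",
                    "iterations") %in% names(cal)))
  expect_lte(abs(cal$dvdt_residual), 2)
})
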