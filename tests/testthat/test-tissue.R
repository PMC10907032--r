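# Monodomain solvers: diffusion scaling, dimensional consistency, gradient
# sheet construction.

test_that("CV scales as sqrt(D) (within 3 percent on doubling)", {
  p <- ctl()
  cv1 <- measure_cv(p, length = 2, diffusion = 0.001)
  cv2 <- measure_cv(p, length = 2, diffusion = 0.002)
  expect_lt(abs(cv2 / cv1 - sqrt(2)), 0.03 * sqrt(2))
})

test_that("zero diffusion decouples tissue into the 0-D trajectory", {
  p <- ctl()
  nx <- 8
  r <- cardpes:::tissue_run(p, nx = nx,
                            dx = 0.01, dt = 0.001, diffusion = 0,
                            stim_nodes = 0:(nx - 1), stim_times = 0,
                            t_end = 450, rec_node = 3, rec_dt = 0.5)
  cell <- cardpes:::cell_run(p, stim_times = 0, t_end = 450)
  apd_tissue <- r$down[1, 4] - r$up[1, 4]
  expect_lt(abs(apd_tissue - cell$beats$apd[1]), 0.5)
})

test_that("a uniform unstimulated sheet stays spatially uniform", {
  p <- ctl()
  r <- cardpes:::tissue_run(p, nx = 10,
                            ny = 10, dx = 0.04, dt = 0.01,
                            stim_nodes = integer(0), stim_times = numeric(0),
                            t_end = 50)
  expect_lt(diff(range(r$state[1, ])), 1e-9)
})

test_that("plane-wave CV in a uniform sheet matches the cable within 5 percent", {
  p <- ctl()
  cv_cable <- measure_cv(p, length = 2, dx = 0.02, dt = 0.01)
  # sheet stimulated along the full left edge -> plane wave
  nx <- 100; ny <- 20
  r <- cardpes:::tissue_run(p, nx = nx, ny = ny, dx = 0.02, dt = 0.01,
                            stim_nodes = as.integer(outer(0:4, (0:(ny - 1)) * nx,
                                                          "+")),
                            stim_times = 0, t_end = 60)
  mid <- (ny %/% 2) * nx
  t1 <- r$up[1, mid + 41]; t2 <- r$up[1, mid + 61]
  cv_sheet <- 20 * 0.02 / (t2 - t1)
  expect_lt(abs(cv_sheet - cv_cable) / cv_cable, 0.05)
})

test_that("gradient sheet carries corner and center values exactly", {
  p <- ctl()
  hf <- hf_params()
  fld <- build_gradient_sheet(p, hf, length = 2, dx = 0.04)
  n <- fld$nx
  pn <- field_pnode(fld)
  co <- unclass(p)[cardpes:::.node_par_names]
  expect_equal(unname(pn[, 1]), unname(co))            # bottom-left
  expect_equal(unname(pn[, n * n]), unname(co))        # top-right
  mid_ix <- n %/% 2 + 1L           # node nearest the tent peak
  mid <- (mid_ix - 1L) * n + mid_ix
  f_mid <- 1 - abs(2 * (mid_ix - 1) / (n - 1) - 1)
  ce <- unclass(hf)[cardpes:::.node_par_names]
  expect_equal(unname(pn["g_k1", mid]),
               unname(co[["g_k1"]] + (ce[["g_k1"]] - co[["g_k1"]]) * f_mid))
  # no negative conductances anywhere
  expect_true(all(pn[1:6, ] >= 0))
  # mirror symmetry of the construction: reflecting both axes maps the
  # parameter field onto itself
  m <- matrix(pn["g_kr", ], n, n)
  expect_equal(m, m[n:1, ][, n:1])
})

test_that("gradient sheets expose the pyramid symmetry in unique parameterizations", {
  p <- ctl()
  hf <- hf_params()
  fld <- build_gradient_sheet(p, hf, length = 0.8, dx = 0.04)  # 20 x 20
  n <- fld$nx
  uniq <- unique(apply(field_pnode(fld), 2, paste, collapse = ","))
  expect_equal(length(uniq), (n / 2)^2)   # tent symmetry pairs edge nodes
})

test_that("uniform sheet has zero APD gradient", {
  run <- list(apd_map = matrix(250, 10, 10), field = list(dx = 0.04))
  expect_equal(measure_apd_gradient(run), 0)
})


test_that("diastolic calcium accumulates with pacing rate", {
  for (p in list(ctl(), hf_params())) {
    slow <- tail(steady_state_pace(p, bcl = 2000, n_beats = 12)$beats$ca_pre, 1)
    fast <- tail(steady_state_pace(p, bcl = 333, n_beats = 12)$beats$ca_pre, 1)
    expect_gt(fast, slow)
    # roughly threefold accumulation at 3 Hz relative to slow pacing
    expect_gt(fast / slow, 2)
    expect_lt(fast / slow, 4)
  }
})
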