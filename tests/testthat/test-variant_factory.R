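# Variant construction algebra (ratios, axes enumeration, composition).

test_that("HF applies the literature current reductions", {
  p <- ctl()
  hf <- hf_params()
  expect_equal(hf[["g_ks"]] / p[["g_ks"]], 0.42)
  expect_equal(hf[["g_k1"]] / p[["g_k1"]], 0.59)
  expect_equal(hf[["g_to"]] / p[["g_to"]], 0.56)
  expect_equal(hf[["g_cal"]] / p[["g_cal"]], 0.75)
  expect_lt(hf[["g_na"]], p[["g_na"]])    # g_Na reduced toward dV/dt 180
  expect_equal(hf[["g_kr"]], p[["g_kr"]]) # I_Kr untouched by HF
  # scaling of zero conductances stays zero
  z <- model_params(setNames(rep(0, 6),
                             c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to")),
                    base = p)
  expect_true(all(unclass(apply_hf(z))[c("g_ks", "g_k1", "g_to", "g_cal")] == 0))
})

test_that("the three binary axes enumerate eight distinct AM variants", {
  p <- ctl()
  vs <- lapply(1:8, am_params)
  # distinct parameterizations
  key <- vapply(vs, function(q)
    paste(signif(unclass(q), 8), collapse = ","), character(1))
  expect_equal(length(unique(key)), 8)
  # index round trip
  for (i in 1:8)
    expect_equal(cardpes:::am_index(am_axes_from_index(i)), i)
  # K block ratios present (relative to the common uniform scale)
  am_k1 <- vs[[5]]  # k1_block = TRUE, others FALSE
  s <- am_k1[["g_ks"]] / (p[["g_ks"]] * 0.61)
  expect_equal(am_k1[["g_kr"]] / (p[["g_kr"]] * 0.45), s)
  expect_equal(am_k1[["g_k1"]] / (p[["g_k1"]] * 0.36), s)
  am_nok1 <- vs[[1]]
  expect_equal(am_nok1[["g_k1"]], p[["g_k1"]])  # no I_K1 block on this axis
  # availability shift only on the avail_shift axis
  expect_equal(vs[[2]][["eh_shift"]], -10.8)
  expect_equal(vs[[1]][["eh_shift"]], 0)
})

test_that("DS scales I_Kr by ~23 percent and doubles TauH", {
  p <- ctl()
  ds <- ds_params()
  f <- ds[["g_kr"]] / p[["g_kr"]]
  expect_gt(f, 0.74); expect_lt(f, 0.80)
  expect_equal(ds[["tauh_scale"]], 2 * p[["tauh_scale"]])
  expect_equal(ds[["g_na"]], p[["g_na"]])
})

test_that("AM' overwrites tauh_scale with 2.0 and keeps everything else", {
  am3 <- am_params(3)
  am3p <- apply_tauh_prime(am3)
  expect_equal(am3p[["tauh_scale"]], 2.0)
  others <- setdiff(cardpes:::.param_names, "tauh_scale")
  expect_equal(unclass(am3p)[others], unclass(am3)[others])
  expect_error(apply_tauh_prime(ctl()), "AM variant")
})

test_that("HF + drug composition is multiplicative, additive in eh_shift, and order-independent", {
  p <- ctl()
  hf <- hf_params(); am2 <- am_params(2)
  d_hf <- variant_deltas(hf, p); d_am <- variant_deltas(am2, p)
  both <- compose_hf_drug(p, d_hf, d_am)
  expect_equal(both[["g_k1"]],
               p[["g_k1"]] * d_hf$factors[["g_k1"]] * d_am$factors[["g_k1"]])
  expect_equal(both[["eh_shift"]], -10.8)
  swapped <- compose_hf_drug(p, d_am, d_hf)
  expect_equal(as.numeric(both), as.numeric(swapped))
  # identity composition: drug = none reproduces HF exactly
  alone <- compose_hf_drug(p, d_hf)
  expect_equal(as.numeric(alone), as.numeric(hf))
  # double application is not idempotent
  twice <- apply_hf(hf)
  expect_false(isTRUE(all.equal(twice[["g_ks"]], hf[["g_ks"]])))
})

test_that("the variant registry builds every documented label", {
  p <- ctl()
  for (lab in c("hf", "am5", "am5p", "ds", "hf+am3", "hf+ds", "hf+am3p")) {
    v <- make_variant(lab, control = p)
    expect_s3_class(v, "model_params")
    expect_equal(variant_label(v), lab)
  }
  expect_error(make_variant("am9"), "unknown")
  hfam3 <- make_variant("hf+am3", control = p)
  am3 <- make_variant("am3", control = p)
  hf <- make_variant("hf", control = p)
  expect_equal(hfam3[["g_ks"]] / p[["g_ks"]],
               (am3[["g_ks"]] / p[["g_ks"]]) * (hf[["g_ks"]] / p[["g_ks"]]))
})
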