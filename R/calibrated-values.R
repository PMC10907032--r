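# Stored outputs of the calibration module (see calibration.R), so variants
# can be constructed without re-running the bisections. Each value is the
# converged result of the corresponding calibrate_* call on the default
# control shapes; re-derive with calibrate = TRUE in the variant factory.

.calibrated <- new.env(parent = emptyenv())

# g_Na factor taking the control cell to dV/dt_max 180 mV/ms after the HF
# potassium/calcium reductions
.calibrated$hf_gna_factor <- 0.762500

# first-pass uniform scales on the AM-affected potassium conductances
# reaching a cell APD of 298 ms at BCL 400 (with and without I_K1 block);
# the per-variant s_total below includes the post-solve re-polish
.calibrated$am_scale_k1 <- 1.560938
.calibrated$am_scale_nok1 <- 1.412500

# I_Kr factor reaching the DS cell APD of 265 ms at BCL 400
.calibrated$ds_kr_factor <- 0.792500

# per-variant (total g_Na factor, tauh_scale, total K scale) from the
# iterated K-scale / (g_Na, TauH) calibration; index = am_index(axes)
.calibrated$am <- list(
  c(gna_factor = 0.735522, tauh_scale = 32.077544, s_total = 1.366152),
  c(gna_factor = 0.932705, tauh_scale = 22.865974, s_total = 1.355117),
  c(gna_factor = 0.615804, tauh_scale = 22.865974, s_total = 1.366152),
  c(gna_factor = 0.777776, tauh_scale = 22.865974, s_total = 1.355117),
  c(gna_factor = 0.735522, tauh_scale = 22.865974, s_total = 1.528011),
  c(gna_factor = 0.932705, tauh_scale = 22.865974, s_total = 1.515817),
  c(gna_factor = 0.615804, tauh_scale = 22.865974, s_total = 1.521914),
  c(gna_factor = 0.802979, tauh_scale = 11.618950, s_total = 1.515817))
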