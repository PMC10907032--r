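# Shared fixtures: heavier objects are built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ctl <- function() memo("ctl", make_control())

hf_params <- function() memo("hf", apply_hf(ctl()))

ds_params <- function() memo("ds", apply_ds(ctl()))

am_params <- function(i) {
  memo(paste0("am", i), apply_am(ctl(), am_axes_from_index(i)))
}

# steady paced state caches
paced <- function(p, bcl, n = 8) {
  key <- paste0("pace_", attr(p, "label"), "_", bcl, "_", n)
  memo(key, steady_state_pace(p, bcl = bcl, n_beats = n))
}

pes_cell_of <- function(p, ...) {
  key <- paste0("pes_", attr(p, "label"))
  memo(key, run_pes_cell(p, protocol_spec(...)))
}

# short protocol for cable tests (3 S1, 2 premature beats): cable dynamics
# reach steady diastole quickly at BCL 400
cable_proto <- function() protocol_spec(n_s1 = 3, n_premature = 2)
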