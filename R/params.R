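# Model parameter container (ModelParams) and cell state (CellState).

# Order must match the C++ kernels in src/core.cpp.
.param_names <- c(
  "g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to",
  "e_na", "e_ca", "e_k",
  "eh_mid", "eh_shift", "kh", "tauh_scale",
  "tau_w", "ca_gain", "ca_decay", "ca_alpha",
  "vm", "km",
  "vd", "kd",
  "vw", "kw",
  "vk1", "kk1",
  "vkr", "kkr", "vkr_r", "kkr_r",
  "vks", "kks",
  "vto", "kto",
  "th_floor", "th_amp", "th_mid", "th_sig", "th_sig_l", "th_up")

#' Default control parameterization
#'
#' Returns the package's baseline ("control") human ventricular cell
#' parameterization. The voltage-curve shape constants are fixed properties of
#' the model; the conductances are the values produced by
#' \code{\link{calibrate_control}} run at the reference tolerances (cell APD
#' 288 ms at BCL 1000 ms, maximal upstroke velocity 245 mV/ms), stored here so
#' that variants can be constructed without re-running the calibration.
#'
#' @return A \code{model_params} object.
#' @export
default_control_params <- function() {
  p <- c(
    g_na = 4.4475591,
    g_cal =   0.08491,
    g_kr = 0.02894708,
    g_ks = 0.032869253,
    g_k1 =       0.6,
    g_to =   0.04145,
    e_na =        65,
    e_ca =        50,
    e_k =       -88,
    eh_mid =       -71,
    eh_shift =         0,
    kh =         5,
    tauh_scale =         1,
    tau_w =       195,
    ca_gain =    0.0012,
    ca_decay =   0.00022,
    ca_alpha =      0.05,
    vm =       -40,
    km =       5.5,
    vd =     -17.5,
    kd =     8.914,
    vw =    -37.15,
    kw =      4.61,
    vk1 =       -70,
    kk1 =         3,
    vkr =       -45,
    kkr =       5.5,
    vkr_r =     -19.1,
    kkr_r =        11,
    vks =    -13.35,
    kks =         9,
    vto =    -5.368,
    kto =         8,
    th_floor =       0.3,
    th_amp =       6.6,
    th_mid =       -72,
    th_sig =        34,
    th_sig_l =       3.5,
    th_up =         0)
  model_params(p, label = "control")
}

#' Construct a model parameter set
#'
#' @param par named numeric vector covering all model parameters (any subset;
#'   missing entries are filled from \code{\link{default_control_params}}
#'   shapes when \code{base} is supplied).
#' @param label variant name carried through results.
#' @param base optional \code{model_params} to take unspecified entries from.
#' @return A \code{model_params} object (named numeric vector, classed).
#' @export
model_params <- function(par, label = "custom", base = NULL) {
  if (!is.null(base)) {
    stopifnot(inherits(base, "model_params"))
    full <- unclass(base)
    full[names(par)] <- par
    par <- full
  }
  if (!all(.param_names %in% names(par)))
    stop("missing parameters: ",
         paste(setdiff(.param_names, names(par)), collapse = ", "))
  p <- structure(as.numeric(par[.param_names]), names = .param_names,
                 class = "model_params", label = label)
  validate_params(p)
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> variant:", attr(x, "label"), "\n")
  cond <- x[c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to")]
  cat("  conductances:", paste(names(cond), signif(cond, 4), sep = "=",
                               collapse = "  "), "\n")
  cat(sprintf("  tauh_scale=%.4g  eh_shift=%.3g mV\n",
              x[["tauh_scale"]], x[["eh_shift"]]))
  invisible(x)
}

#' Validate model parameter invariants
#'
#' Conductances must be non-negative; tauh_scale, kh and tau_w strictly
#' positive. Called by the constructor; exported for direct use on edited
#' vectors.
#' @param p a \code{model_params} object.
#' @return \code{p}, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  g <- p[c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to")]
  if (any(!is.finite(p))) stop("non-finite model parameter")
  if (any(g < 0)) stop("negative conductance: ",
                       paste(names(g)[g < 0], collapse = ", "))
  if (p[["tauh_scale"]] <= 0) stop("tauh_scale must be > 0")
  if (p[["kh"]] <= 0) stop("kh must be > 0")
  if (p[["tau_w"]] <= 0) stop("tau_w must be > 0")
  invisible(p)
}

#' @export
`$.model_params` <- function(x, name) x[[name]]

# internal: modify parameters, keep class/label
set_par <- function(p, ..., label = attr(p, "label")) {
  v <- c(...)
  q <- unclass(p)
  q[names(v)] <- v
  model_params(q, label = label)
}

scale_par <- function(p, ..., label = attr(p, "label")) {
  v <- c(...)
  q <- unclass(p)
  q[names(v)] <- q[names(v)] * v
  model_params(q, label = label)
}

#' Variant label of a parameter set or result
#' @param x object carrying a variant label.
#' @return character scalar.
#' @export
variant_label <- function(x) attr(x, "label")

#' Construct a cell state
#'
#' @param v membrane potential (mV); \code{h}, \code{w} gates in [0, 1];
#'   \code{ca_d} diastolic-calcium memory (arbitrary units, >= 0);
#'   \code{t} time (ms).
#' @return A \code{cell_state} named numeric vector.
#' @export
cell_state <- function(v, h, w, ca_d = 0, t = 0) {
  if (!is.finite(v)) stop("v must be finite")
  if (h < 0 || h > 1) stop("h outside [0, 1]")
  if (w < 0 || w > 1) stop("w outside [0, 1]")
  if (ca_d < 0) stop("ca_d must be >= 0")
  structure(c(v = v, h = h, w = w, ca_d = ca_d, t = t), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> t=%.3f ms  v=%.2f mV  h=%.4f  w=%.4f  ca_d=%.4g\n",
              x[["t"]], x[["v"]], x[["h"]], x[["w"]], x[["ca_d"]]))
  invisible(x)
}
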