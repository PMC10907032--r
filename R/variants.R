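# Variant factory: control, heart failure (HF), amiodarone (AM1-AM8, AM'),
# d-sotalol (DS), and multiplicative HF + drug combinations.

# Fixed literature block ratios (fractions of current remaining).
.hf_ratios <- c(g_ks = 0.42, g_k1 = 0.59, g_to = 0.56, g_cal = 0.75)
.am_k_ratios <- c(g_ks = 0.61, g_kr = 0.45, g_k1 = 0.36)
.ds_kr_ratio <- 0.77
.am_avail_shift <- -10.8

# Calibrated per-variant values live in .calibrated (see calibrated-values.R),
# frozen from calibrate_* runs at the reference targets; regenerated by the
# calibration module at run time when calibrate = TRUE.

#' Calibrated control model
#'
#' The control parameterization: shapes from
#' \code{\link{default_control_params}}, conductances calibrated so that the
#' steady-state cell APD at BCL 1000 ms is 288 ms and the maximal upstroke
#' velocity is 245 mV/ms.
#'
#' @param calibrate if \code{TRUE}, re-run \code{\link{calibrate_control}}
#'   instead of using the stored calibrated values.
#' @return a \code{model_params} object labelled \code{"control"}.
#' @export
make_control <- function(calibrate = FALSE) {
  if (calibrate) calibrate_control(default_control_params())
  else default_control_params()
}

#' Amiodarone axes
#'
#' The three binary axes generating the eight AM variants:
#' \code{k1_block} (whether I_K1 is reduced), \code{dvdt_reduced} (whether the
#' upstroke-velocity target is lowered from 245 to 205 mV/ms), and
#' \code{avail_shift} (whether the availability curve is shifted by -10.8 mV).
#' Variant index = 1 + 4*k1_block + 2*dvdt_reduced + avail_shift, a canonical
#' enumeration (the original labels AM1-AM8 are not tied to printed axes).
#'
#' @param k1_block,dvdt_reduced,avail_shift logicals.
#' @return named logical vector of length 3.
#' @export
am_axes <- function(k1_block = FALSE, dvdt_reduced = FALSE,
                    avail_shift = FALSE) {
  c(k1_block = isTRUE(k1_block), dvdt_reduced = isTRUE(dvdt_reduced),
    avail_shift = isTRUE(avail_shift))
}

#' @rdname am_axes
#' @param i variant index in 1..8.
#' @export
am_axes_from_index <- function(i) {
  stopifnot(i >= 1, i <= 8)
  b <- i - 1L
  am_axes(k1_block = b >= 4, dvdt_reduced = (b %% 4) >= 2,
          avail_shift = (b %% 2) == 1)
}

am_index <- function(axes) {
  1L + 4L * axes[["k1_block"]] + 2L * axes[["dvdt_reduced"]] +
    1L * axes[["avail_shift"]]
}

#' Apply heart-failure remodelling
#'
#' Scales the repolarization currents by the literature ratios (I_Ks -58
#' percent, I_K1 -41, I_to -44, I_Ca,L -25) and reduces g_Na so that the
#' steady-state cell dV/dt_max matches the value measured in failing human
#' tissue (180 mV/ms). With \code{calibrate = FALSE} the stored calibrated
#' g_Na factor is used; with \code{TRUE} the bisection is re-run.
#'
#' @param p control-like \code{model_params}.
#' @param dvdt_target upstroke-velocity target (mV/ms).
#' @param calibrate re-run the g_Na calibration.
#' @return \code{model_params} labelled from \code{p}'s label.
#' @export
apply_hf <- function(p, dvdt_target = 180, calibrate = FALSE) {
  q <- scale_par(p, .hf_ratios, label = paste0(attr(p, "label"), "+hf"))
  q <- set_label(q, sub("^control\\+", "", attr(q, "label")))
  if (calibrate) {
    q <- calibrate_gna_dvdt(q, dvdt_target = dvdt_target, bcl = 400)
  } else {
    q <- scale_par(q, g_na = .calibrated$hf_gna_factor)
  }
  q
}

#' Apply amiodarone block for a given axes combination
#'
#' Applies the chronic potassium-block ratios (I_Ks -39 percent, I_Kr -55,
#' and I_K1 -64 when \code{k1_block}), multiplies the AM-affected potassium
#' conductances by the uniform scale calibrated to a cell APD of 298 ms at
#' BCL 400 ms, applies the -10.8 mV availability shift when
#' \code{avail_shift}, and sets (g_Na, tauh_scale) by the simultaneous
#' calibration to the upstroke-velocity target (205 mV/ms when
#' \code{dvdt_reduced}, else 245) and a post-repolarization refractoriness of
#' 8 ms (mean over S2-S4).
#'
#' @param p control-like \code{model_params}.
#' @param axes an \code{\link{am_axes}} vector.
#' @param calibrate re-run the calibrations instead of using stored values.
#' @param prime if \code{TRUE}, build the AM' variant: identical potassium
#'   block and g_Na, but \code{tauh_scale} overwritten to 2.0 (no PRR
#'   re-calibration).
#' @return \code{model_params} labelled \code{"am<i>"} (or \code{"am<i>p"}).
#' @export
apply_am <- function(p, axes = am_axes(), calibrate = FALSE, prime = FALSE) {
  idx <- am_index(axes)
  lab <- paste0("am", idx, if (prime) "p" else "")
  base_lab <- attr(p, "label")
  lab <- if (identical(base_lab, "control")) lab else paste0(base_lab, "+", lab)

  ratios <- .am_k_ratios
  if (!axes[["k1_block"]]) ratios <- ratios[setdiff(names(ratios), "g_k1")]
  q <- scale_par(p, ratios, label = lab)

  if (calibrate) {
    ks <- calibrate_k_scale(q, affected = names(ratios), target_apd = 298,
                            bcl = 400)
    s <- attr(ks, "calibration")$scale
    q <- ks
  } else {
    cal0 <- .calibrated$am[[idx]]
    s <- if (!is.na(cal0["s_total"])) cal0[["s_total"]] else
      if (axes[["k1_block"]]) .calibrated$am_scale_k1 else
        .calibrated$am_scale_nok1
    q <- scale_par(q, setNames(rep(s, length(ratios)), names(ratios)))
  }

  if (axes[["avail_shift"]]) q <- set_par(q, eh_shift = .am_avail_shift)

  if (prime) {
    gna_f <- .calibrated$am[[idx]]["gna_factor"]
    q <- scale_par(q, g_na = gna_f)
    q <- set_par(q, tauh_scale = 2.0)
  } else if (calibrate) {
    dvdt_target <- if (axes[["dvdt_reduced"]]) 205 else 245
    q <- calibrate_gna_tauh(q, dvdt_target = dvdt_target, prr_target = 8)
    # the g_Na/TauH solve shifts the APD slightly; re-polish the uniform K
    # scale back to the 298-ms target, then re-solve (g_Na, TauH) once more
    # so the PRR and upstroke targets hold on the finished variant
    q2 <- calibrate_k_scale(q, affected = names(ratios), target_apd = 298,
                            bcl = 400)
    s2 <- attr(q2, "calibration")$scale
    q <- calibrate_gna_tauh(q2, dvdt_target = dvdt_target, prr_target = 8)
    cal <- attr(q, "calibration")
    q <- cal_report(q, scale = s * s2,
                    gna_factor = q[["g_na"]] / p[["g_na"]],
                    tauh_scale = cal$tauh_scale)
  } else {
    cal <- .calibrated$am[[idx]]
    q <- scale_par(q, g_na = cal[["gna_factor"]])
    q <- set_par(q, tauh_scale = cal[["tauh_scale"]])
  }
  q
}

#' Apply d-sotalol
#'
#' Pure class III block plus slowed recovery of sodium inactivation:
#' g_Kr is reduced by 23 percent (the factor may be re-tuned within 3
#' percentage points so the steady-state cell APD at BCL 400 ms is 265 ms,
#' mirroring how the block was chosen against the clinical 11 percent APD
#' increase) and tauh_scale is doubled.
#'
#' @param p control-like \code{model_params}.
#' @param calibrate re-tune the I_Kr factor to APD 265 ms within [0.74, 0.80].
#' @return \code{model_params} labelled \code{"ds"}.
#' @export
apply_ds <- function(p, calibrate = FALSE) {
  base_lab <- attr(p, "label")
  lab <- if (identical(base_lab, "control")) "ds" else paste0(base_lab, "+ds")
  f <- if (calibrate) NULL else .calibrated$ds_kr_factor
  q <- scale_par(p, g_kr = if (is.null(f)) .ds_kr_ratio else f, label = lab)
  q <- scale_par(q, tauh_scale = 2.0)
  if (calibrate) {
    q <- calibrate_kr_factor(q, target_apd = 265, bcl = 400,
                             bounds = c(0.74, 0.80) / .ds_kr_ratio)
  }
  q
}

#' Remove the AM slowing of sodium-inactivation recovery (AM' variants)
#'
#' Overwrites \code{tauh_scale} with 2.0 (twice control, matching the DS
#' change) while retaining every other AM parameter; deliberately not
#' re-calibrated to the clinical PRR values.
#'
#' @param am_params an AM or HF+AM \code{model_params}.
#' @return \code{model_params} with label suffixed \code{"p"}.
#' @export
apply_tauh_prime <- function(am_params) {
  lab <- attr(am_params, "label")
  if (!grepl("am", lab)) stop("apply_tauh_prime expects an AM variant")
  set_par(am_params, tauh_scale = 2.0,
          label = if (grepl("p$", lab)) lab else paste0(lab, "p"))
}

#' Parameter deltas of a variant relative to a base
#'
#' Expresses a variant as multiplicative conductance/tauh factors plus the
#' additive availability shift, the representation in which independent
#' disease and drug effects compose.
#'
#' @param variant,base \code{model_params} objects.
#' @return list with \code{factors} (named multiplicative), \code{eh_shift}
#'   (additive, mV) and \code{tauh_factor} (multiplicative).
#' @export
variant_deltas <- function(variant, base) {
  gn <- c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to")
  f <- unclass(variant)[gn] / unclass(base)[gn]
  list(factors = f,
       eh_shift = variant[["eh_shift"]] - base[["eh_shift"]],
       tauh_factor = variant[["tauh_scale"]] / base[["tauh_scale"]],
       label = attr(variant, "label"))
}

#' Compose independent effects multiplicatively
#'
#' Conductance factors multiply, availability shifts add, tauh factors
#' multiply — disease and drug assumed independent. Drug deltas are the ones
#' calibrated on the control base; they are not re-calibrated on HF.
#'
#' @param base \code{model_params} the deltas act on (usually control).
#' @param ... one or more delta lists from \code{\link{variant_deltas}}.
#' @param label label for the result.
#' @return composed \code{model_params}.
#' @export
compose_hf_drug <- function(base, ..., label = NULL) {
  deltas <- list(...)
  f <- setNames(rep(1, 6), c("g_na", "g_cal", "g_kr", "g_ks", "g_k1", "g_to"))
  sh <- 0; tf <- 1
  labs <- character()
  for (d in deltas) {
    f <- f * d$factors
    sh <- sh + d$eh_shift
    tf <- tf * d$tauh_factor
    labs <- c(labs, d$label)
  }
  if (is.null(label)) label <- paste(labs, collapse = "+")
  q <- scale_par(base, f, label = label)
  q <- set_par(q, eh_shift = base[["eh_shift"]] + sh,
               tauh_scale = base[["tauh_scale"]] * tf)
  q
}

set_label <- function(p, label) { attr(p, "label") <- label; p }

#' Variant registry
#'
#' Builds any named variant from its label: \code{"control"}, \code{"hf"},
#' \code{"am1"}..\code{"am8"}, \code{"am1p"}..\code{"am8p"}, \code{"ds"}, and
#' HF combinations \code{"hf+am3"}, \code{"hf+am3p"}, \code{"hf+ds"}, etc.
#' Drug effects are calibrated on the control base and composed
#' multiplicatively onto HF.
#'
#' @param label variant label string.
#' @param control the control parameterization to build from.
#' @param calibrate re-run calibrations (slow) instead of stored values.
#' @return \code{model_params}.
#' @export
make_variant <- function(label, control = make_control(), calibrate = FALSE) {
  label <- tolower(label)
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  if (identical(parts, "control")) return(control)
  hf <- "hf" %in% parts
  drug <- setdiff(parts, c("hf", "control"))
  if (length(drug) > 1) stop("at most one drug in a variant label")
  dp <- NULL
  if (length(drug) == 1) {
    d <- drug[[1]]
    if (d == "ds") dp <- apply_ds(control, calibrate = calibrate)
    else if (grepl("^am[1-8]p?$", d)) {
      idx <- as.integer(substr(d, 3, 3))
      dp <- apply_am(control, am_axes_from_index(idx), calibrate = calibrate,
                     prime = grepl("p$", d))
    } else stop("unknown variant label: ", label)
  }
  if (!hf) return(set_label(dp, label))
  hfp <- apply_hf(control, calibrate = calibrate)
  if (is.null(dp)) return(set_label(hfp, label))
  compose_hf_drug(control, variant_deltas(hfp, control),
                  variant_deltas(dp, control), label = label)
}

#' Labels of all built-in variants
#' @return character vector of registry labels.
#' @export
variant_labels <- function() {
  c("control", "hf", paste0("am", 1:8), paste0("am", 1:8, "p"), "ds",
    paste0("hf+am", 1:8), paste0("hf+am", 1:8, "p"), "hf+ds")
}
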