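# Closed-form wall shear stress under three rheological models, SI inside,
# mm / mm/s / cP at the I/O boundary only.

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

.check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("`%s` must lie strictly in (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

#' Convert centipoise to pascal-seconds
#' @param eta_cP dynamic viscosity in centipoise.
#' @return Viscosity in Pa·s (1 cP = 1e-3 Pa·s).
#' @export
cp_to_pas <- function(eta_cP) eta_cP * 1e-3

#' Build a table of per-animal hemodynamic records
#'
#' Validates and assembles the per-animal measurements every WSS method
#' consumes: vessel inner diameter, Doppler maximal blood velocity,
#' hematocrit, and optionally total blood viscosity and heart rate.
#'
#' @param animal_id identifier vector.
#' @param sex `"male"` or `"female"`.
#' @param phase cardiac phase, `"diastole"` or `"systole"`.
#' @param diameter_mm vessel inner diameter, mm; must be > 0.
#' @param vmax_mm_s maximal blood velocity, mm/s; must be > 0.
#' @param hematocrit red-cell volume fraction, strictly in (0, 1).
#' @param eta_b_cP optional per-animal total blood viscosity, cP.
#' @param heart_rate_bpm optional heart rate, beats per minute
#'   (pass-through).
#' @return A tibble with one validated row per animal × phase.
#' @export
#' @examples
#' hemodynamic_records("m1", "male", "diastole", 0.387, 157, 0.43, 4.1)
hemodynamic_records <- function(animal_id, sex, phase, diameter_mm,
                                vmax_mm_s, hematocrit, eta_b_cP = NA_real_,
                                heart_rate_bpm = NA_real_) {
  .check_positive(diameter_mm, "diameter_mm")
  .check_positive(vmax_mm_s, "vmax_mm_s")
  .check_fraction(hematocrit, "hematocrit")
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  phase <- match.arg(as.character(phase), c("diastole", "systole"),
                     several.ok = TRUE)
  tibble::tibble(
    animal_id = as.character(animal_id), sex = sex, phase = phase,
    diameter_mm = diameter_mm, vmax_mm_s = vmax_mm_s,
    hematocrit = hematocrit, eta_b_cP = eta_b_cP,
    heart_rate_bpm = heart_rate_bpm
  )
}

#' Normalize hemodynamic inputs to SI units
#'
#' @param diameter_mm diameter in mm.
#' @param vmax_mm_s maximal velocity in mm/s.
#' @param eta_cP viscosity in cP.
#' @return A list with `D` (m), `vmax` (m/s) and `eta` (Pa·s).
#' @export
to_si <- function(diameter_mm, vmax_mm_s, eta_cP) {
  .check_positive(diameter_mm, "diameter_mm")
  .check_positive(vmax_mm_s, "vmax_mm_s")
  .check_positive(eta_cP, "eta_cP")
  list(D = diameter_mm * 1e-3, vmax = vmax_mm_s * 1e-3,
       eta = cp_to_pas(eta_cP))
}

#' Viscosity model parameters
#'
#' Bundles the group plasma viscosity, optional measured total blood
#' viscosity, the plasma-to-apparent viscosity correction factor, the
#' Vmax/Vm velocity-profile ratio, and the coefficients of the linear
#' hematocrit-to-blood-viscosity regression.
#'
#' @param eta_p_cP plasma viscosity, cP (pooled per group).
#' @param eta_b_cP optional total blood viscosity, cP; if given must be
#'   >= `eta_p_cP`.
#' @param correction_factor apparent-viscosity multiplier on plasma
#'   viscosity (default 1.78).
#' @param vmax_vm_ratio centerline-to-mean velocity ratio (default 1.45).
#' @param regression_slope,regression_intercept hematocrit-to-viscosity
#'   line, yielding Pa·s from hematocrit as a fraction.
#' @return An object of class `viscosity_model`.
#' @export
viscosity_model <- function(eta_p_cP = 1.265, eta_b_cP = NULL,
                            correction_factor = 1.78, vmax_vm_ratio = 1.45,
                            regression_slope = 0.01258,
                            regression_intercept = -0.001443) {
  .check_positive(eta_p_cP, "eta_p_cP")
  .check_positive(correction_factor, "correction_factor")
  if (vmax_vm_ratio < 1) stop("`vmax_vm_ratio` must be >= 1", call. = FALSE)
  if (!is.null(eta_b_cP)) {
    .check_positive(eta_b_cP, "eta_b_cP")
    if (any(eta_b_cP < eta_p_cP)) {
      stop("`eta_b_cP` must be >= `eta_p_cP`", call. = FALSE)
    }
  }
  structure(
    list(eta_p_cP = eta_p_cP, eta_b_cP = eta_b_cP,
         correction_factor = correction_factor,
         vmax_vm_ratio = vmax_vm_ratio,
         regression_slope = regression_slope,
         regression_intercept = regression_intercept),
    class = "viscosity_model"
  )
}

#' @export
print.viscosity_model <- function(x, ...) {
  cat("Viscosity model\n")
  cat(sprintf("  plasma viscosity      : %.3f cP\n", x$eta_p_cP))
  if (!is.null(x$eta_b_cP)) {
    cat(sprintf("  total blood viscosity : %.3f cP\n", x$eta_b_cP))
  }
  cat(sprintf("  correction factor     : %.2f (apparent = %.2f cP)\n",
              x$correction_factor,
              apparent_viscosity(x$eta_p_cP, x$correction_factor)))
  cat(sprintf("  Vmax/Vm ratio         : %.2f\n", x$vmax_vm_ratio))
  cat(sprintf("  Ht->viscosity line    : %.5f * Ht %+.6f [Pa s]\n",
              x$regression_slope, x$regression_intercept))
  invisible(x)
}

.wss_result <- function(method, record, viscosity_used_cP, shear_rate_s1) {
  tibble::tibble(
    animal_id = record$animal_id, sex = record$sex, phase = record$phase,
    method = method, viscosity_used_cP = viscosity_used_cP,
    shear_rate_s1 = shear_rate_s1,
    wss_Pa = cp_to_pas(viscosity_used_cP) * shear_rate_s1
  )
}

#' Newtonian wall shear rate
#'
#' Wall shear rate of a parabolic Poiseuille profile, 4·Vmax/D.
#'
#' @inheritParams to_si
#' @return Shear rate in 1/s.
#' @export
shear_rate_newtonian <- function(diameter_mm, vmax_mm_s) {
  .check_positive(diameter_mm, "diameter_mm")
  .check_positive(vmax_mm_s, "vmax_mm_s")
  4 * (vmax_mm_s * 1e-3) / (diameter_mm * 1e-3)
}

#' Theoretical Newtonian (Poiseuille) wall shear stress
#'
#' Treats blood as a homogeneous Newtonian fluid with a parabolic velocity
#' profile (Vmax/Vm = 2), so that WSS = ηb · 4 · Vmax / D using the measured
#' total blood viscosity.
#'
#' @param records tibble from [hemodynamic_records()] (or any data frame
#'   with `diameter_mm`, `vmax_mm_s` columns).
#' @param eta_b_cP total blood viscosity, cP; defaults to the records'
#'   `eta_b_cP` column.
#' @return A tibble of WSS results: one row per record with `method`
#'   (`"tN"`), `viscosity_used_cP`, `shear_rate_s1` and `wss_Pa`.
#' @export
#' @examples
#' r <- hemodynamic_records("f", "female", "diastole", 0.376, 167, 0.43)
#' wss_theoretical_newtonian(r, eta_b_cP = 3.9)$wss_Pa  # ~6.9 Pa
wss_theoretical_newtonian <- function(records, eta_b_cP = records$eta_b_cP) {
  .check_positive(eta_b_cP, "eta_b_cP")
  sr <- shear_rate_newtonian(records$diameter_mm, records$vmax_mm_s)
  .wss_result("tN", records, eta_b_cP, sr)
}

#' Apparent viscosity from plasma viscosity
#'
#' Effective viscosity correcting cell-free plasma viscosity for residual
#' cellular effects: η_app = factor × η_p.
#'
#' @param eta_p_cP plasma viscosity, cP.
#' @param correction_factor multiplier, default 1.78.
#' @param digits rounding used for tabulation; `NULL` for full precision.
#' @return Apparent viscosity, cP.
#' @export
#' @examples
#' apparent_viscosity(1.26)  # 2.24 cP
#' apparent_viscosity(1.27)  # 2.26 cP
apparent_viscosity <- function(eta_p_cP, correction_factor = 1.78,
                               digits = 2) {
  .check_positive(eta_p_cP, "eta_p_cP")
  .check_positive(correction_factor, "correction_factor")
  out <- eta_p_cP * correction_factor
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Corrected Newtonian wall shear stress
#'
#' Empirical correction of the Poiseuille formula for the blunted velocity
#' profile of small arteries: WSS = η · (8 / ratio) · Vmax / D with a
#' centerline-to-mean velocity ratio of 1.45 by default, for which the
#' coefficient is conventionally printed rounded to 5.5 (the default here;
#' set `use_exact_coefficient = TRUE` for 8/ratio = 5.5172...). The caller
#' chooses which viscosity to insert: plasma, total blood, or apparent.
#'
#' @inheritParams wss_theoretical_newtonian
#' @param eta_cP viscosity inserted in the formula, cP.
#' @param vmax_vm_ratio centerline-to-mean velocity ratio in \[1, 2\].
#' @param use_exact_coefficient if `TRUE`, use 8/ratio exactly; if `FALSE`
#'   (default) and the ratio is 1.45, use the printed rounded 5.5.
#' @return A tibble of WSS results with `method = "cN"`.
#' @export
#' @examples
#' r <- hemodynamic_records("f", "female", "systole", 0.466, 1015, 0.43)
#' wss_corrected_newtonian(r, eta_cP = apparent_viscosity(1.27))$wss_Pa
wss_corrected_newtonian <- function(records, eta_cP,
                                    vmax_vm_ratio = 1.45,
                                    use_exact_coefficient = FALSE) {
  .check_positive(eta_cP, "eta_cP")
  if (vmax_vm_ratio < 1 || vmax_vm_ratio > 2) {
    stop("`vmax_vm_ratio` must lie in [1, 2]", call. = FALSE)
  }
  coef <- if (!use_exact_coefficient && isTRUE(all.equal(vmax_vm_ratio, 1.45))) {
    5.5
  } else {
    8 / vmax_vm_ratio
  }
  sr <- coef * (records$vmax_mm_s * 1e-3) / (records$diameter_mm * 1e-3)
  .wss_result("cN", records, eta_cP, sr)
}

#' Plug-flow hematocrit factor
#'
#' Hematocrit-dependent amplification of the Newtonian wall shear rate in
#' the plug/sheath flow separation model, in which all red cells travel in
#' a central plug at Vmax and the velocity drops to zero across a cell-free
#' plasma sheath: f(Ht) = (1 − Ht) / (1 − Ht·(1 − ln Ht)), taken positive.
#' f is > 1, strictly increasing, tends to 1 as Ht → 0 (plasma-only limit)
#' and diverges as Ht → 1.
#'
#' @param hematocrit red-cell volume fraction, strictly in (0, 1).
#' @return Dimensionless factor f(Ht) > 1.
#' @export
#' @examples
#' fahraeus_plug_factor(0.43)  # 2.7524
fahraeus_plug_factor <- function(hematocrit) {
  .check_fraction(hematocrit, "hematocrit")
  abs((1 - hematocrit) / (1 - hematocrit * (1 - log(hematocrit))))
}

#' Plug/sheath-model wall shear rate
#'
#' Magnitude of the wall shear rate of the plug/sheath flow model,
#' (4·Vmax/D)·f(Ht). The shear-stress vector points opposite to the flow;
#' the magnitude is returned per the usual positive-WSS convention.
#'
#' @inheritParams wss_theoretical_newtonian
#' @return Shear rate magnitude, 1/s.
#' @export
fahraeus_shear_rate <- function(records) {
  shear_rate_newtonian(records$diameter_mm, records$vmax_mm_s) *
    fahraeus_plug_factor(records$hematocrit)
}

#' Plug/sheath (Fahraeus) wall shear stress
#'
#' The F-method: wall shear stress exerted across the cell-free plasma
#' sheath, WSS = η_p · (4·Vmax/D) · f(Ht), using the pooled plasma
#' viscosity of the animal group and each animal's hematocrit. No
#' correction factor or assumed Vmax/Vm ratio is needed.
#'
#' @inheritParams wss_theoretical_newtonian
#' @param eta_p_cP plasma viscosity, cP.
#' @return A tibble of WSS results with `method = "F"`.
#' @export
#' @examples
#' r <- hemodynamic_records("f", "female", "systole", 0.466, 1015, 0.43)
#' wss_fahraeus(r, eta_p_cP = 1.27)$wss_Pa  # ~30.4 Pa
wss_fahraeus <- function(records, eta_p_cP) {
  .check_positive(eta_p_cP, "eta_p_cP")
  .wss_result("F", records, eta_p_cP, fahraeus_shear_rate(records))
}

#' Total blood viscosity predicted from hematocrit
#'
#' Linear regression of measured total blood viscosity on hematocrit:
#' η_b\[Pa·s\] = slope · Ht + intercept with Ht as a fraction, returned in
#' cP. Valid only where the line is positive (Ht above ~0.115 with the
#' default coefficients).
#'
#' @inheritParams fahraeus_plug_factor
#' @param model a [viscosity_model()] carrying the regression coefficients.
#' @return Predicted total blood viscosity, cP.
#' @export
#' @examples
#' blood_viscosity_from_hematocrit(0.43)  # ~3.97 cP
blood_viscosity_from_hematocrit <- function(hematocrit,
                                            model = viscosity_model()) {
  .check_fraction(hematocrit, "hematocrit")
  eta_pas <- model$regression_slope * hematocrit + model$regression_intercept
  if (any(eta_pas <= 0)) {
    stop("`hematocrit` below the positivity root of the viscosity line",
         call. = FALSE)
  }
  eta_pas * 1e3
}

#' Theoretical Newtonian WSS with regression-implied viscosity
#'
#' Composition used by the hematocrit sensitivity analysis: the Poiseuille
#' WSS with the total blood viscosity replaced by its hematocrit regression
#' prediction, WSS = (slope·Ht + intercept) · 4·Vmax/D.
#'
#' @inheritParams wss_theoretical_newtonian
#' @param model a [viscosity_model()] carrying the regression coefficients.
#' @return A tibble of WSS results with `method = "tN"`.
#' @export
wss_tn_from_hematocrit <- function(records, model = viscosity_model()) {
  eta_b <- blood_viscosity_from_hematocrit(records$hematocrit, model)
  wss_theoretical_newtonian(records, eta_b_cP = eta_b)
}
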