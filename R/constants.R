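#' Default model and pipeline constants
#'
#' All tunable constants of the package in one auditable place: the
#' plasma-to-apparent viscosity correction factor, the centerline-to-mean
#' velocity (Vmax/Vm) ratio of the corrected Newtonian method and its
#' printed rounded coefficient, the hematocrit-viscosity regression
#' coefficients, the background-threshold multiplier of the image pipeline,
#' the organelle size thresholds, and the orientation class boundaries.
#'
#' @return A named list of constants:
#' \describe{
#'   \item{correction_factor}{plasma-to-apparent viscosity multiplier
#'     (dimensionless, default 1.78).}
#'   \item{vmax_vm_ratio}{centerline-to-mean velocity ratio (default 1.45;
#'     2 for a parabolic Newtonian profile).}
#'   \item{cn_coefficient}{rounded coefficient 8 / vmax_vm_ratio used by the
#'     corrected Newtonian method as conventionally printed (5.5).}
#'   \item{regression_slope, regression_intercept}{linear
#'     hematocrit-to-blood-viscosity model, producing Pa·s from hematocrit
#'     expressed as a fraction.}
#'   \item{threshold_k}{background threshold multiplier: foreground is
#'     strictly above mean + k·SD of the background mode (3.89, retaining
#'     99.995\% of a Gaussian background).}
#'   \item{min_area_nucleus_um2, min_area_golgi_um2}{size-segmentation
#'     thresholds, µm².}
#'   \item{angle_breaks_deg}{class boundaries on the semicircle separating
#'     dromic / lateral / antidromic orientations.}
#'   \item{pixel_size_um}{default pixel size of the imaging setup, µm.}
#' }
#' @export
wss_defaults <- function() {
  list(
    correction_factor     = 1.78,
    vmax_vm_ratio         = 1.45,
    cn_coefficient        = 5.5,
    regression_slope      = 0.01258,
    regression_intercept  = -0.001443,
    threshold_k           = 3.89,
    min_area_nucleus_um2  = 10,
    min_area_golgi_um2    = 2,
    angle_breaks_deg      = c(60, 120),
    pixel_size_um         = 0.078
  )
}

#' Reference carotid hemodynamics of young adult mice
#'
#' Group-level summary (mean and SD) of right common carotid hemodynamics in
#' 8-week-old C57BL6/J mice, by sex and cardiac phase: inner diameter,
#' maximal blood velocity, hematocrit, total blood viscosity, heart rate,
#' and the pooled-plasma viscosity of each sex group. These group means are
#' the default inputs of the synthetic cohort generator and of the
#' method-comparison sweeps.
#'
#' @return A tibble with one row per sex × cardiac phase and columns
#'   `sex`, `phase`, `diameter_mm`, `diameter_sd_mm`, `vmax_mm_s`,
#'   `vmax_sd_mm_s`, `hematocrit`, `hematocrit_sd`, `eta_b_cP`,
#'   `eta_b_sd_cP`, `eta_p_cP`, `heart_rate_bpm`, `heart_rate_sd_bpm`.
#' @export
#' @examples
#' carotid_reference_groups()
carotid_reference_groups <- function() {
  tibble::tibble(
    sex   = rep(c("male", "female"), each = 2L),
    phase = rep(c("diastole", "systole"), times = 2L),
    diameter_mm       = c(0.387, 0.484, 0.376, 0.466),
    diameter_sd_mm    = c(0.05, 0.05, 0.04, 0.05),
    vmax_mm_s         = c(157, 999, 167, 1015),
    vmax_sd_mm_s      = c(43, 183, 54, 258),
    hematocrit        = c(0.43, 0.43, 0.43, 0.43),
    hematocrit_sd     = c(0.02, 0.02, 0.03, 0.03),
    eta_b_cP          = c(4.1, 4.1, 3.9, 3.9),
    eta_b_sd_cP       = c(0.4, 0.4, 0.6, 0.6),
    eta_p_cP          = c(1.26, 1.26, 1.27, 1.27),
    heart_rate_bpm    = c(455, 455, 429, 429),
    heart_rate_sd_bpm = c(36, 36, 62, 62)
  )
}
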