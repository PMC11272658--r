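# Method-comparison sensitivity analysis: theoretical Newtonian vs
# plug/sheath WSS over diameter, velocity and hematocrit grids.

#' Normalized difference between two WSS estimates
#'
#' Signed percent difference of two wall-shear-stress values normalized to
#' their mean: 100·(a − b) / ((a + b)/2).
#'
#' @param wss_a,wss_b WSS values, Pa; both > 0.
#' @return Signed percent difference.
#' @export
#' @examples
#' normalized_method_difference(6, 6)  # 0
normalized_method_difference <- function(wss_a, wss_b) {
  .check_positive(wss_a, "wss_a")
  .check_positive(wss_b, "wss_b")
  m <- (wss_a + wss_b) / 2
  if (any(m == 0)) stop("two-method mean is zero", call. = FALSE)
  100 * (wss_a - wss_b) / m
}

#' Specify a one-parameter method-comparison sweep
#'
#' Holds one of diameter, maximal velocity or hematocrit on a grid while
#' the other inputs stay at fixed values. Defaults reproduce the reference
#' comparison: sex-pooled diastolic group means (diameter 0.3815 mm, Vmax
#' 162 mm/s, hematocrit 0.43) with pooled plasma viscosity 1.265 cP; the
#' theoretical Newtonian arm takes its viscosity from the hematocrit
#' regression line.
#'
#' @param parameter one of `"diameter"`, `"vmax"`, `"hematocrit"`.
#' @param grid strictly increasing grid of values (mm, mm/s, or fraction).
#'   Defaults: 0.1–1.0 mm by 0.1; 100–1100 mm/s by 100; 0.38–0.48 by 0.01.
#' @param diameter_mm,vmax_mm_s,hematocrit held-constant inputs.
#' @param model a [viscosity_model()]: plasma viscosity for the plug/sheath
#'   arm and regression coefficients for the Newtonian arm.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter = c("diameter", "vmax", "hematocrit"),
                       grid = NULL,
                       diameter_mm = 0.3815, vmax_mm_s = 162,
                       hematocrit = 0.43,
                       model = viscosity_model(eta_p_cP = 1.265)) {
  parameter <- match.arg(parameter)
  if (is.null(grid)) {
    grid <- switch(parameter,
      diameter   = seq(0.1, 1.0, by = 0.1),
      vmax       = seq(100, 1100, by = 100),
      hematocrit = seq(0.38, 0.48, by = 0.01)
    )
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  .check_positive(grid, "grid")
  .check_positive(diameter_mm, "diameter_mm")
  .check_positive(vmax_mm_s, "vmax_mm_s")
  .check_fraction(hematocrit, "hematocrit")
  structure(
    list(parameter = parameter, grid = grid, diameter_mm = diameter_mm,
         vmax_mm_s = vmax_mm_s, hematocrit = hematocrit, model = model),
    class = "sweep_spec"
  )
}

#' Run a tN-vs-F method-comparison sweep
#'
#' At each grid point, computes the theoretical Newtonian WSS with the
#' regression-implied blood viscosity and the plug/sheath WSS with the
#' pooled plasma viscosity, plus their normalized percent difference.
#' Because both methods share the 4·Vmax/D dependence, the difference is
#' constant across diameter and velocity grids and varies only with
#' hematocrit.
#'
#' @param spec a [sweep_spec()].
#' @return A tibble with columns `parameter`, `grid_value`, `wss_tn_Pa`,
#'   `wss_f_Pa`, `diff_pct`.
#' @export
#' @examples
#' run_sweep(sweep_spec("hematocrit"))
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  d  <- rep(spec$diameter_mm, length(spec$grid))
  v  <- rep(spec$vmax_mm_s, length(spec$grid))
  ht <- rep(spec$hematocrit, length(spec$grid))
  switch(spec$parameter,
    diameter   = d  <- spec$grid,
    vmax       = v  <- spec$grid,
    hematocrit = ht <- spec$grid
  )
  rec <- hemodynamic_records(
    animal_id = sprintf("grid_%02d", seq_along(spec$grid)),
    sex = "female", phase = "diastole",
    diameter_mm = d, vmax_mm_s = v, hematocrit = ht
  )
  tn <- wss_tn_from_hematocrit(rec, model = spec$model)
  f  <- wss_fahraeus(rec, eta_p_cP = spec$model$eta_p_cP)
  tibble::tibble(
    parameter  = spec$parameter,
    grid_value = spec$grid,
    wss_tn_Pa  = tn$wss_Pa,
    wss_f_Pa   = f$wss_Pa,
    diff_pct   = normalized_method_difference(tn$wss_Pa, f$wss_Pa)
  )
}

#' Normalized tN-vs-F difference at a given hematocrit
#'
#' Closed-path convenience wrapper: the normalized method difference
#' depends only on hematocrit and the viscosity model (the 4·Vmax/D kernel
#' cancels), so any common diameter and velocity give the same value.
#'
#' @inheritParams fahraeus_plug_factor
#' @param model a [viscosity_model()].
#' @return Signed percent difference between the theoretical Newtonian
#'   (regression viscosity) and plug/sheath methods.
#' @export
#' @examples
#' method_difference_at_ht(0.43)  # ~13.0
method_difference_at_ht <- function(hematocrit,
                                    model = viscosity_model(eta_p_cP = 1.265)) {
  rec <- hemodynamic_records("x", "female", "diastole",
                             diameter_mm = 0.3815, vmax_mm_s = 162,
                             hematocrit = hematocrit)
  tn <- wss_tn_from_hematocrit(rec, model = model)$wss_Pa
  f  <- wss_fahraeus(rec, eta_p_cP = model$eta_p_cP)$wss_Pa
  normalized_method_difference(tn, f)
}
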