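test_that("unit normalization converts mm, mm/s and cP to SI", {
  expect_equal(to_si(1, 1, 1), list(D = 0.001, vmax = 0.001, eta = 0.001))
  si <- to_si(0.387, 157, 4.1)
  expect_equal(si$D, 3.87e-4)
  expect_equal(si$vmax, 0.157)
  expect_equal(si$eta, 4.1e-3)
  expect_error(to_si(0, 1, 1), "diameter_mm")
  expect_error(to_si(1, -2, 1), "vmax_mm_s")
  expect_error(to_si(1, 1, 0), "eta_cP")
})

test_that("record construction enforces physical invariants", {
  expect_error(
    hemodynamic_records("a", "male", "diastole", 0.4, 150, 1.2),
    "hematocrit"
  )
  expect_error(
    hemodynamic_records("a", "male", "diastole", -0.4, 150, 0.4),
    "diameter_mm"
  )
  r <- hemodynamic_records(c("a", "b"), "male", "diastole",
                           c(0.4, 0.5), c(150, 160), 0.43)
  expect_equal(nrow(r), 2L)
})

test_that("theoretical Newtonian WSS matches direct Poiseuille evaluation", {
  # female diastole group means; published group value 6.9 Pa
  r <- hemodynamic_records("f", "female", "diastole", 0.376, 167, 0.43)
  w <- wss_theoretical_newtonian(r, eta_b_cP = 3.9)
  expect_equal(w$wss_Pa, 3.9e-3 * 4 * 0.167 / 3.76e-4, tolerance = 1e-12)
  expect_equal(w$wss_Pa, 6.9, tolerance = 0.02)
  expect_equal(w$shear_rate_s1, 4 * 0.167 / 3.76e-4, tolerance = 1e-12)
  # male systole group means, direct evaluation
  r2 <- hemodynamic_records("m", "male", "systole", 0.484, 999, 0.43)
  expect_equal(wss_theoretical_newtonian(r2, 4.1)$wss_Pa,
               4.1e-3 * 4 * 0.999 / 4.84e-4, tolerance = 1e-12)
  # Vmax/D scale invariance
  r3 <- hemodynamic_records("m", "male", "systole", 2 * 0.484, 2 * 999, 0.43)
  expect_equal(wss_theoretical_newtonian(r3, 4.1)$wss_Pa,
               wss_theoretical_newtonian(r2, 4.1)$wss_Pa)
})

test_that("apparent viscosity reproduces the tabulated group values", {
  expect_identical(apparent_viscosity(1.26), 2.24)
  expect_identical(apparent_viscosity(1.27), 2.26)
  expect_equal(apparent_viscosity(1.0, 1.0), 1.0)
  expect_equal(apparent_viscosity(1.26, digits = NULL), 1.26 * 1.78)
})

test_that("corrected Newtonian WSS uses the blunted-profile coefficient", {
  r <- hemodynamic_records("f", "female", "systole", 0.466, 1015, 0.43)
  w <- wss_corrected_newtonian(r, eta_cP = 2.26)
  expect_equal(w$wss_Pa, 2.26e-3 * 5.5 * 1.015 / 4.66e-4, tolerance = 1e-12)
  expect_equal(w$wss_Pa, 27.2, tolerance = 0.02)
  # exact-coefficient option: 8 / 1.45
  w2 <- wss_corrected_newtonian(r, eta_cP = 2.26, use_exact_coefficient = TRUE)
  expect_equal(w2$wss_Pa, 2.26e-3 * (8 / 1.45) * 1.015 / 4.66e-4,
               tolerance = 1e-12)
  # ratio 2 recovers the parabolic (theoretical) formula
  w3 <- wss_corrected_newtonian(r, eta_cP = 3.9, vmax_vm_ratio = 2)
  expect_equal(w3$wss_Pa, wss_theoretical_newtonian(r, 3.9)$wss_Pa,
               tolerance = 1e-12)
  expect_error(wss_corrected_newtonian(r, 2.26, vmax_vm_ratio = 2.5),
               "vmax_vm_ratio")
  # male diastole with apparent viscosity, direct evaluation
  r4 <- hemodynamic_records("m", "male", "diastole", 0.387, 157, 0.43)
  expect_equal(wss_corrected_newtonian(r4, 2.24)$wss_Pa,
               2.24e-3 * 5.5 * 0.157 / 3.87e-4, tolerance = 1e-12)
})

test_that("plug factor follows the plug/sheath closed form and limits", {
  f <- function(ht) (1 - ht) / (1 - ht * (1 - log(ht)))
  expect_equal(fahraeus_plug_factor(0.43), f(0.43), tolerance = 1e-12)
  expect_equal(fahraeus_plug_factor(0.43), 2.7524, tolerance = 1e-4)
  expect_equal(fahraeus_plug_factor(0.38), 2.4573, tolerance = 1e-4)
  # plasma-only limit
  expect_equal(fahraeus_plug_factor(1e-9), 1, tolerance = 1e-6)
  # strictly increasing on a hematocrit grid, always > 1
  grid <- seq(0.05, 0.95, by = 0.05)
  vals <- fahraeus_plug_factor(grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 1))
  expect_error(fahraeus_plug_factor(0), "hematocrit")
  expect_error(fahraeus_plug_factor(1), "hematocrit")
})

test_that("plug/sheath shear rate amplifies the Newtonian rate by f(Ht)", {
  r <- hemodynamic_records("f", "female", "systole", 0.466, 1015, 0.43)
  expect_equal(fahraeus_shear_rate(r),
               (4 * 1.015 / 4.66e-4) * fahraeus_plug_factor(0.43),
               tolerance = 1e-12)
  # ratio invariance under joint scaling of D and Vmax
  r2 <- hemodynamic_records("f", "female", "systole", 0.932, 2030, 0.43)
  expect_equal(fahraeus_shear_rate(r2), fahraeus_shear_rate(r))
  # Newtonian limit
  r3 <- hemodynamic_records("f", "female", "systole", 0.466, 1015, 1e-9)
  expect_equal(fahraeus_shear_rate(r3), 4 * 1.015 / 4.66e-4,
               tolerance = 1e-6)
})

test_that("plug/sheath WSS matches the published group values", {
  r <- hemodynamic_records("f", "female", "systole", 0.466, 1015, 0.43)
  expect_equal(wss_fahraeus(r, 1.27)$wss_Pa, 30.4, tolerance = 0.02)
  r2 <- hemodynamic_records("f", "female", "diastole", 0.387, 157, 0.43)
  expect_equal(wss_fahraeus(r2, 1.26)$wss_Pa,
               1.26e-3 * (4 * 0.157 / 3.87e-4) * fahraeus_plug_factor(0.43),
               tolerance = 1e-12)
})

test_that("WSS homogeneity: linear in viscosity and Vmax, inverse in D", {
  set.seed(11)
  for (i in 1:20) {
    d <- runif(1, 0.1, 1); v <- runif(1, 50, 1200)
    ht <- runif(1, 0.2, 0.6); eta <- runif(1, 1, 6)
    s <- runif(1, 1.1, 3)
    r <- hemodynamic_records("a", "male", "systole", d, v, ht)
    rv <- hemodynamic_records("a", "male", "systole", d, s * v, ht)
    rd <- hemodynamic_records("a", "male", "systole", s * d, v, ht)
    for (fn in list(
      function(x, e) wss_theoretical_newtonian(x, e)$wss_Pa,
      function(x, e) wss_corrected_newtonian(x, e)$wss_Pa,
      function(x, e) wss_fahraeus(x, e)$wss_Pa
    )) {
      w <- fn(r, eta)
      expect_equal(fn(r, s * eta), s * w, tolerance = 1e-10)
      expect_equal(fn(rv, eta), s * w, tolerance = 1e-10)
      expect_equal(fn(rd, eta), w / s, tolerance = 1e-10)
    }
  }
})

test_that("plug/sheath WSS converges to Newtonian plasma WSS as Ht -> 0", {
  r <- hemodynamic_records("a", "male", "diastole", 0.4, 160, 1e-6)
  wf <- wss_fahraeus(r, 1.26)$wss_Pa
  wt <- wss_theoretical_newtonian(r, eta_b_cP = 1.26)$wss_Pa
  expect_lt(abs(wf - wt) / wt, 1e-4)
})

test_that("every result satisfies wss = viscosity x shear rate", {
  set.seed(12)
  recs <- hemodynamic_records(letters[1:10], "female", "systole",
                              runif(10, 0.2, 0.8), runif(10, 100, 1200),
                              runif(10, 0.3, 0.55), eta_b_cP = runif(10, 3, 5))
  for (w in list(wss_theoretical_newtonian(recs),
                 wss_corrected_newtonian(recs, eta_cP = 2.26),
                 wss_fahraeus(recs, eta_p_cP = 1.27))) {
    expect_equal(w$wss_Pa, cp_to_pas(w$viscosity_used_cP) * w$shear_rate_s1,
                 tolerance = 1e-12)
    expect_true(all(w$wss_Pa > 0))
  }
})

test_that("hematocrit-viscosity line predicts measured-range viscosities", {
  expect_equal(blood_viscosity_from_hematocrit(0.43),
               (0.01258 * 0.43 - 0.001443) * 1e3, tolerance = 1e-12)
  expect_equal(blood_viscosity_from_hematocrit(0.43), 3.9664,
               tolerance = 1e-4)
  expect_equal(blood_viscosity_from_hematocrit(0.48), 4.5954,
               tolerance = 1e-4)
  # below the positivity root of the line
  expect_error(blood_viscosity_from_hematocrit(0.11), "positivity")
})

test_that("regression-viscosity WSS is the composition of its two parts", {
  r <- hemodynamic_records("a", "female", "diastole", 0.3815, 162, 0.43)
  expect_equal(
    wss_tn_from_hematocrit(r)$wss_Pa,
    wss_theoretical_newtonian(
      r, eta_b_cP = blood_viscosity_from_hematocrit(0.43))$wss_Pa,
    tolerance = 1e-12
  )
  expect_equal(wss_tn_from_hematocrit(r)$wss_Pa,
               3.9664e-3 * 4 * 0.162 / 3.815e-4, tolerance = 1e-4)
})
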