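test_that("fetoplacental unit refuses pre-week-15 physiology", {
  expect_error(simulate_pregnant_with_fetus(esc, build_physiology(12),
                                            dose_regimen(10)),
               "week 15")
})

test_that("zero barrier clearances decouple the fetus", {
  esc0 <- esc
  esc0$cl_pdm <- 0
  esc0$cl_pdf <- 0
  prof <- simulate_pregnant_with_fetus(esc0, phys_gw40, dose_regimen(10),
                                       fast_settings())
  expect_equal(max(abs(prof$fetal_plasma)), 0, tolerance = 1e-12)
  expect_equal(max(abs(prof$amniotic)), 0, tolerance = 1e-12)
})

test_that("symmetric binding gives unit cord-to-maternal ratio", {
  phys_sym <- build_physiology(40, overrides = list(
    fetal_protein_ratio = phys_gw40$binding_protein_conc_ratio))
  prof <- simulate_pregnant_with_fetus(esc, phys_sym, dose_regimen(10),
                                       fast_settings())
  expect_equal(as.numeric(cord_to_maternal_ratio(prof)), 1.0,
               tolerance = 0.01)
})

test_that("the cord ratio is exactly dose-independent", {
  s <- fast_settings()
  r10 <- cord_to_maternal_ratio(
    simulate_pregnant_with_fetus(esc, phys_gw40, dose_regimen(10), s))
  r20 <- cord_to_maternal_ratio(
    simulate_pregnant_with_fetus(esc, phys_gw40, dose_regimen(20), s))
  expect_equal(as.numeric(r10), as.numeric(r20), tolerance = 1e-12)
})

test_that("weaker fetal binding lowers the total-concentration cord ratio", {
  # smaller fetal protein ratio -> larger fetal fu -> lower ratio
  s <- fast_settings()
  phys_lo <- build_physiology(40, overrides = list(fetal_protein_ratio = 0.2))
  r_default <- as.numeric(cord_to_maternal_ratio(
    simulate_pregnant_with_fetus(esc, phys_gw40, dose_regimen(10), s)))
  r_lo <- as.numeric(cord_to_maternal_ratio(
    simulate_pregnant_with_fetus(esc, phys_lo, dose_regimen(10), s)))
  expect_lt(r_lo, r_default)
})

test_that("fetal and amniotic concentrations stay non-negative and bounded", {
  prof <- simulate_pregnant_with_fetus(esc, phys_gw40, dose_regimen(10),
                                       fast_settings())
  expect_true(all(prof$fetal_plasma >= -1e-9))
  expect_true(all(prof$amniotic >= -1e-9))
  expect_true(all(prof$fetal_plasma < 1e4))
})

test_that("cord ratio computation handles degenerate profiles", {
  tt <- seq(216, 240, by = 0.5)
  base <- 10 + sin(tt / 4)
  prof <- structure(data.frame(time = tt, maternal_plasma = base,
                               fetal_plasma = base),
                    class = c("conc_profile", "data.frame"), interval = 24)
  expect_equal(as.numeric(cord_to_maternal_ratio(prof)), 1.0,
               tolerance = 1e-12)
  prof$fetal_plasma <- 0.7 * base
  expect_equal(as.numeric(cord_to_maternal_ratio(prof)), 0.7,
               tolerance = 1e-12)
  prof$fetal_plasma <- NULL
  expect_error(cord_to_maternal_ratio(prof), "fetal")
})
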