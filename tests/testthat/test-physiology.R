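test_that("gestational scaling polynomial matches hand-evaluated values", {
  cyp2d6 <- preg_coeffs(1, b1 = 0.0163, b2 = 0.0009)
  cyp3a4 <- preg_coeffs(1, b1 = 0.0129, b2 = 0.0005)
  expect_equal(scale_parameter(cyp2d6, 0), 1)
  expect_equal(scale_parameter(cyp2d6, 35), 1 + 0.5705 + 1.1025,
               tolerance = 1e-12)
  expect_equal(scale_parameter(cyp3a4, 20), 1.458, tolerance = 1e-12)
  # constant trajectory with all-zero coefficients, any baseline
  flat <- preg_coeffs(7.3)
  expect_equal(scale_parameter(flat, c(0, 10, 25, 40)), rep(7.3, 4))
  expect_error(scale_parameter(cyp2d6, -1), "non-negative")
})

test_that("scaling polynomial agrees with an independent Horner evaluation", {
  set.seed(11)
  horner <- function(baseline, b, gw) {
    acc <- 0
    for (coef in rev(b)) acc <- (acc + coef) * gw
    baseline * (1 + acc)
  }
  for (i in 1:20) {
    b <- stats::runif(4, -0.01, 0.05)
    base <- stats::runif(1, 0.1, 300)
    gw <- stats::runif(1, 0, 40)
    expect_equal(scale_parameter(preg_coeffs(base, b[1], b[2], b[3], b[4]), gw),
                 horner(base, b, gw), tolerance = 1e-12)
    # linear in the baseline value
    expect_equal(scale_parameter(preg_coeffs(2 * base, b[1], b[2], b[3], b[4]),
                                 gw),
                 2 * scale_parameter(preg_coeffs(base, b[1], b[2], b[3], b[4]),
                                     gw),
                 tolerance = 1e-12)
  }
})

test_that("non-negative coefficients give non-decreasing trajectories", {
  set.seed(12)
  for (i in 1:10) {
    b <- stats::runif(4, 0, 0.02)
    tr <- scale_parameter(preg_coeffs(1, b[1], b[2], b[3], b[4]),
                          seq(0, 40, by = 1))
    expect_true(all(diff(tr) >= 0))
  }
})

test_that("fraction-unbound scaling follows the binding-protein ratio", {
  expect_equal(scale_fraction_unbound(0.44, 1), 0.44)
  expect_equal(scale_fraction_unbound(0.44, 0.37), 0.6799, tolerance = 1e-4)
  expect_equal(scale_fraction_unbound(1.0, 0.5), 1.0)
  expect_error(scale_fraction_unbound(0, 1), "fu_baseline")
  expect_error(scale_fraction_unbound(0.44, 0), "protein_ratio")
})

test_that("physiology snapshot satisfies its structural invariants", {
  expect_equal(unname(phys_gw0$enzyme_activity_multiplier), c(1, 1, 1))
  expect_null(phys_gw0$fetal_weight)
  expect_true(all(phys_gw0$tissue_volumes > 0))
  expect_true(all(phys_gw0$tissue_flows > 0))
  expect_true(all(phys_gw0$enzyme_abundance > 0))
  expect_gt(phys_gw0$hematocrit, 0)
  expect_lt(phys_gw0$hematocrit, 1)

  for (phys in list(phys_gw0, build_physiology(21), phys_gw40)) {
    systemic <- sum(phys$tissue_flows[setdiff(names(phys$tissue_flows),
                                              c("liver", "lung"))]) +
      (phys$hepatic_blood_flow - phys$tissue_flows[["gut"]] -
         phys$tissue_flows[["spleen"]])
    expect_equal(unname(systemic), phys$cardiac_output,
                 tolerance = 0.01)
  }
})

test_that("gestational week 35 snapshot carries the printed CYP multipliers", {
  expect_equal(phys_gw35$enzyme_activity_multiplier[["CYP2D6"]], 2.673,
               tolerance = 1e-6)
  expect_equal(phys_gw35$enzyme_activity_multiplier[["CYP3A4"]], 2.064,
               tolerance = 1e-6)
  expect_equal(phys_gw35$enzyme_activity_multiplier[["CYP2C19"]], 1.0)
})

test_that("fetal fields appear at week 15 and match term anchors", {
  expect_null(build_physiology(14.9)$fetal_weight)
  expect_false(is.null(build_physiology(15)$fetal_weight))
  expect_equal(phys_gw40$fetal_weight, 3.7, tolerance = 1e-12)
  # term amniotic volume consistent with a 750 mL/day swallowing input
  expect_equal(phys_gw40$amniotic_volume, 0.75, tolerance = 1e-12)
  expect_equal(phys_gw40$fetal_swallowed_volume, 750)
  expect_true(all(diff(fetal_weight_at(15:40)) > 0))
  expect_true(all(diff(amniotic_volume_at(15:40)) > 0))
})

test_that("snapshot construction validates its domain and is deterministic", {
  expect_error(build_physiology(41), "exceed 40")
  expect_error(build_physiology(-1), "non-negative")
  expect_error(build_physiology(20, overrides = list(nonsense = 1)),
               "unknown physiology override")
  expect_error(build_physiology(20, scaling = list(nonsense = preg_coeffs(1))),
               "unknown scaling")
  expect_identical(build_physiology(27), build_physiology(27))
  # overrides propagate
  phys <- build_physiology(0, overrides = list(gfr = 100))
  expect_equal(phys$gfr, 100)
})
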