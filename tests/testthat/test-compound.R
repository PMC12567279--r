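test_that("packaged escitalopram fixture reproduces the published inputs", {
  expect_equal(esc$molecular_weight, 324.39)
  expect_equal(esc$logp, 1.34)
  expect_equal(esc$pka, 9.5)
  expect_equal(esc$blood_to_plasma, 2.0)
  expect_equal(esc$fu_plasma, 0.44)
  expect_equal(esc$f_absorbed, 1.0)
  expect_equal(esc$k_absorption, 0.19)
  expect_equal(esc$fu_gut, 1.0)
  expect_equal(esc$q_gut, 5.69)
  expect_equal(esc$kp_scalar, 0.92)
  expect_equal(unname(esc$clint_by_isoform), c(0.774, 0.505, 0.0155))
  expect_equal(esc$cl_renal_adult, 4.0)
  expect_equal(esc$cl_pdm, 0.80902)
  expect_equal(esc$cl_pdf, 0.80902)
})

test_that("compound record validates fractions and rates", {
  expect_error(load_compound() |> (\(x) {
    compound_record(x$molecular_weight, x$logp, x$pka, x$blood_to_plasma,
                    fu_plasma = 1.2, x$f_absorbed, x$k_absorption, x$fu_gut,
                    x$q_gut, x$kp_scalar, x$clint_by_isoform,
                    x$cl_renal_adult, x$cl_pdm, x$cl_pdf)
  })(), "fractions")
})

test_that("fetal swallowing clearance follows its closed form", {
  expect_equal(fetal_swallowing_clearance(750, 3.7), 0.00844,
               tolerance = 1e-5 / 0.00844)
  expect_equal(fetal_swallowing_clearance(0, 3.7), 0)
  expect_equal(fetal_swallowing_clearance(500, 2.5), 0.008333,
               tolerance = 1e-4)
  expect_error(fetal_swallowing_clearance(750, 0), "positive")
  # independent arithmetic over random inputs
  set.seed(21)
  v <- stats::runif(10, 50, 1200)
  w <- stats::runif(10, 0.2, 4)
  expect_equal(fetal_swallowing_clearance(v, w), (v / 24 / 1000) / w,
               tolerance = 1e-12)
})

test_that("fetal renal clearance scales the adult value by the GFR ratio", {
  expect_equal(fetal_renal_clearance(4.0, 4.92, 121, 3.7), 0.044,
               tolerance = 5e-4 / 0.044)
  expect_equal(fetal_renal_clearance(4.0, 121, 121, 1.0), 4.0)
  # linear in the adult clearance
  expect_equal(fetal_renal_clearance(2.0, 4.92, 121, 3.7),
               fetal_renal_clearance(4.0, 4.92, 121, 3.7) / 2,
               tolerance = 1e-12)
  expect_error(fetal_renal_clearance(4.0, 4.92, 121, 0), "positive")
})

test_that("whole-liver intrinsic clearance is additive and linear", {
  expect_equal(whole_liver_intrinsic_clearance(
    esc, phys_gw0, c(CYP2C19 = 0, CYP2D6 = 0, CYP3A4 = 0)), 0)
  # per-isoform contribution ordering at baseline: 2C19 > 2D6 > 3A4
  contrib <- vapply(c("CYP2C19", "CYP2D6", "CYP3A4"), function(iso) {
    mult <- stats::setNames(rep(0, 3), c("CYP2C19", "CYP2D6", "CYP3A4"))
    mult[iso] <- 1
    whole_liver_intrinsic_clearance(esc, phys_gw0, mult)
  }, numeric(1))
  expect_true(contrib[["CYP2C19"]] > contrib[["CYP2D6"]])
  expect_true(contrib[["CYP2D6"]] > contrib[["CYP3A4"]])
  expect_equal(sum(contrib), whole_liver_intrinsic_clearance(esc, phys_gw0),
               tolerance = 1e-12)
  # gestational induction: ratio of totals at week 35 vs week 0
  expect_equal(whole_liver_intrinsic_clearance(esc, phys_gw35) /
                 whole_liver_intrinsic_clearance(esc, phys_gw0),
               1.53, tolerance = 0.001)
  # linear in each CLint
  esc2 <- esc
  esc2$clint_by_isoform <- esc$clint_by_isoform * 2
  expect_equal(whole_liver_intrinsic_clearance(esc2, phys_gw0),
               2 * whole_liver_intrinsic_clearance(esc, phys_gw0),
               tolerance = 1e-12)
  expect_error(whole_liver_intrinsic_clearance(esc, phys_gw0,
                                               c(CYP2C19 = -1)),
               "non-negative")
})

test_that("Kp prediction is proportional to the scalar and complete", {
  kp <- predict_kp(esc)
  expect_true(all(kp > 0))
  esc0 <- esc
  esc0$kp_scalar <- 0
  expect_equal(unname(predict_kp(esc0)), rep(0, length(kp)))
  esc2 <- esc
  esc2$kp_scalar <- 2 * esc$kp_scalar
  expect_equal(predict_kp(esc2), 2 * kp, tolerance = 1e-12)
  comp <- load_tissue_composition()
  expect_error(predict_kp(esc, comp[comp$tissue != "muscle", ]), "muscle")
})

test_that("predicted Vss falls in the published range and is monotone in Kp", {
  kp <- predict_kp(esc)
  vss <- predict_vss(kp, phys_gw0, esc)
  expect_gt(vss, 13.513 * 0.75)
  expect_lt(vss, 13.513 * 1.25)
  # all-zero Kp leaves the plasma (+ blood cell) volume term only
  zero <- stats::setNames(rep(0, length(kp)), names(kp))
  expect_gt(predict_vss(zero, phys_gw0), 0)
  expect_lt(predict_vss(zero, phys_gw0), 0.1)
  # strictly increasing in every Kp
  for (tis in c("muscle", "adipose", "liver")) {
    kp2 <- kp
    kp2[tis] <- kp2[tis] * 1.1
    expect_gt(predict_vss(kp2, phys_gw0, esc), vss)
  }
})
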