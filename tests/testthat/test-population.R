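test_that("sampling is reproducible and respects degenerate settings", {
  spec <- population_spec(5, 2, gw = 0, seed = 7)
  a <- sample_individuals(spec, esc)
  b <- sample_individuals(spec, esc)
  expect_identical(a, b)

  # zero CVs, single phenotype: every individual equals the default
  spec0 <- population_spec(4, 1, gw = 0,
                           cv_map = c(clint = 0, k_absorption = 0,
                                      kp_scalar = 0, fu_plasma = 0),
                           seed = 1)
  inds <- sample_individuals(spec0, esc, nm_only)
  for (ind in inds) {
    expect_identical(ind$compound$clint_by_isoform, esc$clint_by_isoform)
    expect_identical(ind$compound$k_absorption, esc$k_absorption)
    expect_identical(ind$phenotype, "NM")
  }
})

test_that("phenotype frequencies are validated and honored", {
  bad <- list(phenotype_spec("NM", 0.6, 1), phenotype_spec("PM", 0.2, 0.6))
  expect_error(sample_individuals(population_spec(2, 1), esc, bad),
               "sum to 1")
  inds <- sample_individuals(population_spec(10, 2, seed = 3), esc, nm_only)
  expect_true(all(vapply(inds, `[[`, character(1), "phenotype") == "NM"))
})

test_that("percentile band collapses at zero variability and widens with CV", {
  spec0 <- population_spec(3, 1, gw = 0,
                           cv_map = c(clint = 0, k_absorption = 0,
                                      kp_scalar = 0, fu_plasma = 0))
  pop0 <- run_population(spec0, esc, dose_regimen(10), nm_only)
  expect_equal(pop0$p5, pop0$mean, tolerance = 1e-12)
  expect_equal(pop0$p95, pop0$mean, tolerance = 1e-12)

  width <- function(cv) {
    spec <- population_spec(25, 2, gw = 0,
                            cv_map = c(clint = cv, k_absorption = cv,
                                       kp_scalar = cv, fu_plasma = cv),
                            seed = 5)
    pop <- run_population(spec, esc, dose_regimen(10), nm_only)
    mean(pop$p95 - pop$p5)
  }
  expect_gt(width(0.35), width(0.15))
  # band ordering holds pointwise
  spec <- population_spec(10, 2, gw = 0, seed = 9)
  pop <- run_population(spec, esc, dose_regimen(10))
  expect_true(all(pop$p5 <= pop$mean + 1e-9))
  expect_true(all(pop$mean <= pop$p95 + 1e-9))
})

test_that("phenotype exposure ordering PM > IM > NM > UM holds", {
  spec0 <- function(gw) population_spec(1, 1, gw = gw,
                                        cv_map = c(clint = 0,
                                                   k_absorption = 0,
                                                   kp_scalar = 0,
                                                   fu_plasma = 0))
  for (gw in c(0, 21, 35)) {
    aucs <- vapply(c("PM", "IM", "NM", "UM"), function(ph) {
      pure <- list(phenotype_spec(ph, 1,
                                  phenotype_multiplier(ph)[["CYP2C19"]]))
      pop <- run_population(spec0(gw), esc, dose_regimen(10), pure)
      mean(attr(pop, "pk")$auc)
    }, numeric(1))
    expect_true(all(diff(aucs) < 0))  # PM > IM > NM > UM
  }
})

test_that("population-mean exposure stays near the default individual", {
  spec <- population_spec(40, 2, gw = 0, seed = 13)
  pop <- run_population(spec, esc, dose_regimen(10), nm_only)
  det <- compute_pk_metrics(simulate_individual(esc, phys_gw0,
                                                dose_regimen(10),
                                                fast_settings()))
  ratio <- mean(attr(pop, "pk")$auc) / det$auc
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.25)
})
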