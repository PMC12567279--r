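test_that("interval metrics handle flat and pulsed profiles", {
  m <- compute_pk_metrics(flat_profile(10))
  expect_equal(m$c_max, 10)
  expect_equal(m$c_min_ss, 10)
  expect_equal(m$c_avg_ss, 10)
  expect_equal(m$auc, 240)

  tt <- seq(0, 24, by = 0.1)
  tri <- structure(
    data.frame(time = tt,
               maternal_plasma = pmax(0, 10 - 2.5 * abs(tt - 4))),
    class = c("conc_profile", "data.frame"), interval = 24)
  m2 <- compute_pk_metrics(tri)
  expect_equal(m2$c_max, 10)
  expect_equal(m2$t_max, 4)

  short <- flat_profile(10, interval = 24, t_end = 12)
  expect_error(compute_pk_metrics(short), "shorter")
})

test_that("interval AUC is dose-proportional in the simulated model", {
  s <- fast_settings()
  a10 <- compute_pk_metrics(simulate_individual(esc, phys_gw0,
                                                dose_regimen(10), s))$auc
  a20 <- compute_pk_metrics(simulate_individual(esc, phys_gw0,
                                                dose_regimen(20), s))$auc
  expect_equal(a20, 2 * a10, tolerance = 1e-12)
})

test_that("prediction ratio flags the published acceptance band", {
  r <- prediction_ratio(5, 5)
  expect_equal(as.numeric(r), 1.0)
  expect_true(attr(r, "acceptable"))
  expect_true(attr(prediction_ratio(0.7, 1.0), "acceptable"))
  expect_false(attr(prediction_ratio(2, 1), "acceptable"))
  expect_error(prediction_ratio(1, 0), "positive")
  # reciprocal pairs multiply to one
  set.seed(31)
  for (i in 1:5) {
    a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, 0.1, 10)
    expect_equal(as.numeric(prediction_ratio(a, b)) *
                   as.numeric(prediction_ratio(b, a)), 1,
                 tolerance = 1e-12)
  }
})

test_that("AAFE matches hand-evaluated folds and its identities", {
  expect_equal(aafe(c(3, 3, 3), c(3, 3, 3)), 1.0)
  expect_equal(aafe(0.80902, 1.03), 1.27, tolerance = 0.005)
  expect_equal(aafe(c(2, 1), c(1, 2)), 2.0, tolerance = 1e-12)
  # symmetric under global inversion; never below 1
  set.seed(32)
  p <- stats::runif(20, 0.1, 10)
  o <- stats::runif(20, 0.1, 10)
  expect_equal(aafe(p, o), aafe(o, p), tolerance = 1e-12)
  expect_gte(aafe(p, o), 1)
  expect_error(aafe(c(1, -1), c(1, 1)), "positive")
})

test_that("band coverage counts interpolated inclusion", {
  band <- data.frame(time = 0:24, mean = 2, p5 = 1, p95 = 3)
  on_mean <- data.frame(time_h = c(2, 8, 16), conc = c(2, 2, 2))
  expect_equal(coverage_check(on_mean, band), 1.0)
  half <- data.frame(time_h = c(5, 10), conc = c(2, 4))
  expect_equal(coverage_check(half, band), 0.5)
  above <- data.frame(time_h = c(5, 10), conc = c(5, 7))
  expect_equal(coverage_check(above, band), 0.0)
  expect_error(coverage_check(band[0, c("time", "mean")], band), "empty")
})

test_that("Morris screening recovers analytic elementary effects", {
  a <- c(x1 = 3, x2 = -1, x3 = 0, x4 = 0.5)
  model <- function(x) c(y = sum(a * x[names(a)]))
  ranges <- stats::setNames(rep(list(c(0, 1)), 4), names(a))
  res <- morris_screening(model, ranges, r = 8, seed = 2)
  df <- res$outputs$y
  mu <- stats::setNames(df$mu_star, df$parameter)[names(a)]
  expect_equal(unname(mu), abs(unname(a)), tolerance = 1e-9)
  expect_equal(mu[["x3"]], 0)
  expect_equal(df$parameter[1], "x1")
})
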