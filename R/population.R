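# Virtual populations: log-normal parameter variability (median-preserving)
# and CYP2C19 phenotype structure.

#' CYP2C19 phenotype specification
#'
#' Activity multipliers scale the CYP2C19 intrinsic clearance. The packaged
#' defaults ({UM 1.3, NM 1.0, IM 0.75, PM 0.6}) were calibrated so that the
#' simulated phenotype spread of steady-state exposure matches the model's
#' qualification data (IM/NM AUC ratio ~1.12 and the published trough-
#' concentration ranges), see the methods vignette. Frequencies default to a
#' Caucasian population fixture (PM ~2%).
#'
#' @param phenotype one of `"UM"`, `"NM"`, `"IM"`, `"PM"`
#' @param frequency population frequency, fraction
#' @param activity_multiplier multiplier on the CYP2C19 CLint
#' @return an object of class `phenotype_spec`
#' @export
phenotype_spec <- function(phenotype, frequency, activity_multiplier) {
  phenotype <- match.arg(phenotype, c("UM", "NM", "IM", "PM"))
  if (frequency < 0 || frequency > 1) stop_domain("frequency must be in [0,1]")
  if (activity_multiplier < 0) stop_domain("multiplier must be non-negative")
  structure(list(phenotype = phenotype, frequency = frequency,
                 activity_multiplier = activity_multiplier),
            class = "phenotype_spec")
}

#' Default CYP2C19 phenotype set (Caucasian frequency fixture)
#'
#' @return list of [phenotype_spec()] with frequencies
#'   {PM 0.02, IM 0.26, NM 0.60, UM 0.12} and activity multipliers
#'   {UM 1.3, NM 1.0, IM 0.75, PM 0.6}
#' @export
default_phenotypes <- function() {
  list(phenotype_spec("UM", 0.12, 1.3),
       phenotype_spec("NM", 0.60, 1.0),
       phenotype_spec("IM", 0.26, 0.75),
       phenotype_spec("PM", 0.02, 0.6))
}

#' Activity multiplier lookup for one phenotype
#' @param phenotype phenotype label
#' @param phenotypes list of [phenotype_spec()]
#' @return named CLint multiplier vector usable as `phenotype_multipliers`
#' @export
phenotype_multiplier <- function(phenotype, phenotypes = default_phenotypes()) {
  for (p in phenotypes)
    if (p$phenotype == phenotype)
      return(c(CYP2C19 = p$activity_multiplier))
  stop_domain("unknown phenotype: ", phenotype)
}

#' Population simulation specification
#'
#' @param n_subjects_per_trial subjects per virtual trial
#' @param n_trials number of virtual trials (total n = product)
#' @param gw gestational week of the population
#' @param cv_map named coefficients of variation (log-normal,
#'   median-preserving) for `clint`, `k_absorption`, `kp_scalar`, `fu_plasma`
#' @param seed integer seed
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_subjects_per_trial = 10, n_trials = 10, gw = 0,
                            cv_map = c(clint = 0.35, k_absorption = 0.25,
                                       kp_scalar = 0.20, fu_plasma = 0.15),
                            seed = 1) {
  if (n_subjects_per_trial < 1 || n_trials < 1)
    stop_domain("trial counts must be at least 1")
  if (any(cv_map < 0)) stop_domain("CVs must be non-negative")
  structure(list(n_subjects_per_trial = n_subjects_per_trial,
                 n_trials = n_trials, gw = gw, cv_map = cv_map, seed = seed),
            class = "population_spec")
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = 0, sd = sdlog))   # median 1
}

#' Sample virtual individuals
#'
#' Draws reproducible log-normal perturbations of the per-isoform CLints,
#' absorption rate, Kp scalar, and fraction unbound around the compound
#' defaults (median-preserving), assigns a CYP2C19 phenotype by frequency,
#' and folds the phenotype activity multiplier into the CYP2C19 CLint.
#'
#' @param spec a [population_spec()]
#' @param compound a [compound_record()]
#' @param phenotypes list of [phenotype_spec()]; frequencies must sum to 1
#' @return list of individuals, each a list with elements `compound`
#'   (perturbed record) and `phenotype`
#' @export
sample_individuals <- function(spec, compound = load_compound(),
                               phenotypes = default_phenotypes()) {
  freqs <- vapply(phenotypes, function(p) p$frequency, numeric(1))
  if (abs(sum(freqs) - 1) > 1e-9)
    stop_domain("phenotype frequencies must sum to 1 (got ", sum(freqs), ")")
  n <- spec$n_subjects_per_trial * spec$n_trials
  cv <- spec$cv_map
  set.seed(spec$seed)
  f_clint <- vapply(1:3, function(i) lognormal_factor(n, cv[["clint"]]),
                    numeric(n))
  if (n == 1) f_clint <- matrix(f_clint, nrow = 1)
  f_ka <- lognormal_factor(n, cv[["k_absorption"]])
  f_kp <- lognormal_factor(n, cv[["kp_scalar"]])
  f_fu <- lognormal_factor(n, cv[["fu_plasma"]])
  phen_idx <- sample.int(length(phenotypes), n, replace = TRUE, prob = freqs)

  lapply(seq_len(n), function(i) {
    cmp <- compound
    ph <- phenotypes[[phen_idx[i]]]
    cl <- compound$clint_by_isoform * f_clint[i, ]
    cl[["CYP2C19"]] <- cl[["CYP2C19"]] * ph$activity_multiplier
    cmp$clint_by_isoform <- cl
    cmp$k_absorption <- compound$k_absorption * f_ka[i]
    cmp$kp_scalar <- compound$kp_scalar * f_kp[i]
    cmp$fu_plasma <- min(compound$fu_plasma * f_fu[i], 1)
    list(compound = cmp, phenotype = ph$phenotype, subject_id = i)
  })
}

#' Run a population simulation and summarize percentile bands
#'
#' Simulates every sampled individual at the spec's gestational week and
#' aggregates the mean and the 5th/95th percentile profiles on the common
#' output grid, plus per-subject PK summaries over the final dosing interval.
#'
#' @param spec a [population_spec()]
#' @param compound a [compound_record()]
#' @param regimen a [dose_regimen()]
#' @param phenotypes list of [phenotype_spec()]
#' @param settings a [sim_settings()]; the default favors speed over the
#'   single-profile default tolerances
#' @param include_fetus simulate the fetoplacental unit (gw >= 15 only)
#' @return object of class `population_summary`: data.frame with `time`,
#'   `mean`, `p5`, `p95` (ng/mL) and attributes `pk` (per-subject metrics
#'   data.frame) and `phenotype` assignments
#' @export
run_population <- function(spec, compound = load_compound(),
                           regimen = dose_regimen(10),
                           phenotypes = default_phenotypes(),
                           settings = fast_settings(),
                           include_fetus = FALSE) {
  phys <- build_physiology(spec$gw)
  inds <- sample_individuals(spec, compound, phenotypes)
  simulate_one <- if (include_fetus) simulate_pregnant_with_fetus else
    simulate_individual
  profs <- lapply(inds, function(ind)
    tryCatch(simulate_one(ind$compound, phys, regimen, settings),
             error = function(e)
               stop("subject ", ind$subject_id, ": ", conditionMessage(e),
                    call. = FALSE)))
  conc <- vapply(profs, function(p) p$maternal_plasma,
                 numeric(nrow(profs[[1]])))
  if (nrow(profs[[1]]) == 1) conc <- matrix(conc, nrow = 1)
  pk <- do.call(rbind, lapply(seq_along(profs), function(i) {
    m <- compute_pk_metrics(profs[[i]])
    data.frame(subject_id = i, phenotype = inds[[i]]$phenotype,
               c_max = m$c_max, auc = m$auc, c_min_ss = m$c_min_ss,
               c_avg_ss = m$c_avg_ss, c_max_ss = m$c_max_ss)
  }))
  out <- data.frame(time = profs[[1]]$time,
                    mean = rowMeans(conc),
                    p5 = apply(conc, 1, stats::quantile, probs = 0.05),
                    p95 = apply(conc, 1, stats::quantile, probs = 0.95))
  structure(out, class = c("population_summary", "data.frame"),
            pk = pk, gw = spec$gw, dose = regimen$dose,
            interval = regimen$interval, n = length(profs))
}

#' @export
print.population_summary <- function(x, ...) {
  pk <- attr(x, "pk")
  cat("<population_summary>", attr(x, "n"), "subjects, gw", attr(x, "gw"),
      ", dose", attr(x, "dose"), "mg\n")
  cat("  mean AUC_tau,ss:", round(mean(pk$auc), 1), "ng*h/mL; mean Cmax,ss:",
      round(mean(pk$c_max_ss), 2), "ng/mL\n")
  invisible(x)
}
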