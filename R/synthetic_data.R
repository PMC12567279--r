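# Synthetic "observed" datasets: sparse steady-state sampling of maternal
# plasma (and optionally a cord/maternal pair at delivery) with proportional
# log-normal residual error around the model's own predictions. These stand
# in for clinical observations so the verification and estimation stages are
# testable end to end.

#' Generate a synthetic observed dataset
#'
#' Per subject: draws individual parameters (via [sample_individuals()] when
#' population CVs are nonzero), simulates the truth model, samples it at the
#' requested times, and multiplies by a log-normal residual with coefficient
#' of variation `noise_cv` (median-preserving). Fully reproducible from
#' `seed`.
#'
#' @param compound truth [compound_record()]
#' @param gw gestational week of the truth physiology
#' @param regimen truth [dose_regimen()]
#' @param sampling_times observation times, h (within the simulated horizon)
#' @param noise_cv residual proportional CV (>= 0)
#' @param n_subjects number of subjects
#' @param seed integer seed
#' @param population_cv named CV map for between-subject variability
#'   (all zero by default: residual error only)
#' @param phenotypes list of [phenotype_spec()] used when sampling subjects
#' @param site `"maternal"` or `"cord"`; cord sampling requires gw >= 15
#' @param settings a [sim_settings()]
#' @return data.frame of class `observed_dataset` with columns `subject_id`,
#'   `gw`, `dose`, `time_h`, `conc`, `site`; generation metadata in
#'   attributes
#' @export
generate_observed <- function(compound = load_compound(), gw = 0,
                              regimen = dose_regimen(10),
                              sampling_times = c(1, 2, 4, 6, 12, 24) +
                                (regimen$n_doses - 1) * regimen$interval,
                              noise_cv = 0.2, n_subjects = 1, seed = 1,
                              population_cv = c(clint = 0, k_absorption = 0,
                                                kp_scalar = 0, fu_plasma = 0),
                              phenotypes = list(phenotype_spec("NM", 1, 1)),
                              site = "maternal",
                              settings = fast_settings()) {
  if (noise_cv < 0) stop_domain("noise_cv must be non-negative")
  site <- match.arg(site, c("maternal", "cord"))
  horizon <- regimen$n_doses * regimen$interval + settings$horizon_extra
  if (any(sampling_times > horizon))
    stop_domain("sampling time beyond the simulated horizon (", horizon, " h)")

  phys <- build_physiology(gw)
  pspec <- population_spec(n_subjects_per_trial = n_subjects, n_trials = 1,
                           gw = gw, cv_map = population_cv, seed = seed)
  inds <- sample_individuals(pspec, compound, phenotypes)
  simulate_one <- if (site == "cord") simulate_pregnant_with_fetus else
    simulate_individual

  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  rows <- lapply(inds, function(ind) {
    prof <- simulate_one(ind$compound, phys, regimen, settings)
    col <- if (site == "cord") "fetal_plasma" else "maternal_plasma"
    pred <- stats::approx(prof$time, prof[[col]], xout = sampling_times)$y
    eps <- if (sdlog > 0)
      exp(stats::rnorm(length(pred), 0, sdlog)) else rep(1, length(pred))
    data.frame(subject_id = ind$subject_id, gw = gw, dose = regimen$dose,
               time_h = sampling_times, conc = pred * eps, site = site)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("observed_dataset", "data.frame"),
            seed = seed, noise_cv = noise_cv,
            truth = list(compound = compound, gw = gw, regimen = regimen))
}

#' Write an observed dataset in the observed-data CSV dialect
#' @param observed an `observed_dataset`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_observed_csv <- function(observed, path) {
  utils::write.csv(as.data.frame(observed), path, row.names = FALSE)
  invisible(path)
}

#' Read an observed-data CSV (columns subject_id, time_h, conc, ...)
#' @param path CSV path
#' @return data.frame
#' @export
read_observed_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
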