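# Reproducible pipeline stages over a structured config. Each stage writes
# its tables under an output directory together with a run manifest
# (config hash, seed, package version); identical config and seed give
# identical numeric outputs.

default_run_config <- function() {
  list(
    compound_file = escipbpk_fixture("escitalopram.csv"),
    dose = 10, interval = 24, n_doses = 10,
    gws = c(0, 20, 35),
    gw_term = 40,
    population = list(n_subjects_per_trial = 10, n_trials = 10),
    doseopt = list(doses = c(10, 20), gws = c(7, 21, 35),
                   n_subjects_per_trial = 20, n_trials = 20),
    synth = list(noise_cv = 0.2, n_subjects = 6,
                 sampling_times = c(1, 2, 4, 6, 12, 24)),
    fit = list(n_restarts = 10, maxit = 300),
    sensitivity = list(r = 20, levels = 4),
    seed = 1
  )
}

load_run_config <- function(config) {
  base <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "))
  modifyList(base, config)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, stage, out_dir, files) {
  manifest <- list(stage = stage, seed = config$seed,
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("escipbpk")),
                   files = files)
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
}

#' Run one pipeline stage
#'
#' Stages: `nonpregnant` (gw-0 PK summary), `pregnant` (PK summaries across
#' gestational weeks with percent change from week 0), `fetal` (fetoplacental
#' simulation at term with cord-to-maternal ratio), `phenotypes`
#' (per-phenotype population PK), `doseopt` (therapeutic-window assessment
#' table), `synth` (synthetic observed dataset), `verify`
#' (prediction-ratio/AAFE/coverage report of the model against a synthetic
#' dataset), `fit` (parameter re-estimation from synthetic data),
#' `sensitivity` (Morris screening).
#'
#' @param config a config list or YAML file path (missing keys take
#'   defaults; unknown keys are rejected)
#' @param stage stage name
#' @param out_dir output directory (created if needed)
#' @return the stage's main result object, invisibly; tables and a manifest
#'   are written under `out_dir`
#' @export
run_pipeline <- function(config = list(), stage, out_dir = "results") {
  stage <- match.arg(stage, c("nonpregnant", "pregnant", "fetal",
                              "phenotypes", "doseopt", "verify", "fit",
                              "sensitivity", "synth"))
  cfg <- load_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  compound <- load_compound(cfg$compound_file)
  regimen <- dose_regimen(cfg$dose, cfg$interval, cfg$n_doses)

  result <- switch(stage,
    nonpregnant = {
      prof <- simulate_individual(compound, build_physiology(0), regimen)
      m <- compute_pk_metrics(prof)
      df <- data.frame(gw = 0, dose_mg = cfg$dose,
                       c_max = m$c_max, t_max = m$t_max, auc = m$auc,
                       c_min_ss = m$c_min_ss, c_avg_ss = m$c_avg_ss)
      utils::write.csv(df, file.path(out_dir, "pk_summary_nonpregnant.csv"),
                       row.names = FALSE)
      df
    },
    pregnant = {
      df <- do.call(rbind, lapply(cfg$gws, function(gw) {
        prof <- simulate_individual(compound, build_physiology(gw), regimen)
        m <- compute_pk_metrics(prof)
        data.frame(gw = gw, dose_mg = cfg$dose, c_max = m$c_max,
                   t_max = m$t_max, auc = m$auc)
      }))
      ref <- df[df$gw == min(df$gw), ]
      df$cmax_change_pct <- 100 * (ref$c_max - df$c_max) / ref$c_max
      df$auc_change_pct <- 100 * (ref$auc - df$auc) / ref$auc
      utils::write.csv(df, file.path(out_dir, "pk_summary_pregnancy.csv"),
                       row.names = FALSE)
      df
    },
    fetal = {
      prof <- simulate_pregnant_with_fetus(compound,
                                           build_physiology(cfg$gw_term),
                                           regimen)
      ratio <- cord_to_maternal_ratio(prof)
      write_profile_csv(prof, file.path(out_dir, "profile_fetal_term.csv"))
      df <- data.frame(gw = cfg$gw_term, dose_mg = cfg$dose,
                       cord_maternal_ratio = as.numeric(ratio),
                       trough_ratio = attr(ratio, "trough_ratio"))
      utils::write.csv(df, file.path(out_dir, "cord_maternal_ratio.csv"),
                       row.names = FALSE)
      df
    },
    phenotypes = {
      df <- do.call(rbind, lapply(c("UM", "NM", "IM", "PM"), function(ph) {
        pure <- list(phenotype_spec(ph, 1,
                                    phenotype_multiplier(ph)[["CYP2C19"]]))
        spec <- population_spec(cfg$population$n_subjects_per_trial,
                                cfg$population$n_trials,
                                gw = max(cfg$gws), seed = cfg$seed)
        pop <- run_population(spec, compound, regimen, phenotypes = pure)
        pk <- attr(pop, "pk")
        data.frame(phenotype = ph, gw = max(cfg$gws), dose_mg = cfg$dose,
                   mean_auc = mean(pk$auc), mean_cmax = mean(pk$c_max_ss),
                   mean_cmin = mean(pk$c_min_ss))
      }))
      utils::write.csv(df, file.path(out_dir, "pk_by_phenotype.csv"),
                       row.names = FALSE)
      df
    },
    doseopt = {
      tab <- assess_regimen(doses = cfg$doseopt$doses, gws = cfg$doseopt$gws,
                            compound = compound,
                            n_subjects_per_trial =
                              cfg$doseopt$n_subjects_per_trial,
                            n_trials = cfg$doseopt$n_trials,
                            seed = cfg$seed)
      utils::write.csv(as.data.frame(tab),
                       file.path(out_dir, "dose_assessment.csv"),
                       row.names = FALSE)
      tab
    },
    synth = {
      obs <- generate_observed(compound, gw = 0, regimen = regimen,
                               sampling_times = cfg$synth$sampling_times +
                                 (cfg$n_doses - 1) * cfg$interval,
                               noise_cv = cfg$synth$noise_cv,
                               n_subjects = cfg$synth$n_subjects,
                               seed = cfg$seed)
      write_observed_csv(obs, file.path(out_dir, "synthetic_observed.csv"))
      obs
    },
    verify = {
      obs <- generate_observed(compound, gw = 0, regimen = regimen,
                               sampling_times = cfg$synth$sampling_times +
                                 (cfg$n_doses - 1) * cfg$interval,
                               noise_cv = cfg$synth$noise_cv,
                               n_subjects = cfg$synth$n_subjects,
                               seed = cfg$seed)
      prof <- simulate_individual(compound, build_physiology(0), regimen)
      pred <- stats::approx(prof$time, prof$maternal_plasma,
                            xout = obs$time_h)$y
      obs_mean <- stats::aggregate(conc ~ time_h, obs, mean)
      pred_mean <- stats::approx(prof$time, prof$maternal_plasma,
                                 xout = obs_mean$time_h)$y
      m_pred <- compute_pk_metrics(prof)
      ratios <- c(
        c_max = as.numeric(prediction_ratio(m_pred$c_max_ss,
                                            max(obs_mean$conc))),
        auc = as.numeric(prediction_ratio(
          m_pred$auc, trapz(obs_mean$time_h, obs_mean$conc) /
            diff(range(obs_mean$time_h)) * cfg$interval)))
      spec <- population_spec(cfg$population$n_subjects_per_trial,
                              cfg$population$n_trials, gw = 0,
                              seed = cfg$seed + 1)
      band <- run_population(spec, compound, regimen)
      rep <- verification_report(ratios, aafe(pred, obs$conc), nrow(obs),
                                 coverage_check(obs, band))
      out <- data.frame(metric = c(names(rep$prediction_ratios), "aafe",
                                   "coverage"),
                        value = c(rep$prediction_ratios, rep$aafe,
                                  rep$coverage_fraction))
      utils::write.csv(out, file.path(out_dir, "verification_report.csv"),
                       row.names = FALSE)
      rep
    },
    fit = {
      obs <- generate_observed(compound, gw = 0,
                               regimen = dose_regimen(cfg$dose, n_doses = 1),
                               sampling_times = c(1, 2, 4, 6, 8, 12, 24, 36,
                                                  48),
                               noise_cv = cfg$synth$noise_cv,
                               n_subjects = cfg$synth$n_subjects,
                               seed = cfg$seed,
                               settings = sim_settings(rtol = 1e-6,
                                                       atol = 1e-8,
                                                       grid = 0.25,
                                                       horizon_extra = 24))
      fit <- fit_parameters(obs, compound, build_physiology(0),
                            dose_regimen(cfg$dose, n_doses = 1,
                                         interval = 72),
                            fit_spec(n_restarts = cfg$fit$n_restarts,
                                     maxit = cfg$fit$maxit,
                                     seed = cfg$seed))
      utils::write.csv(fit$restarts, file.path(out_dir, "fit_restarts.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(parameter = names(fit$estimates),
                                  estimate = fit$estimates),
                       file.path(out_dir, "fit_estimates.csv"),
                       row.names = FALSE)
      fit
    },
    sensitivity = {
      setup <- morris_setup_nonpregnant(compound)
      res <- morris_screening(setup$model, setup$ranges,
                              r = cfg$sensitivity$r,
                              levels = cfg$sensitivity$levels,
                              seed = cfg$seed)
      df <- do.call(rbind, lapply(names(res$outputs), function(out)
        cbind(output = out, res$outputs[[out]])))
      utils::write.csv(df, file.path(out_dir, "morris_mu_star.csv"),
                       row.names = FALSE)
      res
    })

  files <- setdiff(list.files(out_dir), "manifest.yaml")
  write_manifest(cfg, stage, out_dir, files)
  invisible(result)
}
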