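# Therapeutic-window dose assessment across CYP2C19 phenotypes and
# trimesters.

#' Therapeutic window for escitalopram trough concentrations
#'
#' Steady-state trough range 15-80 ng/mL, laboratory alert level 160 ng/mL,
#' and the 17 ng/mL average-concentration threshold associated with >80%
#' serotonin-transporter occupancy.
#'
#' @param trough_lower,trough_upper trough range bounds, ng/mL
#' @param alert_level laboratory alert level, ng/mL
#' @param cavg_threshold Cavg,ss efficacy threshold, ng/mL
#' @return an object of class `therapeutic_window`
#' @export
therapeutic_window <- function(trough_lower = 15, trough_upper = 80,
                               alert_level = 160, cavg_threshold = 17) {
  if (!(trough_lower < trough_upper && trough_upper < alert_level))
    stop_domain("window must satisfy lower < upper < alert")
  structure(list(trough_lower = trough_lower, trough_upper = trough_upper,
                 alert_level = alert_level, cavg_threshold = cavg_threshold),
            class = "therapeutic_window")
}

#' Classify one exposure summary against the therapeutic window
#'
#' `subtherapeutic` iff the trough is below the lower bound; `within` iff
#' the trough is at/above the lower bound and the peak at/below the upper;
#' `above` iff the peak exceeds the upper bound; `alert` iff the peak
#' reaches the alert level. `near_lower` flags troughs within 20% below the
#' lower bound (reported distinctly, never merged into `within`).
#'
#' @param c_min_ss,c_max_ss,c_avg_ss steady-state trough/peak/average, ng/mL
#' @param window a [therapeutic_window()]
#' @return list with `classification`, `cavg_meets_threshold`, `near_lower`
#' @export
classify_exposure <- function(c_min_ss, c_max_ss, c_avg_ss,
                              window = therapeutic_window()) {
  cls <- if (c_max_ss >= window$alert_level) "alert"
  else if (c_max_ss > window$trough_upper) "above"
  else if (c_min_ss < window$trough_lower) "subtherapeutic"
  else "within"
  list(classification = cls,
       cavg_meets_threshold = c_avg_ss >= window$cavg_threshold,
       near_lower = c_min_ss < window$trough_lower &
         c_min_ss >= 0.8 * window$trough_lower)
}

#' Assess dosing regimens across phenotypes and gestational weeks
#'
#' For every (dose, gestational week, phenotype) cell, simulates a
#' phenotype-pure virtual population, summarizes the population-mean profile
#' over the final dosing interval, and classifies it against the therapeutic
#' window. The 5th-percentile subject's trough is reported alongside.
#'
#' @param doses doses to assess, mg
#' @param gws gestational weeks (trimester representatives default 7, 21, 35)
#' @param phenotype_names phenotypes to assess
#' @param window a [therapeutic_window()]
#' @param compound a [compound_record()]
#' @param n_subjects_per_trial,n_trials population size per cell (default
#'   20 x 20)
#' @param phenotypes list of [phenotype_spec()] providing the multipliers
#' @param seed integer seed
#' @param settings a [sim_settings()]
#' @return data.frame of class `dose_assessment` with columns `dose_mg`,
#'   `gw`, `phenotype`, `cmin_ss`, `cavg_ss`, `cmax_ss`, `cmin_p5_subject`,
#'   `classification`, `cavg_flag`, `near_lower`
#' @export
assess_regimen <- function(doses = c(10, 20), gws = c(7, 21, 35),
                           phenotype_names = c("UM", "NM", "IM", "PM"),
                           window = therapeutic_window(),
                           compound = load_compound(),
                           n_subjects_per_trial = 20, n_trials = 20,
                           phenotypes = default_phenotypes(), seed = 1,
                           settings = fast_settings()) {
  cells <- expand.grid(gw = gws, phenotype = phenotype_names,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    pure <- list(phenotype_spec(cell$phenotype, 1,
                                phenotype_multiplier(cell$phenotype,
                                                     phenotypes)[["CYP2C19"]]))
    spec <- population_spec(n_subjects_per_trial, n_trials, gw = cell$gw,
                            seed = seed + i)
    # the model is dose-linear: simulate each (gw, phenotype) population at
    # a 1 mg reference dose and rescale the metrics per dose
    pop <- run_population(spec, compound, dose_regimen(1),
                          phenotypes = pure, settings = settings)
    m <- compute_pk_metrics(pop, interval = attr(pop, "interval"),
                            column = "mean")
    pk <- attr(pop, "pk")
    cmin_p5 <- stats::quantile(pk$c_min_ss, 0.05, names = FALSE)
    do.call(rbind, lapply(doses, function(d) {
      cls <- classify_exposure(d * m$c_min_ss, d * m$c_max_ss,
                               d * m$c_avg_ss, window)
      data.frame(dose_mg = d, gw = cell$gw, phenotype = cell$phenotype,
                 cmin_ss = d * m$c_min_ss, cavg_ss = d * m$c_avg_ss,
                 cmax_ss = d * m$c_max_ss,
                 cmin_p5_subject = d * cmin_p5,
                 classification = cls$classification,
                 cavg_flag = cls$cavg_meets_threshold,
                 near_lower = cls$near_lower)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dose_mg, out$gw, out$phenotype), ]
  rownames(out) <- NULL
  structure(out, class = c("dose_assessment", "data.frame"))
}
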