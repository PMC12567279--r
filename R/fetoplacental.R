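# Fetoplacental unit: a small placental tissue node between two
# permeability barriers (maternal-placental CL_PDM and placental-fetal
# CL_PDF), a fetal plasma compartment, and an amniotic fluid compartment.
# Transfer across both barriers is driven by unbound concentrations. Fetal
# renal clearance (per-kg value times current fetal weight) moves drug from
# fetal plasma into amniotic fluid; swallowing clearance returns it to fetal
# plasma (fully reabsorbed). The unit's only exit is back-transfer to the
# mother, so fetoplacental mass balance is closed.

#' Simulate a pregnant individual including the fetoplacental unit
#'
#' Maternal whole-body model plus placental node, fetal plasma, and amniotic
#' fluid compartments. Active from gestational week 15.
#'
#' @inheritParams simulate_individual
#' @return a `conc_profile` with columns `time`, `maternal_plasma`,
#'   `fetal_plasma`, `amniotic` (ng/mL)
#' @export
simulate_pregnant_with_fetus <- function(compound, physiology, regimen,
                                         settings = sim_settings(),
                                         phenotype_multipliers = NULL) {
  if (physiology$gw < 15)
    stop_domain("the fetoplacental unit is implemented from gestational ",
                "week 15; got gw = ", physiology$gw)
  pars <- build_model_pars(compound, physiology, phenotype_multipliers,
                           include_fetus = TRUE)
  finish_profile(pars, compound, physiology, regimen, settings)
}

#' Cord-to-maternal concentration ratio over the final dosing interval
#'
#' Ratio of the time-averaged fetal (cord) to time-averaged maternal plasma
#' concentration over the last dosing interval of the profile. The trough
#' (end-of-interval) ratio is attached as attribute `trough_ratio`.
#'
#' @param profile a `conc_profile` containing a `fetal_plasma` series
#' @param interval averaging interval, h; defaults to the profile's dosing
#'   interval
#' @return the time-averaged concentration ratio (dimensionless)
#' @export
cord_to_maternal_ratio <- function(profile, interval = attr(profile, "interval")) {
  if (is.null(profile$fetal_plasma))
    stop_domain("profile has no fetal series; run the fetoplacental model")
  t_end <- max(profile$time)
  sel <- profile$time >= t_end - interval
  tt <- profile$time[sel]
  auc_f <- trapz(tt, profile$fetal_plasma[sel])
  auc_m <- trapz(tt, profile$maternal_plasma[sel])
  ratio <- auc_f / auc_m
  last <- which.max(profile$time)
  structure(ratio, trough_ratio =
              profile$fetal_plasma[last] / profile$maternal_plasma[last])
}
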