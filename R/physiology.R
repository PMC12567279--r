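# Maternal and fetal physiology as continuous functions of gestational age.
#
# Every pregnancy trajectory is a fourth-order polynomial multiplier on the
# gestational-week-0 baseline:
#   value(GW) = GW0 * (1 + b1*GW + b2*GW^2 + b3*GW^3 + b4*GW^4)
# CYP2D6 and CYP3A4 activity use published induction coefficients
# (b1 = 0.0163, b2 = 0.0009 and b1 = 0.0129, b2 = 0.0005 respectively);
# CYP2C19 activity is held constant (all coefficients zero). The remaining
# trajectories (cardiac output, GFR, binding-protein concentration, plasma
# volume) are packaged fixtures in the same polynomial form and can be
# overridden.

#' Pregnancy scaling coefficients
#'
#' A baseline value plus four polynomial coefficients describing its change
#' with gestational week (GW):
#' `value(GW) = baseline * (1 + b1*GW + b2*GW^2 + b3*GW^3 + b4*GW^4)`.
#'
#' @param baseline value at gestational week 0, in the parameter's own units
#' @param b1,b2,b3,b4 polynomial coefficients per week, week^2, week^3, week^4
#' @return an object of class `preg_coeffs`
#' @export
preg_coeffs <- function(baseline, b1 = 0, b2 = 0, b3 = 0, b4 = 0) {
  stopifnot(is.numeric(baseline), length(baseline) == 1)
  structure(list(baseline = baseline, b = c(b1, b2, b3, b4)),
            class = "preg_coeffs")
}

#' Evaluate a gestational scaling polynomial
#'
#' @param coeffs a [preg_coeffs()] object
#' @param gw gestational week(s), must be non-negative
#' @return the scaled physical quantity, same length as `gw`
#' @examples
#' cyp2d6 <- preg_coeffs(1, b1 = 0.0163, b2 = 0.0009)
#' scale_parameter(cyp2d6, 35)  # 2.673
#' @export
scale_parameter <- function(coeffs, gw) {
  stopifnot(inherits(coeffs, "preg_coeffs"))
  if (any(gw < 0)) stop_domain("gestational week must be non-negative")
  b <- coeffs$b
  coeffs$baseline * (1 + b[1] * gw + b[2] * gw^2 + b[3] * gw^3 + b[4] * gw^4)
}

#' Scale the fraction unbound for a changed binding-protein concentration
#'
#' Assumes linear binding to a single protein, so the bound:free ratio scales
#' with the protein concentration:
#' `fu' = 1 / (1 + ((1 - fu)/fu) * protein_ratio)`.
#'
#' @param fu_baseline baseline fraction unbound, in (0, 1]
#' @param protein_ratio binding-protein concentration relative to baseline (> 0)
#' @return scaled fraction unbound
#' @export
scale_fraction_unbound <- function(fu_baseline, protein_ratio) {
  if (any(fu_baseline <= 0) || any(fu_baseline > 1))
    stop_domain("fu_baseline must be in (0, 1]")
  if (any(protein_ratio <= 0)) stop_domain("protein_ratio must be positive")
  1 / (1 + ((1 - fu_baseline) / fu_baseline) * protein_ratio)
}

# Names of the 13 perfused compartments (plasma handled separately).
tissue_names <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
    "lung", "muscle", "skin", "spleen", "rest")
}

# Systemic flow entries; liver receives hepatic artery + gut + spleen outflow.
systemic_flow_names <- function() {
  c("adipose", "bone", "brain", "gut", "heart", "kidney", "hepatic_artery",
    "muscle", "skin", "spleen", "rest")
}

load_pregnancy_coeffs <- function(path = escipbpk_fixture("pregnancy_scaling.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    preg_coeffs(df$baseline[i], df$b1[i], df$b2[i], df$b3[i], df$b4[i]))
  names(out) <- df$name
  out
}

#' Fetal weight at a gestational week
#'
#' Smooth monotone growth curve anchored to the mean term weight (3.7 kg at
#' week 40); weight(GW) = 3.7 * (GW/40)^3.4 kg.
#'
#' @param gw gestational week
#' @param term_weight weight at week 40, kg
#' @return fetal weight in kg
#' @export
fetal_weight_at <- function(gw, term_weight = 3.7) {
  term_weight * (gw / 40)^3.4
}

#' Amniotic fluid volume at a gestational week
#'
#' Monotone fixture anchored to 0.75 L at term (consistent with a 750 mL/day
#' term swallowing volume); volume(GW) = 0.75 * (GW/40)^2 L.
#'
#' @param gw gestational week
#' @param term_volume volume at week 40, L
#' @return amniotic fluid volume in L
#' @export
amniotic_volume_at <- function(gw, term_volume = 0.75) {
  term_volume * (gw / 40)^2
}

#' Build a maternal (and, from week 15, fetal) physiology snapshot
#'
#' Assembles tissue volumes and blood flows, cardiac output, GFR, hepatic
#' enzyme abundances and gestational activity multipliers, the
#' binding-protein concentration ratio, and (for `gw >= 15`) the fetal and
#' amniotic parameters of the fetoplacental unit. Pregnancy trajectories are
#' polynomial multipliers on a nonpregnant-female reference table; all flows
#' are scaled proportionally with cardiac output so that systemic flows always
#' sum to cardiac output.
#'
#' @param gw gestational week, in `[0, 40]`
#' @param overrides named list replacing entries of the baseline table
#'   (see `physiology_baseline.csv`) before scaling
#' @param scaling named list of [preg_coeffs()] replacing packaged trajectories
#' @return an object of class `physiology` with elements `gw`,
#'   `tissue_volumes` (L), `tissue_flows` (L/h), `cardiac_output` (L/h),
#'   `hepatic_blood_flow` (L/h), `gfr` (mL/min), `gfr_ratio`, `hematocrit`,
#'   `binding_protein_conc_ratio`, `plasma_volume` (L), `liver_weight` (g),
#'   `mppgl` (mg/g), `enzyme_abundance` (pmol/mg), `enzyme_activity_multiplier`,
#'   `gut_cyp3a4_total` (pmol), `body_weight` (kg), and for `gw >= 15`
#'   `fetal_weight` (kg), `amniotic_volume` (L), `fetal_plasma_volume` (L),
#'   `placenta_volume` (L), `fetal_protein_ratio`, `fetal_gfr` (mL/min),
#'   `fetal_swallowed_volume` (mL/day)
#' @export
build_physiology <- function(gw, overrides = list(), scaling = list()) {
  if (gw < 0) stop_domain("gestational week must be non-negative")
  if (gw > 40) stop_domain("gestational week must not exceed 40")

  base <- as.list(read_named_csv(escipbpk_fixture("physiology_baseline.csv")))
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(base))
    if (length(unknown))
      stop_domain("unknown physiology override(s): ",
                  paste(unknown, collapse = ", "))
    base[names(overrides)] <- overrides
  }

  traj <- load_pregnancy_coeffs()
  if (length(scaling)) {
    unknown <- setdiff(names(scaling), names(traj))
    if (length(unknown))
      stop_domain("unknown scaling trajectory override(s): ",
                  paste(unknown, collapse = ", "))
    traj[names(scaling)] <- scaling
  }

  mult <- vapply(traj, scale_parameter, numeric(1), gw = gw)

  co <- base$cardiac_output * mult[["cardiac_output"]]
  flow_frac <- vapply(systemic_flow_names(),
                      function(nm) base[[paste0("flowfrac_", nm)]], numeric(1))
  flows_systemic <- flow_frac * co
  # liver outflow = hepatic artery + splanchnic inflow
  q_h <- flows_systemic[["hepatic_artery"]] + flows_systemic[["gut"]] +
    flows_systemic[["spleen"]]
  tissue_flows <- c(
    flows_systemic[setdiff(systemic_flow_names(), "hepatic_artery")],
    liver = unname(q_h), lung = unname(co))

  volumes <- vapply(tissue_names(),
                    function(nm) base[[paste0("volume_", nm)]], numeric(1))
  plasma_volume <- base$volume_plasma * mult[["plasma_volume"]]

  snap <- structure(list(
    gw = gw,
    body_weight = base$body_weight,
    tissue_volumes = volumes,
    tissue_flows = tissue_flows[tissue_names()],
    cardiac_output = co,
    hepatic_blood_flow = unname(q_h),
    gfr = base$gfr * mult[["gfr"]],
    gfr_baseline = base$gfr,
    gfr_ratio = unname(mult[["gfr"]]),
    hematocrit = base$hematocrit,
    binding_protein_conc_ratio = unname(mult[["binding_protein"]]),
    plasma_volume = plasma_volume,
    liver_weight = base$liver_weight,
    mppgl = base$mppgl,
    enzyme_abundance = c(CYP2C19 = base$abundance_cyp2c19,
                         CYP2D6 = base$abundance_cyp2d6,
                         CYP3A4 = base$abundance_cyp3a4),
    enzyme_activity_multiplier = c(CYP2C19 = unname(mult[["cyp2c19_activity"]]),
                                   CYP2D6 = unname(mult[["cyp2d6_activity"]]),
                                   CYP3A4 = unname(mult[["cyp3a4_activity"]])),
    gut_cyp3a4_total = base$gut_cyp3a4_total
  ), class = "physiology")

  if (gw >= 15) {
    fw <- fetal_weight_at(gw, base$fetal_weight_term)
    snap$fetal_weight <- fw
    snap$amniotic_volume <- amniotic_volume_at(gw, base$amniotic_volume_term)
    snap$fetal_plasma_volume <- base$fetal_plasma_volume_per_kg * fw
    snap$placenta_volume <- base$placenta_volume
    snap$fetal_protein_ratio <- base$fetal_protein_ratio
    snap$fetal_gfr <- base$fetal_gfr
    snap$fetal_swallowed_volume <- base$fetal_swallowed_volume
  }
  snap
}

#' @export
print.physiology <- function(x, ...) {
  cat("<physiology> gestational week", x$gw, "\n")
  cat("  cardiac output:", round(x$cardiac_output, 1), "L/h;",
      "GFR:", round(x$gfr, 1), "mL/min\n")
  cat("  CYP activity multipliers:",
      paste(names(x$enzyme_activity_multiplier),
            round(x$enzyme_activity_multiplier, 3), collapse = ", "), "\n")
  if (!is.null(x$fetal_weight))
    cat("  fetal weight:", round(x$fetal_weight, 2), "kg; amniotic volume:",
        round(x$amniotic_volume * 1000), "mL\n")
  invisible(x)
}
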