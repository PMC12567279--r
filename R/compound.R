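# Drug-specific parameters and the quantities derived from them.

#' Compound parameter record
#'
#' Holds all drug-specific inputs of the model: physicochemistry, binding,
#' first-order absorption, per-isoform hepatic intrinsic clearances, renal
#' clearance, and the two placental barrier clearances. The packaged
#' escitalopram defaults are loaded with [load_compound()].
#'
#' @param molecular_weight g/mol
#' @param logp octanol-water log partition coefficient
#' @param pka basic pKa (the compound is treated as a monoprotic base)
#' @param blood_to_plasma blood-to-plasma concentration ratio (B/P)
#' @param fu_plasma fraction unbound in plasma, in (0, 1]
#' @param f_absorbed fraction absorbed from the gut lumen, in (0, 1]
#' @param k_absorption first-order absorption rate constant, 1/h
#' @param fu_gut fraction unbound in gut enterocytes, in (0, 1]
#' @param q_gut hybrid gut flow/permeability parameter, L/h
#' @param kp_scalar uniform multiplier applied to predicted tissue Kp values
#' @param clint_by_isoform named vector, uL/min/pmol, for CYP2C19, CYP2D6,
#'   CYP3A4
#' @param cl_renal_adult adult renal clearance, L/h
#' @param cl_pdm maternal-placental barrier clearance, L/h
#' @param cl_pdf placental-fetal barrier clearance, L/h
#' @return an object of class `compound`
#' @export
compound_record <- function(molecular_weight, logp, pka, blood_to_plasma,
                            fu_plasma, f_absorbed, k_absorption, fu_gut,
                            q_gut, kp_scalar, clint_by_isoform,
                            cl_renal_adult, cl_pdm, cl_pdf) {
  fracs <- c(fu_plasma = fu_plasma, f_absorbed = f_absorbed, fu_gut = fu_gut)
  if (any(fracs <= 0) || any(fracs > 1))
    stop_domain("fractions must be in (0, 1]: ",
                paste(names(fracs)[fracs <= 0 | fracs > 1], collapse = ", "))
  nonneg <- c(k_absorption, q_gut, kp_scalar, clint_by_isoform,
              cl_renal_adult, cl_pdm, cl_pdf)
  if (any(nonneg < 0)) stop_domain("rates and clearances must be non-negative")
  stopifnot(all(c("CYP2C19", "CYP2D6", "CYP3A4") %in% names(clint_by_isoform)))
  structure(list(
    molecular_weight = molecular_weight, logp = logp, pka = pka,
    blood_to_plasma = blood_to_plasma, fu_plasma = fu_plasma,
    f_absorbed = f_absorbed, k_absorption = k_absorption, fu_gut = fu_gut,
    q_gut = q_gut, kp_scalar = kp_scalar,
    clint_by_isoform = clint_by_isoform[c("CYP2C19", "CYP2D6", "CYP3A4")],
    cl_renal_adult = cl_renal_adult, cl_pdm = cl_pdm, cl_pdf = cl_pdf
  ), class = "compound")
}

#' Load a compound parameter file
#'
#' Reads the tabular compound format (columns `name,value,units`); the
#' packaged default is the escitalopram parameter set.
#'
#' @param path CSV path; defaults to the packaged escitalopram fixture
#' @return a [compound_record()] object
#' @examples
#' drug <- load_compound()
#' drug$kp_scalar
#' @export
load_compound <- function(path = escipbpk_fixture("escitalopram.csv")) {
  v <- read_named_csv(path)
  compound_record(
    molecular_weight = v[["molecular_weight"]], logp = v[["logp"]],
    pka = v[["pka"]], blood_to_plasma = v[["blood_to_plasma"]],
    fu_plasma = v[["fu_plasma"]], f_absorbed = v[["f_absorbed"]],
    k_absorption = v[["k_absorption"]], fu_gut = v[["fu_gut"]],
    q_gut = v[["q_gut"]], kp_scalar = v[["kp_scalar"]],
    clint_by_isoform = c(CYP2C19 = v[["clint_cyp2c19"]],
                         CYP2D6 = v[["clint_cyp2d6"]],
                         CYP3A4 = v[["clint_cyp3a4"]]),
    cl_renal_adult = v[["cl_renal_adult"]],
    cl_pdm = v[["cl_pdm"]], cl_pdf = v[["cl_pdf"]])
}

#' @export
print.compound <- function(x, ...) {
  cat("<compound> MW", x$molecular_weight, "g/mol, logP", x$logp,
      ", pKa", x$pka, "(monoprotic base)\n")
  cat("  fu_p", x$fu_plasma, ", B/P", x$blood_to_plasma,
      ", ka", x$k_absorption, "/h, Kp scalar", x$kp_scalar, "\n")
  cat("  CLint (uL/min/pmol):",
      paste(names(x$clint_by_isoform), x$clint_by_isoform, collapse = ", "),
      "\n")
  invisible(x)
}

#' Fetal clearance through amniotic fluid swallowing
#'
#' `swallowed_volume / 24 / 1000 / fetal_weight`, expressed per kg fetal
#' weight. With the term reference values (750 mL/day, 3.7 kg) this gives
#' 0.00844 L/h/kg.
#'
#' @param swallowed_volume amniotic fluid swallowed, mL/day
#' @param fetal_weight fetal weight, kg
#' @return clearance in L/h per kg fetal weight
#' @export
fetal_swallowing_clearance <- function(swallowed_volume = 750,
                                       fetal_weight = 3.7) {
  if (any(fetal_weight <= 0)) stop_domain("fetal weight must be positive")
  if (any(swallowed_volume < 0))
    stop_domain("swallowed volume must be non-negative")
  swallowed_volume / 24 / 1000 / fetal_weight
}

#' Fetal renal clearance scaled from the adult value by the GFR ratio
#'
#' `cl_renal_adult * fetal_gfr / (fetal_weight * adult_gfr)`, per kg fetal
#' weight. With the reference values (4.0 L/h, 4.92 mL/min, 121 mL/min,
#' 3.7 kg) this gives 0.044 L/h/kg.
#'
#' @param cl_renal_adult adult renal clearance, L/h
#' @param fetal_gfr fetal glomerular filtration rate, mL/min
#' @param adult_gfr adult glomerular filtration rate, mL/min
#' @param fetal_weight fetal weight, kg
#' @return clearance in L/h per kg fetal weight
#' @export
fetal_renal_clearance <- function(cl_renal_adult = 4.0, fetal_gfr = 4.92,
                                  adult_gfr = 121, fetal_weight = 3.7) {
  if (any(c(cl_renal_adult, fetal_gfr, adult_gfr, fetal_weight) <= 0))
    stop_domain("all inputs must be positive")
  cl_renal_adult * fetal_gfr / (fetal_weight * adult_gfr)
}

#' Whole-liver unbound intrinsic clearance scaled up from per-pmol values
#'
#' Sums, over isoforms, `CLint * abundance * MPPGL * liver weight`, each
#' multiplied by the gestational activity multiplier and any phenotype
#' multiplier, and converts uL/min to L/h. Additive and linear in every
#' component.
#'
#' @param compound a [compound_record()]
#' @param physiology a [build_physiology()] snapshot
#' @param phenotype_multipliers named multipliers on the per-isoform CLint
#'   (defaults to 1 for every isoform)
#' @return unbound intrinsic clearance in L/h
#' @export
whole_liver_intrinsic_clearance <- function(compound, physiology,
                                            phenotype_multipliers = NULL) {
  iso <- names(compound$clint_by_isoform)
  mult <- stats::setNames(rep(1, length(iso)), iso)
  if (!is.null(phenotype_multipliers)) {
    if (any(phenotype_multipliers < 0))
      stop_domain("phenotype multipliers must be non-negative")
    mult[names(phenotype_multipliers)] <- phenotype_multipliers
  }
  act <- physiology$enzyme_activity_multiplier[iso]
  ab <- physiology$enzyme_abundance[iso]
  per_mg <- compound$clint_by_isoform * ab * act * mult[iso]  # uL/min/mg
  ul_min <- sum(per_mg) * physiology$mppgl * physiology$liver_weight
  ul_min_to_l_h(ul_min)
}
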