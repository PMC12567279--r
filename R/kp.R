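# Tissue-to-plasma partitioning by the Rodgers-Rowland mechanistic equations
# for moderate-to-strong monoprotic bases (pKa > 7): distribution into tissue
# water with pH-driven ionization, partitioning into neutral lipid and
# neutral phospholipid, and electrostatic association of the ionized species
# with tissue acidic phospholipids. The acidic-phospholipid association
# constant is back-calculated from blood-cell binding (via the measured
# blood-to-plasma ratio and hematocrit), so no drug-specific tissue binding
# input is needed.

PH_PLASMA <- 7.4
PH_IW <- 7.0
PH_BC <- 7.22

load_tissue_composition <- function(path = escipbpk_fixture("tissue_composition.csv")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Blood-cell-to-plasma-water partition coefficient of unbound drug
#' @param blood_to_plasma measured B/P ratio
#' @param hematocrit fraction
#' @param fu_plasma fraction unbound in plasma
#' @return Kpu for blood cells
#' @keywords internal
kpu_blood_cells <- function(blood_to_plasma, hematocrit, fu_plasma) {
  (blood_to_plasma - (1 - hematocrit)) / (hematocrit * fu_plasma)
}

# Association constant of the ionized base with acidic phospholipids,
# back-calculated from blood-cell partitioning.
ka_acidic_phospholipid <- function(compound, hematocrit, composition) {
  bc <- composition[composition$tissue == "blood_cells", ]
  p <- 10^compound$logp
  ion_p <- 1 + 10^(compound$pka - PH_PLASMA)
  ion_bc <- 10^(compound$pka - PH_BC)
  kpu_bc <- kpu_blood_cells(compound$blood_to_plasma, hematocrit,
                            compound$fu_plasma)
  water_term <- (1 + ion_bc) / ion_p * bc$f_iw
  lipid_term <- (p * bc$f_nl + (0.3 * p + 0.7) * bc$f_np) / ion_p
  (kpu_bc - water_term - lipid_term) * ion_p / (bc$ap_mg_g * ion_bc)
}

#' Predict tissue-to-plasma partition coefficients (Rodgers-Rowland)
#'
#' Mechanistic Kp prediction for a moderate-to-strong monoprotic base, with
#' the acidic-phospholipid association constant derived from blood-cell
#' binding. Each predicted Kp is multiplied by the compound's `kp_scalar`.
#'
#' @param compound a [compound_record()]; must be a base with pKa > 7
#' @param composition tissue composition table (defaults to the packaged
#'   fixture); must cover all model tissues
#' @param hematocrit blood hematocrit fraction
#' @return named vector of total tissue-to-total plasma Kp values
#' @export
predict_kp <- function(compound, composition = load_tissue_composition(),
                       hematocrit = 0.40) {
  if (compound$pka <= 7)
    stop_domain("Kp prediction implemented for moderate-to-strong bases ",
                "(pKa > 7) only")
  missing <- setdiff(tissue_names(), composition$tissue)
  if (length(missing))
    stop_domain("composition table lacks tissue(s): ",
                paste(missing, collapse = ", "))
  p <- 10^compound$logp
  ion_p <- 1 + 10^(compound$pka - PH_PLASMA)
  ion_iw <- 10^(compound$pka - PH_IW)
  ka_ap <- ka_acidic_phospholipid(compound, hematocrit, composition)

  rows <- composition[match(tissue_names(), composition$tissue), ]
  kpu <- rows$f_ew +
    (1 + ion_iw) / ion_p * rows$f_iw +
    ka_ap * rows$ap_mg_g * ion_iw / ion_p +
    (p * rows$f_nl + (0.3 * p + 0.7) * rows$f_np) / ion_p
  kp <- kpu * compound$fu_plasma * compound$kp_scalar
  stats::setNames(kp, rows$tissue)
}

#' Steady-state volume of distribution from tissue Kp values
#'
#' `Vss = (sum_t Kp_t * V_t + V_plasma + V_bc * Kp_bc) / body weight`, in
#' L/kg, where the erythrocyte term uses the cell-to-plasma partition
#' implied by the measured blood-to-plasma ratio and the hematocrit.
#'
#' @param kps named Kp vector covering all tissues in the snapshot
#' @param physiology a [build_physiology()] snapshot
#' @param compound a [compound_record()]; when supplied, blood-cell
#'   partitioning is included in the summation
#' @return Vss in L/kg body weight
#' @export
predict_vss <- function(kps, physiology, compound = NULL) {
  tn <- names(physiology$tissue_volumes)
  if (!all(tn %in% names(kps)))
    stop_domain("Kp vector lacks tissue(s): ",
                paste(setdiff(tn, names(kps)), collapse = ", "))
  v_bc_term <- 0
  if (!is.null(compound)) {
    ht <- physiology$hematocrit
    v_bc <- physiology$plasma_volume * ht / (1 - ht)
    kp_bc <- kpu_blood_cells(compound$blood_to_plasma, ht,
                             compound$fu_plasma) * compound$fu_plasma
    v_bc_term <- v_bc * kp_bc
  }
  (sum(kps[tn] * physiology$tissue_volumes[tn]) + physiology$plasma_volume +
     v_bc_term) / physiology$body_weight
}
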