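#!/usr/bin/env Rscript
# CYP2C19 phenotype stratification: per-phenotype population exposure at
# gestational week 35, and the calibration surface behind the packaged
# activity multipliers — the deterministic AUC fold over NM as a function of
# the CYP2C19 multiplier, which shows the structural cap imposed by the
# CYP2D6, CYP3A4 and renal pathways.

library(escipbpk)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out <- "results/04_phenotypes"
df <- run_pipeline(list(seed = seed), "phenotypes", out)
cat("Population exposure by CYP2C19 phenotype (gw 35, 10 mg):\n")
print(cbind(df[1:3], round(df[4:6], 2)))

# calibration surface: deterministic exposure fold vs activity multiplier
drug <- load_compound()
phys <- build_physiology(0)
auc_at <- function(mult) {
  prof <- simulate_individual(drug, phys, dose_regimen(10), fast_settings(),
                              phenotype_multipliers = c(CYP2C19 = mult))
  compute_pk_metrics(prof)$auc
}
mults <- c(0, 0.05, 0.2, 0.45, 0.6, 0.75, 1, 1.3, 1.5, 2)
folds <- vapply(mults, auc_at, numeric(1)) / auc_at(1)
calib <- data.frame(cyp2c19_multiplier = mults,
                    auc_fold_vs_nm = round(folds, 3))
dir.create(out, showWarnings = FALSE, recursive = TRUE)
write.csv(calib, file.path(out, "multiplier_calibration.csv"),
          row.names = FALSE)
cat("\nAUC fold over NM vs CYP2C19 activity multiplier (gw 0):\n")
print(calib)
cat(sprintf("\nEven at zero CYP2C19 activity the fold caps at %.2f because\n",
            max(folds)))
cat("CYP2D6, CYP3A4 and renal clearance persist; the packaged multipliers\n")
cat("(UM 1.3 / NM 1.0 / IM 0.75 / PM 0.6) were chosen against the simulated\n")
cat("IM/NM exposure ratio and trough-concentration ranges instead.\n")
cat("Tables written under", out, "\n")
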