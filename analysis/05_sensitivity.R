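#!/usr/bin/env Rscript
# Morris elementary-effects screening of the nine drug-specific parameters
# in the nonpregnant single-dose model (20 mg): mu* rankings for Cmax and
# AUC(0-inf).

library(escipbpk)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out <- "results/05_sensitivity"
res <- run_pipeline(list(seed = seed), "sensitivity", out)
print(res)
cat("\nCmax is absorption/distribution-dominated (Kp scalar, f_a, k_a);\n")
cat("AUC is availability/clearance-dominated (f_a, then the CYP2C19 and\n")
cat("CYP2D6 intrinsic clearances).\n")
cat("Tables written under", out, "\n")
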