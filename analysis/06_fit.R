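#!/usr/bin/env Rscript
# Parameter estimation closure: regenerate synthetic single-dose
# observations from the packaged truth and re-estimate k_a, Q_gut and the
# Kp scalar by weighted least squares with multi-start Nelder-Mead.

library(escipbpk)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out <- "results/06_fit"
fit <- run_pipeline(list(seed = seed, fit = list(n_restarts = 40,
                                                 maxit = 400)),
                    "fit", out)
print(fit)
truth <- c(k_absorption = 0.19, q_gut = 5.69, kp_scalar = 0.92)
cat("\nRelative error vs truth (%):\n")
print(round(100 * abs(fit$estimates - truth) / truth, 2))
cat("\nk_a and the Kp scalar are well identified; Q_gut is not, because\n")
cat("gut availability is ~0.99 so the data carry almost no information\n")
cat("about it (see the methods vignette).\n")
cat("Tables written under", out, "\n")
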