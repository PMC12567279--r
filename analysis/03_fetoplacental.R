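#!/usr/bin/env Rscript
# Fetoplacental unit at term: 10 mg once daily for 10 days at gestational
# week 40; reports the cord-to-maternal plasma concentration ratio
# (time-averaged over the final dosing interval, trough ratio alongside)
# and demonstrates its exact dose independence.

library(escipbpk)
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1

out <- "results/03_fetoplacental"
df <- run_pipeline(list(seed = seed), "fetal", out)
cat("Cord-to-maternal concentration ratio at term (10 mg):\n")
print(round(df, 3))

df20 <- run_pipeline(list(dose = 20, seed = seed), "fetal",
                     file.path(out, "dose20"))
cat(sprintf("\nAt 20 mg the ratio is %.6f (identical: the model is linear).\n",
            df20$cord_maternal_ratio))
cat("Tables written under", out, "\n")
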