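# Shared fixtures, built once per test run.

esc <- load_compound()
phys_gw0 <- build_physiology(0)
phys_gw35 <- build_physiology(35)
phys_gw40 <- build_physiology(40)

# reference settings for golden single-profile checks
ref_settings <- sim_settings(rtol = 1e-8, atol = 1e-10, grid = 0.1)

# a degenerate phenotype set: everyone NM with unit activity
nm_only <- list(phenotype_spec("NM", 1, 1))

# synthetic profile helper for metric/classification unit tests
flat_profile <- function(value, interval = 24, t_end = 48) {
  structure(data.frame(time = seq(0, t_end, by = 0.5),
                       maternal_plasma = value),
            class = c("conc_profile", "data.frame"), interval = interval)
}
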