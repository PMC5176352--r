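#!/usr/bin/env Rscript
# Generate every raw data modality the downstream analyses consume, from
# the published parameter values: the five-drug BzATP dose-response panel
# under the non-competitive truth (plus a competitive JNJ panel for
# contrast), dye-uptake time courses, anisotropy titrations, and
# patch-clamp accessibility cohorts. All outputs land under results/sim/.

library(p2x7pharm)
seed <- 1L
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

drugs <- names(p2x7_published_kb("noncompetitive"))

# five-drug panel, non-competitive truth, sigma = 0.02, n = 5
panel <- do.call(rbind, lapply(seq_along(drugs), function(i) {
  truth <- p2x7_published_params("noncompetitive", drugs[i])
  simulate_dose_response(simulation_design(
    truth, antagonist_grid = c(0, truth$KB * 10^seq(-0.7, 0.9,
                                                    length.out = 4)),
    noise_sd = 0.02, seed = seed + i, antagonist_id = drugs[i]))
}))
write_table_csv(panel, "results/sim/dose_response_noncompetitive.csv")

# competitive JNJ panel for the model-selection contrast
truth_c <- p2x7_published_params("competitive", "JNJ47965567")
panel_c <- simulate_dose_response(simulation_design(
  truth_c, antagonist_grid = c(0, 0.3, 1, 3, 10) * 1e-9,
  noise_sd = 0.02, seed = seed + 20, antagonist_id = "JNJ47965567"))
write_table_csv(panel_c, "results/sim/dose_response_competitive.csv")

# uptake time courses: rates proportional to the model response at 1 mM
# BzATP across three JNJ concentrations
truth <- p2x7_published_params("noncompetitive", "JNJ47965567")
conds <- expand.grid(B = c(0, 0.1, 1) * 1e-6, replicate = 1:5)
ts <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
  r <- 2 * mechanism_response(1e-3, conds$B[i], truth)  # AU/s scale
  simulate_uptake_timeseries(r, duration_s = 900, noise_sd_au = 2,
                             agonist_conc_M = 1e-3,
                             antagonist_id = "JNJ47965567",
                             antagonist_conc_M = conds$B[i],
                             replicate = conds$replicate[i],
                             seed = seed + 100 + i)
}))
write_table_csv(ts, "results/sim/uptake_timeseries.csv")

# anisotropy: protein titration, drug-pretreated titration (allosteric
# drugs leave binding untouched), and ATP competition
pg <- 10^seq(-7, -3, length.out = 10)
write_table_csv(anisotropy_records(simulate_anisotropy_titration(
  pg, seed = seed + 200)), "results/sim/anisotropy_titration.csv")
write_table_csv(anisotropy_records(simulate_anisotropy_titration(
  pg, drug_effect = "none", drug_id = "JNJ47965567",
  drug_conc_M = 100e-6, seed = seed + 201)),
  "results/sim/anisotropy_titration_drug.csv")
write_table_csv(anisotropy_records(simulate_competition_titration(
  10^seq(-5, -2, length.out = 8), seed = seed + 202)),
  "results/sim/anisotropy_competition.csv")

# accessibility cohorts: closed-state probing reduces currents for the
# pocket-lining cysteines, open-state probing does not
eff_closed <- c(wildtype = 1.0, F103C = 0.35, K110C = 0.4, T308C = 0.45,
                I310C = 0.3, Y295C = 0.2)
eff_open <- c(wildtype = 1.0, F103C = 0.9, K110C = 0.95, T308C = 0.9,
              I310C = 0.92, Y295C = 0.6)
write_table_csv(simulate_patch_cohort(eff_closed, state = "closed",
                                      rundown = 0.8, n_cells = 6,
                                      seed = seed + 300),
                "results/sim/patch_closed.csv")
write_table_csv(simulate_patch_cohort(eff_open, state = "open",
                                      rundown = 0.8, n_cells = 6,
                                      seed = seed + 301),
                "results/sim/patch_open.csv")

cat("simulated inputs written under results/sim/\n")
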