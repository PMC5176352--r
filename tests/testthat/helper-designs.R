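# Shared fixtures: published truth parameter sets and the simulation
# designs used across the suite. Everything is generated in code; no
# stored data.

jnj_nc <- function() p2x7_published_params("noncompetitive", "JNJ47965567")
jnj_c <- function() p2x7_published_params("competitive", "JNJ47965567")

# antagonist concentrations used for KB estimation designs
kb_grid_nc <- function() c(0, 0.03, 0.1, 0.3, 1) * 1e-6   # molar
kb_grid_c <- function() c(0, 0.3, 1, 3, 10) * 1e-9        # molar

# Schild design: three decades around the knee of the dose-ratio curve
schild_grid_nc <- function() 10^seq(-8, -5, length.out = 12)

# competitive-truth Schild design: dose ratios kept small enough that the
# shifted EC50s stay inside the measured agonist range
schild_grid_c <- function(KB) KB * 10^seq(-1, 1.25, length.out = 6)

sim_nc <- function(seed, noise_sd = 0.02, antagonist_grid = kb_grid_nc())
  simulate_dose_response(simulation_design(
    jnj_nc(), antagonist_grid = antagonist_grid, noise_sd = noise_sd,
    seed = seed, antagonist_id = "JNJ47965567"))

sim_c <- function(seed, noise_sd = 0.02, antagonist_grid = kb_grid_c())
  simulate_dose_response(simulation_design(
    jnj_c(), antagonist_grid = antagonist_grid, noise_sd = noise_sd,
    seed = seed, antagonist_id = "JNJ47965567"))

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / abs(expected), tol)
}
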