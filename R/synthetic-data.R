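# Seeded generators for every raw data modality the pipeline consumes.
# Each generator is bit-reproducible for a fixed seed (seeding is local,
# via withr::with_seed, so generators never disturb the caller's RNG
# state) and attaches its design as attributes of the output.

#' Dose-response simulation design
#'
#' Bundles the truth (a [mechanism_params()] or [hill_params()] object),
#' the concentration grids, replicate count and noise level of a simulated
#' dose-response experiment. Defaults emulate the study conditions: five
#' replicates, additive Gaussian noise of 0.02 on normalized responses, an
#' 8-point log-spaced agonist grid from 0.1 uM to 1 mM, and antagonist
#' concentrations spanning three orders of magnitude around KB.
#'
#' @param truth A [mechanism_params()] or [hill_params()] object.
#' @param agonist_grid Agonist concentrations, molar, sorted ascending.
#' @param antagonist_grid Antagonist concentrations, molar (may include 0);
#'   defaults to 0 plus four log-spaced points spanning three decades
#'   around KB for a mechanism truth, or just 0 for a Hill truth.
#' @param replicates Replicates per condition (default 5).
#' @param noise_sd Additive Gaussian SD on the response (default 0.02).
#' @param seed Integer seed.
#' @param antagonist_id Drug label written into the table.
#' @param fixed_agonist_M Agonist concentration used when the truth is an
#'   inhibition-direction Hill curve (response vs antagonist at fixed
#'   agonist); default 1 mM.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(truth,
                              agonist_grid = 10^seq(-7, -3,
                                                    length.out = 8),
                              antagonist_grid = NULL,
                              replicates = 5L, noise_sd = 0.02,
                              seed = 1L, antagonist_id = "drug",
                              fixed_agonist_M = 1e-3) {
  stopifnot(inherits(truth, "mechanism_params") ||
              inherits(truth, "hill_params"),
            is.numeric(agonist_grid), length(agonist_grid) >= 1,
            !is.unsorted(agonist_grid), all(agonist_grid >= 0),
            replicates >= 1, noise_sd >= 0)
  if (is.null(antagonist_grid)) {
    antagonist_grid <-
      if (inherits(truth, "mechanism_params"))
        c(0, truth$KB * 10^seq(-1.5, 1.5, length.out = 4))
      else 0
  }
  stopifnot(!is.unsorted(antagonist_grid), all(antagonist_grid >= 0))
  structure(list(truth = truth, agonist_grid = agonist_grid,
                 antagonist_grid = antagonist_grid,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 antagonist_id = antagonist_id,
                 fixed_agonist_M = fixed_agonist_M),
            class = "simulation_design")
}

#' Simulate a dose-response table
#'
#' Draws `response = model mean + N(0, noise_sd)` independently per
#' replicate on the design's grids. Negative draws are kept (not clipped);
#' the fitting routines must tolerate them, as a plate reader's normalized
#' baseline can dip below zero. With `noise_sd = 0` the table reproduces
#' the model exactly, which the self-consistency tests exploit.
#'
#' @param design A [simulation_design()].
#' @return Data frame in the `dose_response.csv` schema:
#'   `agonist_conc_M`, `antagonist_id`, `antagonist_conc_M`, `response`,
#'   `replicate`, with the design attached as attribute `design`.
#' @export
simulate_dose_response <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  tr <- design$truth
  if (inherits(tr, "mechanism_params")) {
    grid <- expand.grid(agonist_conc_M = design$agonist_grid,
                        antagonist_conc_M = design$antagonist_grid,
                        replicate = seq_len(design$replicates))
    mu <- mechanism_response(grid$agonist_conc_M, grid$antagonist_conc_M,
                             tr)
  } else if (tr$direction == "activation") {
    grid <- expand.grid(agonist_conc_M = design$agonist_grid,
                        antagonist_conc_M = 0,
                        replicate = seq_len(design$replicates))
    mu <- hill_response(grid$agonist_conc_M, tr)
  } else {
    bnz <- design$antagonist_grid
    grid <- expand.grid(agonist_conc_M = design$fixed_agonist_M,
                        antagonist_conc_M = bnz,
                        replicate = seq_len(design$replicates))
    mu <- hill_response(grid$antagonist_conc_M, tr)
  }
  noise <- withr::with_seed(design$seed,
                            stats::rnorm(length(mu), 0, design$noise_sd))
  out <- data.frame(agonist_conc_M = grid$agonist_conc_M,
                    antagonist_id = design$antagonist_id,
                    antagonist_conc_M = grid$antagonist_conc_M,
                    response = mu + noise,
                    replicate = grid$replicate)
  attr(out, "design") <- design
  out
}

#' Simulate a dye-uptake fluorescence time course
#'
#' Linear fluorescence rise at the given uptake rate, rolling over into an
#' exponential flattening after `decline_after_s` (about 10 min with the
#' default, when uptake activity starts to decline), sampled at fixed
#' intervals with additive Gaussian noise.
#'
#' @param rate_au_per_s True initial uptake rate, AU/s.
#' @param duration_s Total recording length.
#' @param interval_s Sampling interval (default 60 s).
#' @param decline_after_s Onset of the decline (default 600 s).
#' @param decline_tau_s Time constant of the flattening (default 180 s).
#' @param noise_sd_au Additive noise SD in AU.
#' @param baseline_au Fluorescence at t = 0.
#' @param agonist_conc_M,antagonist_id,antagonist_conc_M,replicate,plate_id
#'   Metadata columns copied into the output.
#' @param seed Integer seed (ignored when `noise_sd_au = 0`).
#' @return Data frame in the `timeseries.csv` schema, design attached as
#'   attributes.
#' @export
simulate_uptake_timeseries <- function(rate_au_per_s, duration_s = 900,
                                       interval_s = 60,
                                       decline_after_s = 600,
                                       decline_tau_s = 180,
                                       noise_sd_au = 0,
                                       baseline_au = 100,
                                       agonist_conc_M = 1e-3,
                                       antagonist_id = NA_character_,
                                       antagonist_conc_M = 0,
                                       replicate = 1L, plate_id = "plate1",
                                       seed = 1L) {
  stopifnot(duration_s > interval_s, interval_s > 0, noise_sd_au >= 0)
  t <- seq(0, duration_s, by = interval_s)
  ramp <- ifelse(t <= decline_after_s, t,
                 decline_after_s + decline_tau_s *
                   (1 - exp(-(t - decline_after_s) / decline_tau_s)))
  mu <- baseline_au + rate_au_per_s * ramp
  noise <- if (noise_sd_au > 0)
    withr::with_seed(seed, stats::rnorm(length(t), 0, noise_sd_au))
  else 0
  out <- data.frame(time_s = t, fluorescence_au = mu + noise,
                    agonist_conc_M = agonist_conc_M,
                    antagonist_id = antagonist_id,
                    antagonist_conc_M = antagonist_conc_M,
                    replicate = replicate, plate_id = plate_id)
  attr(out, "rate_au_per_s") <- rate_au_per_s
  attr(out, "decline_after_s") <- decline_after_s
  out
}

# Build an intensity quadruple whose anisotropy is exactly r_target given
# instrument factor G: with total S = IVV + 2*G*IVH,
# IVV = S(1+2r)/3 and G*IVH = S(1-r)/3.
.quadruple_for_r <- function(r_target, G, total_intensity) {
  IVV <- total_intensity * (1 + 2 * r_target) / 3
  IVH <- total_intensity * (1 - r_target) / (3 * G)
  IHH <- total_intensity / 10
  data.frame(IVV = IVV, IVH = IVH, IHV = G * IHH, IHH = IHH)
}

#' Simulate an anisotropy-versus-protein titration
#'
#' Generates polarized intensity quadruples whose anisotropy follows a
#' Hill binding curve r(P) between the free-ligand and bound-state
#' anisotropies, plus Gaussian noise on r. `drug_effect = "none"` leaves
#' the curve untouched (the outcome observed for allosteric antagonists,
#' which do not contest the ATP site); `"block_binding"` collapses it to
#' the free-ligand value (the counterfactual competitive outcome).
#'
#' @param protein_grid Receptor concentrations, molar.
#' @param midpoint_M Apparent dissociation constant of the labelled
#'   ligand, molar.
#' @param slope Hill slope of the binding curve (default 0.90).
#' @param r_free,r_bound Free and bound anisotropies (default 0.10, 0.30).
#' @param noise_sd Gaussian SD added to r (default 0.005).
#' @param replicates Replicates per concentration (default 5).
#' @param drug_effect `"none"` or `"block_binding"`.
#' @param drug_id,drug_conc_M Drug metadata columns.
#' @param G True instrument G factor encoded in the intensities.
#' @param total_intensity Total intensity scale of the quadruples.
#' @param seed Integer seed.
#' @return Data frame in the `polarization.csv` schema (`IVV`, `IVH`,
#'   `IHV`, `IHH`, `protein_conc_M`, `atp_conc_M`, `drug_id`,
#'   `drug_conc_M`, `replicate`).
#' @export
simulate_anisotropy_titration <- function(protein_grid,
                                          midpoint_M = 10e-6,
                                          slope = 0.90,
                                          r_free = 0.10, r_bound = 0.30,
                                          noise_sd = 0.005,
                                          replicates = 5L,
                                          drug_effect = c("none",
                                                          "block_binding"),
                                          drug_id = NA_character_,
                                          drug_conc_M = 0,
                                          G = 0.8,
                                          total_intensity = 1e4,
                                          seed = 1L) {
  drug_effect <- match.arg(drug_effect)
  stopifnot(r_bound >= r_free, noise_sd >= 0, all(protein_grid >= 0))
  hp <- hill_params(midpoint_M, slope, r_bound, r_free, "activation")
  grid <- expand.grid(protein_conc_M = protein_grid,
                      replicate = seq_len(replicates))
  r_mu <- if (drug_effect == "block_binding")
    rep(r_free, nrow(grid))
  else hill_response(grid$protein_conc_M, hp)
  noise <- withr::with_seed(seed,
                            stats::rnorm(nrow(grid), 0, noise_sd))
  q <- .quadruple_for_r(r_mu + noise, G, total_intensity)
  cbind(q, data.frame(protein_conc_M = grid$protein_conc_M,
                      atp_conc_M = 0, drug_id = drug_id,
                      drug_conc_M = drug_conc_M,
                      replicate = grid$replicate))
}

#' Simulate an ATP-competition anisotropy titration
#'
#' Same intensity construction as [simulate_anisotropy_titration()], but
#' anisotropy falls along a decreasing Hill curve as unlabelled ATP
#' displaces the fluorescent analogue, from the bound value down to the
#' free-ligand value.
#'
#' @param atp_grid Unlabelled ATP concentrations, molar (the study design
#'   spans 10 uM to 10 mM).
#' @param ic50_M Half-displacement ATP concentration, molar.
#' @param slope Hill slope of the displacement (default 1).
#' @param r_free,r_bound Anisotropy asymptotes.
#' @param protein_conc_M Receptor concentration metadata (default 100 uM).
#' @inheritParams simulate_anisotropy_titration
#' @return Data frame in the `polarization.csv` schema.
#' @export
simulate_competition_titration <- function(atp_grid, ic50_M = 3e-4,
                                           slope = 1,
                                           r_free = 0.10, r_bound = 0.30,
                                           noise_sd = 0.005,
                                           replicates = 5L,
                                           protein_conc_M = 100e-6,
                                           drug_id = NA_character_,
                                           drug_conc_M = 0,
                                           G = 0.8,
                                           total_intensity = 1e4,
                                           seed = 1L) {
  stopifnot(r_bound >= r_free, noise_sd >= 0, all(atp_grid >= 0))
  hp <- hill_params(ic50_M, slope, r_bound, r_free, "inhibition")
  grid <- expand.grid(atp_conc_M = atp_grid,
                      replicate = seq_len(replicates))
  r_mu <- hill_response(grid$atp_conc_M, hp)
  noise <- withr::with_seed(seed,
                            stats::rnorm(nrow(grid), 0, noise_sd))
  q <- .quadruple_for_r(r_mu + noise, G, total_intensity)
  cbind(q, data.frame(protein_conc_M = protein_conc_M,
                      atp_conc_M = grid$atp_conc_M, drug_id = drug_id,
                      drug_conc_M = drug_conc_M,
                      replicate = grid$replicate))
}

#' Simulate a patch-clamp accessibility cohort
#'
#' Lognormal baseline current amplitudes per cell; the after-reagent
#' amplitude is the baseline times the construct's true post/pre ratio,
#' times the state's rundown factor, times multiplicative lognormal noise.
#' Control cells (no reagent) experience rundown and noise only, which is
#' what the rundown correction divides out.
#'
#' @param effects Named numeric vector mapping construct to its true
#'   post/pre activity ratio under the reagent; ratios must lie in
#'   (0, 1.5].
#' @param state State during reagent application for the treated cells
#'   (`"closed"` or `"open"`).
#' @param rundown Multiplicative rundown factor between the two
#'   measurements (applies to treated and control cells alike).
#' @param n_cells Cells per construct per arm.
#' @param noise_sd SD of the lognormal measurement noise (on log scale).
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   baseline current in nA.
#' @param controls Also emit matching `control_no_MTS` cells (default
#'   TRUE).
#' @param dtt_pretreated Metadata flag copied to all cells.
#' @param seed Integer seed.
#' @return Data frame in the `patch.csv` schema: `cell_id`, `construct`,
#'   `state_during_MTS`, `I_before_nA`, `I_after_nA`, `dtt_pretreated`.
#' @export
simulate_patch_cohort <- function(effects, state = "closed",
                                  rundown = 0.8, n_cells = 6L,
                                  noise_sd = 0.05,
                                  baseline_meanlog = 0,
                                  baseline_sdlog = 0.4,
                                  controls = TRUE,
                                  dtt_pretreated = FALSE, seed = 1L) {
  stopifnot(is.numeric(effects), !is.null(names(effects)),
            all(effects > 0), all(effects <= 1.5),
            rundown > 0, n_cells >= 1, noise_sd >= 0)
  arms <- data.frame(construct = rep(names(effects), each = n_cells),
                     state_during_MTS = state,
                     effect = rep(unname(effects), each = n_cells))
  if (controls) {
    arms <- rbind(arms,
                  data.frame(construct = rep(names(effects),
                                             each = n_cells),
                             state_during_MTS = "control_no_MTS",
                             effect = 1))
  }
  n <- nrow(arms)
  draws <- withr::with_seed(seed, {
    list(base = stats::rlnorm(n, baseline_meanlog, baseline_sdlog),
         eps = stats::rlnorm(n, 0, noise_sd))
  })
  data.frame(cell_id = sprintf("cell%03d", seq_len(n)),
             construct = arms$construct,
             state_during_MTS = arms$state_during_MTS,
             I_before_nA = draws$base,
             I_after_nA = draws$base * arms$effect * rundown * draws$eps,
             dtt_pretreated = dtt_pretreated)
}
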