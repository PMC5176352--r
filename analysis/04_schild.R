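#!/usr/bin/env Rscript
# Schild analysis of simulated JNJ47965567 dose-response data under both
# truths: competitive data give a straight unit-slope line whose
# x-intercept recovers -log10 KB; non-competitive data give dose ratios
# that plateau at high antagonist, the diagnostic non-linearity.

library(p2x7pharm)
seed <- 1L
dir.create("results", showWarnings = FALSE)

# competitive truth: dose ratios kept small enough that shifted EC50s
# stay inside the measured agonist range
p_c <- p2x7_published_params("competitive", "JNJ47965567")
d_c <- simulate_dose_response(simulation_design(
  p_c, antagonist_grid = c(0, p_c$KB * 10^seq(-1, 1.25, length.out = 6)),
  noise_sd = 0.02, seed = seed, antagonist_id = "JNJ47965567"))
sa_c <- suppressWarnings(schild_analysis(d_c))
write_table_csv(sa_c$points, "results/schild_points_competitive.csv")
cat(sprintf("competitive truth: slope %.3f, pA2 %.2f (-log10 KB = %.2f), curvature p = %s\n",
            sa_c$result$slope, sa_c$result$pA2, -log10(p_c$KB),
            format(sa_c$result$curvature_p, digits = 3)))

# non-competitive truth over three decades of antagonist
p_n <- p2x7_published_params("noncompetitive", "JNJ47965567")
d_n <- simulate_dose_response(simulation_design(
  p_n, antagonist_grid = c(0, 10^seq(-8, -5, length.out = 12)),
  noise_sd = 0.02, seed = seed, antagonist_id = "JNJ47965567"))
sa_n <- suppressWarnings(schild_analysis(d_n))
write_table_csv(sa_n$points, "results/schild_points_noncompetitive.csv")
cat(sprintf("non-competitive truth: slope %.3f, curvature p = %s, %d usable points\n",
            sa_n$result$slope, format(sa_n$result$curvature_p, digits = 3),
            sa_n$result$n_points_used))
cat("dose ratios r by antagonist concentration (non-competitive):\n")
print(sa_n$points, digits = 3)

res <- data.frame(
  truth = c("competitive", "noncompetitive"),
  slope = c(sa_c$result$slope, sa_n$result$slope),
  pA2 = c(sa_c$result$pA2, sa_n$result$pA2),
  curvature_p = c(sa_c$result$curvature_p, sa_n$result$curvature_p),
  n_points = c(sa_c$result$n_points_used, sa_n$result$n_points_used))
write_table_csv(res, "results/schild_results.csv")
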