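#!/usr/bin/env Rscript
# Reduce the simulated dye-uptake time courses to normalized initial
# rates: truncate each recording at the decline onset, take the OLS slope
# over the first five samples, and normalize to the plate's control.

library(p2x7pharm)

ts <- read_timeseries("results/sim/uptake_timeseries.csv")
rates <- rates_from_timeseries(ts, window_points = 5L, cutoff_s = 600)
write_table_csv(rates, "results/rates.csv")

ctrl <- rates$antagonist_conc_M == 0
cat(sprintf("reduced %d recordings (window = %d samples, cutoff = %d s)\n",
            nrow(rates), attr(rates, "window_points"),
            attr(rates, "cutoff_s")))
cat(sprintf("control mean response = %.3f (should be 1 by construction)\n",
            mean(rates$response[ctrl])))
for (b in sort(unique(rates$antagonist_conc_M))) {
  sel <- rates$antagonist_conc_M == b
  cat(sprintf("  B = %8.3g M: mean response %.3f (n = %d)\n",
              b, mean(rates$response[sel]), sum(sel)))
}
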