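#!/usr/bin/env Rscript
# Fluorescence-anisotropy binding analysis: the labelled-ATP titration
# against receptor concentration, the same titration after antagonist
# pretreatment (allosteric drugs leave ATP-site binding untouched), and
# displacement by unlabelled ATP.

library(p2x7pharm)

tit <- read_polarization("results/sim/anisotropy_titration.csv")
tit <- anisotropy_records(tit)
f_bind <- fit_binding_titration(tit$protein_conc_M, tit$r)
cat(sprintf("binding titration: Kd(app) %.3g uM, slope %.3f, r %.3f -> %.3f\n",
            f_bind$params$midpoint * 1e6, f_bind$params$slope,
            f_bind$params$bottom, f_bind$params$top))

drug <- anisotropy_records(
  read_polarization("results/sim/anisotropy_titration_drug.csv"))
f_drug <- fit_binding_titration(drug$protein_conc_M, drug$r)
cat(sprintf("after drug pretreatment: Kd(app) %.3g uM, slope %.3f\n",
            f_drug$params$midpoint * 1e6, f_drug$params$slope))
cat(sprintf("anisotropy at 100 uM protein: %.3f (no drug) vs %.3f (drug)\n",
            mean(tit$r[tit$protein_conc_M == max(tit$protein_conc_M)]),
            mean(drug$r[drug$protein_conc_M == max(drug$protein_conc_M)])))

comp <- anisotropy_records(
  read_polarization("results/sim/anisotropy_competition.csv"))
f_comp <- fit_competition(comp$atp_conc_M, comp$r)
cat(sprintf("ATP competition: IC50 %.3g uM, monotone decrease: %s\n",
            f_comp$params$midpoint * 1e6,
            f_comp$flags$monotone_decreasing))

out <- data.frame(
  experiment = c("binding", "binding_drug_pretreated", "atp_competition"),
  midpoint_M = c(f_bind$params$midpoint, f_drug$params$midpoint,
                 f_comp$params$midpoint),
  slope = c(f_bind$params$slope, f_drug$params$slope,
            f_comp$params$slope),
  r_bottom = c(f_bind$params$bottom, f_drug$params$bottom,
               f_comp$params$bottom),
  r_top = c(f_bind$params$top, f_drug$params$top, f_comp$params$top))
write_table_csv(out, "results/anisotropy_fits.csv")
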