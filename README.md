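# p2x7pharm

Quantitative pharmacology for deciding **how** P2X7 receptor antagonists
inhibit: competitively at the ATP site, or non-competitively at an
allosteric site.

The P2X7 receptor is a trimeric ATP-gated cation channel and a target
for chronic pain and inflammation. Five structurally unrelated
antagonists (A740003, A804598, AZ10606120, GW791343, JNJ47965567) block
it potently, and the mode of that block is decided here from
dose-response behaviour. The package is aimed at receptor
pharmacologists working with plate-based dye-uptake assays, binding
assays, and patch-clamp data.

## The models at the core

Responses are normalized initial rates of YO-PRO-1 dye uptake evoked by
BzATP at concentration *A* in the presence of antagonist at *B*.
Competitive antagonism (surmountable; the maximum is untouched):

    R = (A/K_A) / ((A/K_A)(1 + τ) + B/K_B + 1)

Non-competitive (allosteric) antagonism (insurmountable; the maximum
falls with *B*):

    R = A^n τ^n E_max / (A^n τ^n + (A(1 + αB/K_B) + K_A·B/K_B + K_A)^n)

with K_A, K_B the agonist/antagonist dissociation constants, τ the
operational efficacy, n the Hill coefficient, and α the
agonist-antagonist binding cooperativity (fixed at 1). Around these two
equations the package provides:

- reduction of uptake time courses to normalized initial rates
  (`rates_from_timeseries()`),
- two-stage nonlinear least squares — control curve first, then K_B
  (`fit_control()`, `fit_KB()`, `fit_two_stage()`),
- model selection by extra-sum-of-squares F-test with R², SS and a
  verdict per drug (`compare_mechanisms()`, `mechanism_report()`),
- Schild dose-ratio regression with a curvature diagnostic
  (`schild_analysis()`),
- fluorescence-anisotropy binding and ATP-competition fits
  (`anisotropy()`, `fit_binding_titration()`, `fit_competition()`),
- rundown-corrected cysteine-accessibility statistics with Monte-Carlo
  Dunnett many-to-one comparisons (`access_summary()`),
- seeded generators for every raw data modality
  (`simulate_dose_response()` and friends), so the whole pipeline is
  testable end to end.

## Worked example

Simulate a JNJ47965567 dose-response panel from the published
non-competitive parameters (K_A = 220 µM, τ = 10, n = 2.6,
K_B = 0.14 µM), then let the pipeline decide the mechanism:

```r
library(p2x7pharm)

truth <- p2x7_published_params("noncompetitive", "JNJ47965567")
d <- simulate_dose_response(simulation_design(
  truth, antagonist_grid = c(0, 0.03, 0.1, 0.3, 1) * 1e-6,
  noise_sd = 0.02, seed = 1, antagonist_id = "JNJ47965567"))

res <- compare_mechanisms(d)
res$comparison
#> <mechanism_comparison>
#>   SS  competitive = 1.66   noncompetitive = 0.6835
#>   R2  competitive = 0.9483   noncompetitive = 0.9787
#>   F(1, 196) = 280.1, p = 1.25e-39 -> noncompetitive
res$noncompetitive$params$KB * 1e9
#> [1] 73.2
```

The non-competitive model fits far better (R² 0.979 vs 0.948; the
extra-SS F-test rejects the competitive model at p ≈ 1e-39), and the
fitted K_B of 73 nM sits near the generating 140 nM — a single noisy
panel carries this much spread, which is why recovery is judged by the
median over seeded replicates (that median lands within a few percent;
see below).

The numbered scripts under `analysis/` run the full study as a
narrative: `01_simulate_data.R` writes every simulated raw-data modality
under `results/sim/`, and `02`–`06` reduce rates, fit mechanisms per
drug, run Schild, anisotropy, and accessibility analyses, writing their
tables under `results/`.

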