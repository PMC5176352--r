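---
title: "Deciding how P2X7 antagonists inhibit: models, fits, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding how P2X7 antagonists inhibit: models, fits, and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p2x7pharm)
```

## The scientific question

The P2X7 receptor is a trimeric ATP-gated cation channel, and a set of
structurally unrelated antagonists (A740003, A804598, AZ10606120,
GW791343, JNJ47965567) block it with high subtype specificity. The
question this package operationalizes is *how*: do these drugs compete
with the agonist for the ATP site, or do they bind an allosteric site and
suppress gating? Functionally the two mechanisms separate in dose-response
space. A competitive antagonist shifts the agonist curve rightward without
touching its maximum (surmountable inhibition), giving Schild dose ratios
that grow linearly with antagonist concentration. A non-competitive
antagonist depresses the maximum (insurmountable inhibition), and its
apparent dose ratios saturate.

The pipeline runs five analyses: reduction of dye-uptake time courses to
normalized initial rates; two-stage operational-model fitting under both
mechanisms; competitive-versus-non-competitive selection by
extra-sum-of-squares F-test; Schild regression with a nonlinearity
diagnostic; and, as orthogonal evidence, fluorescence-anisotropy binding
analysis (does the drug displace a fluorescent ATP analogue from the
orthosteric site?) plus cysteine-accessibility statistics (does the
drug-binding pocket narrow during gating?).

## The two response models

Responses are normalized initial rates of YO-PRO-1 dye uptake, with BzATP
as agonist at concentration $A$ and antagonist at $B$. The competitive
model is

$$R = \frac{A/K_A}{(A/K_A)(1+\tau) + B/K_B + 1},$$

with agonist dissociation constant $K_A$, antagonist dissociation
constant $K_B$, and operational efficacy $\tau$. Its high-agonist plateau
$1/(1+\tau)$ is independent of $B$: inhibition is purely a rightward
shift. The placement of $\tau$ in the denominator term $(A/K_A)(1+\tau)$
is an unusual operational-model variant; it is implemented exactly as
written, with the response treated as already normalized to the control
maximum (the model has no amplitude parameter, so responses above 1
cannot be absorbed by rescaling).

The non-competitive model is

$$R = \frac{A^n \tau^n E_{max}}
  {A^n \tau^n + \left(A(1 + \alpha B/K_B) + K_A B/K_B + K_A\right)^n},$$

with Hill coefficient $n$, maximal response $E_{max}$, and binding
cooperativity $\alpha$ between agonist and modulator, fixed at 1
(neutral). At $B=0$ it reduces to the operational model of agonism; with
$\alpha = 1$ the antagonist scales the effective efficacy by
$1/(1 + B/K_B)$, so the plateau
$E_{max}\tau^n/(\tau^n + (1+\alpha B/K_B)^n)$ falls with $B$ — the
insurmountability signature. Evaluation is done in log space
($R = E_{max}/(1+e^{v-u})$ with $u = n(\log A + \log\tau)$ and $v$ the
log of the denominator core), so $n = 2.6$ on extreme concentration
grids cannot overflow.

Published control-curve values used throughout as simulation truth:
competitive $K_A = 28\ \mu M$, $\tau = 0.031$; non-competitive
$K_A = 220\ \mu M$, $\tau = 10$, $n = 2.6$, $E_{max} = 1$. Per-drug
$K_B$ values under each mechanism are in `p2x7_published_kb()`.

## From fluorescence to responses

Uptake time courses are sampled at 1-min intervals from agonist addition.
Because uptake activity starts to decline roughly 10 min after agonist
application, samples beyond a 600 s cutoff are dropped, and the response
is the OLS slope of the first five baseline-subtracted samples (0–4 min).
The window is a package choice — the early samples are the linear regime
under the default simulation — and both window and cutoff are recorded in
the output metadata and configurable. Raw slopes are normalized per plate
to the mean rate of that plate's control wells (maximal agonist, no
antagonist), so the control maps to 1 and instrument gain cancels.

## Two-stage estimation

Fitting mirrors the staged procedure the models were designed for:

1. **Control stage.** The antagonist-free curve determines the
   agonist-side parameters: $(K_A, \tau)$ for the competitive model,
   $(K_A, \tau, n)$ for the non-competitive model with $E_{max}$ fixed
   at 1. On normalized data, $E_{max}$, $\tau$ and the plateau are
   jointly unidentifiable, hence the clamp (it can be freed).
2. **Antagonist stage.** With stage-1 parameters held fixed, $K_B$ is
   the only free parameter ($\alpha$ stays at 1), minimizing the joint
   SS over all points including the control curve.

All nonlinear fits use box-bounded L-BFGS-B on transformed scales
(concentration-like parameters and $\tau$ in $\log_{10}$), with a
deterministic multi-start grid (8 log-spaced midpoints for Hill fits; a
$K_A \times \tau$ grid for control fits), lowest-SS selection, and exact
ties broken by the lexicographically smallest parameter vector, so
results are bit-reproducible. $K_B$ is searched on a 61-point log grid
over $[10^{-12}, 10^{-2}]$ M and polished by golden-section refinement.
Bounds: $K_A \in [10^{-9}, 10^{-1}]$ M, $\tau \in [10^{-4}, 10^4]$,
$n \in [0.3, 6]$; loss is unweighted least squares on normalized
responses. Degenerate inputs (flat titrations, inert antagonists) return
flagged, non-converged results rather than raising mid-pipeline; an
inert antagonist is detected by an F-type check that freeing $K_B$ buys
no significant SS improvement.

A caveat worth knowing: with $\tau = 10$ the control plateau is 0.997,
so $\tau$ is only weakly identified from noisy normalized data (any
$\tau \gtrsim 6$ fits the plateau); $K_A$ co-drifts to preserve the
EC50 $\approx K_A/\tau$. The stage-2 $K_B$ inherits a little of that
drift, which is why recovery is judged by the median over seeded
replicates.

## Model selection

The competitive fit spends 3 parameters across the stages
($K_A, \tau, K_B$), the non-competitive fit 4
($K_A, \tau, n, K_B$). The extra-sum-of-squares statistic

$$F = \frac{(SS_c - SS_{nc})/(p_{nc}-p_c)}{SS_{nc}/(N-p_{nc})}$$

is referred to the $F(1, N-4)$ upper tail; if the simpler model fits at
least as well, $F$ is clamped to 0 and $p = 1$. The two mechanisms are
not strictly nested — the competitive model is not a parameter
restriction of the non-competitive one — so the F-test is a heuristic
here, and every comparison object carries that caveat. The verdict rule:
non-competitive if $p < \alpha$ (default 0.05) and its SS is lower;
competitive if the competitive fit is not significantly worse;
inconclusive if either fit failed. Under the simulated study conditions
($\sigma = 0.02$, five replicates, the published parameter sets) the
test selects the non-competitive mechanism in effectively all
non-competitive-truth runs and retains the competitive model in all
competitive-truth runs of the acceptance sweep.

## Schild analysis

For each antagonist concentration the agonist curve is fitted with the
Hill equation; the dose ratio is $r = EC_{50}'/EC_{50}$ and the Schild
plot regresses $\log_{10}(r-1)$ on $\log_{10} B$. For a competitive
antagonist $r = 1 + B/K_B$: slope 1 and x-intercept $\log_{10} K_B$
(pA2 $= -\log_{10} K_B$). Points with $r - 1 \le 0.05$ are excluded —
the variance of $\log(r-1)$ explodes as $r \to 1$ — with a warning.
Curvature is probed by adding a $(\log_{10} B)^2$ term and t-testing its
coefficient; curvature rather than lack-of-fit is used because replicate
EC50s per concentration are not assumed. Slices are fitted with the Hill
slope clamped at the control curve's fitted slope (parallelism is a
premise of Schild analysis; freeing the slope per slice makes the
$EC_{50}'$ of strongly suppressed curves erratic), while each slice
keeps its own free maximum.

**A power limitation, quantified.** Simulations from the non-competitive
truth do bend the Schild plot (noiseless pipelines give a clearly
negative quadratic coefficient, and dose ratios grow sub-linearly), but
the quadratic t-test detects the bend unreliably: with the published
JNJ47965567 parameters, $\sigma = 0.02$, five replicates, and twelve
antagonist concentrations spanning three decades, the detection rate is
only about 20–50% at $\alpha = 0.05$ across the designs we profiled.
Two causes compound. First, the true $\log(r-1)$ curve is
linear-then-plateau, so the quadratic's own lack-of-fit inflates the
coefficient's standard error — even noise-free model-implied dose ratios
only reach $p \approx 0.02$. Second, where the bend lives
($B \gg K_B$) the agonist curve is suppressed to an amplitude comparable
with the noise and its shifted EC50 approaches the top of the 1 mM
agonist range, so $EC_{50}'$ estimates there are noisy and
upward-biased, which straightens the plot. This is a quantitative
restatement of why Schild regression alone is a weak instrument for
mode-of-action inference and why the model comparison and binding assay
carry the decision weight.

## Anisotropy binding analysis

Steady-state anisotropy is
$r = (I_{VV} - G I_{VH})/(I_{VV} + 2 G I_{VH})$ with instrument factor
$G = I_{HV}/I_{HH}$. Binding of a small fluorescent ATP analogue to the
large receptor slows its tumbling and raises $r$; the titration of $r$
against receptor concentration is fitted with a four-parameter Hill
curve (free ends = free/bound anisotropies, published slope 0.90).
Allosteric antagonists leave this curve unchanged — the generator's
`drug_effect = "none"` arm encodes that observed outcome, and
`"block_binding"` encodes the counterfactual competitive outcome —
while excess unlabelled ATP collapses $r$ to the free value (the
competition fit, with a monotone-decrease diagnostic). Anisotropy values
outside $[-0.2, 0.4]$ warn but are returned; deciding whether they are
instrument artifacts is the analyst's call. One sentence in the source
describing the $G$-factor intensities appears to contain a typographical
slip (naming $I_{VV}$ where $I_{HH}$ is meant); the displayed formula
$G = I_{HV}/I_{HH}$ is implemented.

## Accessibility statistics

For cysteine-accessibility experiments each cell contributes the ratio
of current amplitude after to before application of a bulky
thiol-reactive probe (MTS-TPAE). Ratios are divided by the mean ratio of
matched no-reagent control cells to cancel rundown (controls are matched
per construct when available, with a flagged fall-back to the pooled
cohort — the source protocol's same-cell control is not representable in
a table of one before/after pair per cell). Group comparisons use
one-way ANOVA followed by Dunnett's many-to-one test against wildtype at
$\alpha = 0.01$. The Dunnett reference distribution — the null maximum of
the correlated many-to-one |t| statistics sharing the control mean and
pooled variance — is evaluated by seeded Monte Carlo ($10^5$ draws by
default), which handles arbitrary group counts and unequal $n$
identically; it reduces to the pooled two-sample t-test for two groups
and agrees with `multcomp`'s multivariate-t computation to Monte-Carlo
error.

## What the generators emulate, and what they do not

The synthetic-data module emulates: Hill- or mechanism-shaped mean
responses with additive Gaussian noise $\sigma = 0.02$ on normalized
responses (a stand-in on the visual SEM scale of five-replicate uptake
data; the source reports no numeric noise magnitude), five replicates
per condition, an 8-point log-spaced agonist grid (0.1 µM–1 mM
BzATP-equivalent), antagonist designs spanning three decades, uptake
time courses with a 1-min sampling interval and an exponential
flattening after 600 s, anisotropy intensity quadruples constructed to
reproduce a target $r$ exactly under a known $G$, and lognormal
patch-clamp baselines with multiplicative noise and per-state rundown.
Negative simulated responses are kept, not clipped; the fitting must
tolerate them.

Passing tests on these data therefore demonstrate estimator correctness
and statistical behaviour *under the assumed error model* — independent
additive Gaussian noise. Real plate-reader data have replicate
correlation, heteroscedasticity (noise growing with signal),
plate-edge effects, and drift that the generators deliberately omit;
recovery tolerances on real data would be wider.

## Problem sizes and reproducibility

The test and acceptance sweeps use 20 seeded replicates for parameter
recovery (medians reported) and 50 for the model-selection and Schild
property sweeps — sizes at which the medians are stable to a few percent
while the full suite runs in minutes on a laptop. Every generator seeds
locally (`withr::with_seed`), leaving the caller's RNG untouched, and
every stage seed derives deterministically from a single top-level seed.
All concentrations are stored in molar internally; only report
formatting converts to nM/µM/mM.

## Known limitations

- The Schild curvature test is underpowered under realistic noise (see
  above); treat `curvature_p` as supporting, not primary, evidence.
- $\tau$ and $K_A$ are nearly collinear for high-efficacy control curves
  on normalized data; interpret stage-1 parameters jointly, not
  marginally.
- The F-test compares non-nested models; its p-value is a ranking
  heuristic, reported with a caveat, not an exact size guarantee.
- Current-amplitude extraction from raw sweeps, photobleaching
  correction, and vendor plate-reader formats are out of scope; the
  pipeline consumes measured amplitudes and tidy CSV tables.
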