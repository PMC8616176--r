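---
title: "Models and methods behind clonefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonefit)
```

# The scientific problem

Drug-efflux-pump expression (ABCB1/P-glycoprotein, here driven by a
promoter-hijacking *SLC25A40-ABCB1* fusion) makes tumour cell clones
multidrug resistant, but maintaining ATP-dependent pumps carries a
bioenergetic cost that shows up as slower proliferation. clonefit packages
the quantitative machinery needed to study that trade-off in single-cell
derived clones of high-grade serous ovarian cancer and similar systems:

* absolute fitness of each clone from logistic growth fits;
* competitive interactions between a sensitive and a resistant clone in
  co-culture, via a two-species Lotka-Volterra model;
* drug response corrected for division-rate confounding (GR metrics)
  alongside conventional IC50s and mixture predictions;
* hit calling for multi-plate 384-well viability screens;
* normalization, reduction and testing of per-cell morphology features.

Every analysis has a matching synthetic-data generator with a ground-truth
sidecar, so the estimators are continuously validated against known truth
without any external data.

# Growth and fitness

A clone's trajectory (confluence % or fluorescence area) is modelled as
logistic growth,

$$x(t) = \frac{K}{1 + \frac{K - x_0}{x_0} e^{-rt}},$$

with intrinsic growth rate $r$ (1/h) as the absolute fitness measure,
carrying capacity $K$ in signal units and initial signal $x_0$. The doubling
time is $\ln 2 / r$ and the time to a confluence threshold $c$ has the
closed form $t_c = \ln\!\big\{\tfrac{(K-x_0)/x_0}{(K-c)/c}\big\}/r$
(`time_to_threshold()`; a raw-interpolation variant exists for diagnostics,
but the model-based inversion is the default because it is robust to
single-point noise).

`fit_logistic()` fits all three parameters by bounded Levenberg-Marquardt on
the raw signal scale ($r \in (0,1]$/h, $K \in (\max x/2, 10\max x]$,
$x_0 \in (0, 3 x_1]$), starting from $K = 1.05\max x$, the first positive
signal for $x_0$, and the slope of $\log\{x/(K-x)\}$ over the first half of
the series for $r$. Convergence is reported `FALSE` when the optimizer fails
or a parameter sits on a bound. Identifiability caveat: $K$ is only
determined once the curve approaches saturation, so recovery tests sample to
$\approx t_{90\%}$ of each rate; a 44 h-doubling clone observed for 264 h
reaches only ~40% of $K$ and its monoculture-only $K$ estimate is fragile —
this drives a design choice in the competition fit below.

Replicates are fitted independently and summarized per clone by the mean
(`growth_summary()`). Group fitness is compared with a pooled-variance
Student t-test (`compare_fitness()`), which gives integer degrees of freedom
$n_A + n_B - 2$ (8 for the canonical 5-vs-5 clone design); the fold
difference in fitness is the ratio of group-mean rates.

# Competition in co-culture

The two-clone competitive Lotka-Volterra system (s = sensitive,
r = resistant) is

$$\frac{dx_s}{dt} = r_s x_s\Big(1 - \frac{x_s + \alpha_{sr} x_r}{K_s}\Big),
\qquad
\frac{dx_r}{dt} = r_r x_r\Big(1 - \frac{x_r + \alpha_{rs} x_s}{K_r}\Big),$$

where $\alpha_{sr}$ is the per-capita crowding effect of the resistant clone
on the sensitive clone (normalized by the focal clone's carrying capacity)
and $\alpha_{rs}$ the reverse. Their ratio $\alpha_{rs}/\alpha_{sr}$
measures competitive asymmetry; values above 1 mean the sensitive clone
suppresses the resistant clone more than vice versa. With equal rates and
capacities and $\alpha_{sr} = 0.2$, $\alpha_{rs} = 0.7$ (the shipped
preset), the coexistence equilibrium is
$x^*_i = K(1-\alpha_i)/(1-\alpha_{sr}\alpha_{rs})$, i.e. fractions
0.727 : 0.273 — sensitive-dominated, as expected when efflux-pump
maintenance taxes proliferation. Integration uses `deSolve::ode` (`lsoda`,
rtol 1e-8, atol 1e-10; the generator integrates tighter, rtol 1e-11, so the
decoupled case matches the closed-form logistic to ~1e-8).

`fit_lv()` estimates all dynamics parameters jointly — $r_s, r_r, K_s, K_r,
\alpha_{sr}, \alpha_{rs}$, the monoculture seeding signals and a shared
co-culture seeding density — by Levenberg-Marquardt on **log-scale
residuals** over every monoculture and co-culture observation. Two design
choices deserve justification:

* *Joint rather than two-stage.* Freezing $(r, K)$ at monoculture-only
  estimates is attractive for identifiability but breaks down exactly in the
  regime this model targets: a slow resistant clone that never nears $K$
  within the horizon leaves $K_r$ nearly unidentifiable from its
  monoculture, and that error aliases into both competition coefficients.
  The joint fit lets the co-cultures constrain the shared dynamics; the
  per-replicate logistic fits survive as starting values and diagnostics.
* *Log residuals.* Measurement noise on confluence/fluorescence signals is
  proportional to signal (the generator's model, and typical of imaging
  readouts), so constant-CV weighting is the maximum-likelihood choice and
  prevents the plateau from dominating the fit.

When the curve table records the seeded sensitive fraction, each
co-culture's initial state is constrained to (fraction, 1 − fraction) times
a single estimated seeding density — seeding ratios are
experimenter-controlled metadata, and using them measurably tightens the
weakly identified $\alpha_{sr}$.

Uncertainty comes from a residual bootstrap (`bootstrap_lv()`): residuals
are taken as observed/fitted *factors* and resampled with replacement
within each curve, then the whole fit is repeated. Additive resampling
would move plateau-sized residuals onto near-zero early time points and
produce invalid negative pseudo-signals under multiplicative noise.
Resample $i$ uses derived seed `seed + i`, so enlarging the resample count
extends, rather than reshuffles, the stream.

*Precision of the recovered asymmetry.* Under the shipped study conditions
(12 h sampling to 264 h, 4 replicates, 5% noise) the informative signal for
$\alpha_{sr}$ is at most a ~3.5% depression of the sensitive channel — the
same order as the noise — so a single simulated experiment recovers the
ratio only within roughly a factor of 1.5 (bootstrap intervals say as
much). The package therefore reports recovery as the median over several
replicate simulated experiments (9 in the shipped checks), which
stabilizes near the generating value 3.5 while leaving every generating
condition untouched.

# Dose-response: IC50, GR50 and mixtures

`fit_4pl()` fits control-normalized viability
$v(d) = b + (t - b)/(1 + (d/e)^h)$ with the Hill slope constrained positive
(viability decreasing in dose); data whose best fit inverts the asymptotes
are reported non-converged rather than silently fitted. The package reports
the **absolute** IC50 — the dose where viability is 50% of vehicle control —
solved from the fitted curve, alongside the curve midpoint `ec50_rel`; the
two coincide only for $t = 1, b = 0$. Fold resistance between clone groups
is the ratio of arithmetic group-mean IC50s.

Because a slowly dividing clone accumulates fewer drug-affected divisions in
a fixed 72 h window, end-point IC50s confound division rate with intrinsic
sensitivity. The normalized growth-rate inhibition value

$$\mathrm{GR} = 2^{\log_2(x_c/x_0) / \log_2(x_{ctrl}/x_0)} - 1$$

measures the effect per division: GR = 1 means no effect, 0 complete
cytostasis, negative values net cell loss. `fit_gr_curve()` fits
$\mathrm{GR}(c) = \mathrm{GR}_{inf} + (1 - \mathrm{GR}_{inf})/(1 +
(c/\mathrm{GEC}_{50})^{h})$ and solves GR = 0.5 for the GR50. A GR50 is
flagged UTBD ("unable to be determined") when the fitted curve is flat —
operationalized as $|1 - \mathrm{GR}_{inf}| < 0.1$ — or when the 0.5
crossing falls outside the tested dose range; flat inputs are a flag, not
an error. The defining invariance (clones differing *only* in division rate
share a GR curve, hence a GR50, while their IC50s diverge) is exercised in
the test suite by construction.

Clonal mixtures are predicted under independent action:
$S(d) = (1-f) S_{neg}(d) + f S_{pos}(d)$ for resistant fraction $f$, with
the mixture IC50 found by root bisection over a bracket two decades beyond
the tested doses. This model is monotone in $f$, so an empirical finding
that mixtures track the pure sensitive clone's IC50 (as the motivating
system shows) indicates sensitive cells dominate the 72 h assay window
beyond what independent action predicts — the prediction is a null model to
compare against, not a claim about the biology.

# Screen normalization and hit calling

Counts are normalized per plate as fold change to the median of that
plate's negative-control wells, which cancels multiplicative batch effects
exactly (`normalize_plates()`). Robust Z-scores use the normal-consistent
MAD scaling $z = (x - \mathrm{median})/(1.4826\,\mathrm{MAD})$, computed
against all compound wells of the same cell line (controls excluded); a
zero MAD falls back to the SD with a flag (`robust_z()`,
`screen_robust_z()`).

Two rules are exposed: a **primary hit** has fold change < 0.5 at one or
more doses in *every* required cell line (`call_primary_hits()`); a
**validation nomination** requires robust Z < −2 at two or more dose points
(`nominate_validation_hits()`), where by default a dose qualifies on the
across-line mean Z profile (a per-line conjunction mode is available —
how lines are combined is genuinely underdetermined, so both are
implemented). Dose ladders default to the 3-point (5, 0.5, 0.05 µM) primary
and 6-point (10, 5, 2.25, 0.5, 0.225, 0.05 µM) validation designs. No
spatial/B-score correction is applied: the normalization model is
plate-level multiplicative only.

# Morphology features

Per-cell features are robust-Z scored to the median and MAD of the same
feature in the reference (sensitive) population. Features whose reference
MAD is numerically zero (below 1e-6 of the dataset's median feature MAD)
are flagged and centred but not scaled, so near-constant "inactive"
features keep near-zero variance and are removed by the variance floor of
`reduce_features()` (default 1e-3 on the normalized scale) rather than
being inflated into unit-variance noise.

`reduce_features()` then iterates to a fixed point: drop inactive features;
while any retained pair exceeds |Pearson r| = 0.85, take the most
correlated violating pair and drop the member with the higher mean absolute
correlation to all remaining features (ties broken by name, so the
procedure is deterministic). The result is idempotent, its removal log is
complete, and no retained pair exceeds the cut. Group differences are
tested per feature with Welch's t-test on per-cell values;
Benjamini-Hochberg adjusted p-values are reported alongside raw ones.

# What the generators emulate — and what they do not

`gen_growth_curves()`, `gen_coculture()`, `gen_screen()`,
`gen_dose_response()` and `gen_morphology()` emulate, respectively:
logistic clone growth sampled every 12 h to 264 h with 4 replicates;
mono- plus co-cultures at 25:75 / 50:50 / 75:25 seeding ratios read out on
two fluorescence channels; multi-plate 384-well screens with ≥8 DMSO
control wells per plate, per-plate lognormal batch factors and planted
true-viability effects; 4PL survival with fraction-weighted mixtures plus
control and time-zero wells; and Gaussian feature tables with correlated
blocks, inactive features and group shifts in reference-MAD units.

Shared conventions: measurement noise is multiplicative Gaussian,
$x(1+\varepsilon)$, $\varepsilon \sim N(0, cv^2)$ truncated at −0.9
(signals stay positive; counts are real-valued since nuclear counts are
large), with 5% the default CV for imaging signals and 10% for well counts
— plausible magnitudes for these assays, chosen once since the instruments'
noise is not published. Every generator consumes one explicit seed, draws
nothing outside it, restores the caller's RNG, and emits a ground-truth
sidecar that regenerates the data byte-for-byte.

The generators deliberately omit: spatial plate artefacts (edge effects),
temporally autocorrelated imaging noise, channel cross-talk and
non-proportional fluorescence, cell-cycle structure, and non-Gaussian
morphology feature distributions. Passing tests therefore demonstrate
estimator correctness under the stated noise model, not robustness to
every artefact of real instruments.

The shipped presets encode the motivating system's headline parameters as a
reproducible scenario: a 22 h-doubling sensitive clone versus a
44 h-doubling resistant clone (fitness ratio exactly 2), equal $K$, and
competition coefficients 0.2 / 0.7 whose asymmetry ratio is 3.5.

# Numerical choices and degenerate inputs

* Nonlinear fits use `minpack.lm`'s bounded Levenberg-Marquardt through one
  shared wrapper (raw `nls.lm` interface; tight ftol/ptol 1e-15 so exact
  synthetic data are recovered to ~1e-6 relative or better).
* ODE integration: `lsoda` with rtol 1e-8 / atol 1e-10 for fitting, tighter
  for generation; a fixed-step `rk4` can be selected for reproducibility
  experiments.
* Degenerate inputs are contracts, not crashes: flat growth curves and
  missing controls error with diagnostics; flat GR curves return UTBD;
  zero-MAD scales fall back with flags; zero pooled variance with unequal
  means reports an infinite t with a flag; undefined IC50s are excluded
  from fold-resistance with a warning.
* Problem sizes in the shipped checks (4 replicates, 9 simulated
  experiments for the competition recovery, 20–25 seeds for screen
  calibrations, 500 cells/group for morphology) are the package's
  statistical design: large enough that calibration statements (e.g. ~5%
  null significance) are stable, small enough to re-run routinely.

# Known limitations

* The LV model covers exactly two clones with logistic self-limitation; no
  treatment-coupled dynamics or >2-clone communities.
* $\alpha_{sr}$ (effect of a suppressed, slow clone on a dominant fast one)
  is intrinsically weakly identified on a 264 h horizon; report it with its
  bootstrap interval, never as a point value alone.
* GR metrics assume exponential control growth between $x_0$ and
  $x_{ctrl}$; strongly density-limited control wells violate this.
* The mixture IC50 model assumes independent action and no clone-clone
  interaction during drug exposure.
* Feature reduction is a greedy correlation filter, not a factor model; it
  controls redundancy, it does not find latent structure.
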