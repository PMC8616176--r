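# clonefit

Quantitative analysis of drug-sensitive versus drug-resistant tumour cell
clones. Constitutive expression of the ABCB1/P-glycoprotein efflux pump (for
example through a promoter-hijacking *SLC25A40-ABCB1* fusion) confers
multidrug resistance but taxes proliferation — resistant clones grow roughly
half as fast as their sensitive siblings and are outcompeted in co-culture.
clonefit implements the estimators needed to quantify that trade-off, for
researchers studying clonal competition, adaptive-therapy rationales, and
drug screens across mixed clonal populations:

* **Growth & fitness** — logistic fits
  `x(t) = K / (1 + ((K − x₀)/x₀) e^(−rt))` per clone/replicate; intrinsic
  rate `r` as absolute fitness, doubling time `ln2/r`, analytic
  time-to-threshold; pooled-variance group t-tests and OLS correlations.
* **Competition** — two-clone Lotka–Volterra model
  `dx_s/dt = r_s x_s (1 − (x_s + α_sr x_r)/K_s)` (and symmetrically for
  x_r), fitted jointly to mono- and co-culture curves; the coefficient
  ratio `α_rs/α_sr` measures competitive asymmetry, with residual-bootstrap
  uncertainty.
* **Dose–response** — 4PL viability fits with absolute IC50 and fold
  resistance; normalized growth-rate inhibition
  `GR = 2^(log₂(x_c/x₀)/log₂(x_ctrl/x₀)) − 1` with GR50 and UTBD flagging;
  independent-action mixture IC50 predictions; replicate-level group
  comparisons.
* **Screening** — per-plate fold-change normalization to control medians,
  dataset robust Z-scores (1.4826·MAD), <50%-of-control primary hits and
  Z < −2 validation nominations for 384-well screens.
* **Morphology** — reference-population robust-Z scaling, iterative
  variance/correlation feature reduction (|r| > 0.85), per-feature Welch
  tests with BH adjustment.
* **Synthetic data** — seeded generators for every input above, each with a
  ground-truth JSON sidecar that regenerates the data byte-for-byte.

## Worked example

Simulate the shipped scenario — a 22 h-doubling sensitive clone and a
44 h-doubling resistant clone, competing with asymmetric coefficients
α_sr = 0.2, α_rs = 0.7 — then recover the dynamics from the noisy curves:

```r
library(clonefit)

sim <- gen_coculture(fusion_competition_preset(noise_cv = 0.05),
                     n_replicates = 4, seed = 1)
fit <- fit_lv(sim$curves)
fit
#> <lv_fit> r_s = 0.03146, r_r = 0.01570, K_s = 100.3, K_r = 103.3
#>   alpha_sr = 0.2117, alpha_rs = 0.7267  (ratio alpha_rs/alpha_sr = 3.432)
#>   co-culture RSS = 1.923, converged: TRUE
```

The fitted rates reproduce the generating doubling times (ln2/0.03146 ≈ 22 h,
ln2/0.01570 ≈ 44 h) and the competition ratio of 3.43 recovers the planted
asymmetry of 3.5: sensitive cells suppress resistant cells ~3.5× more
strongly than the reverse. Per-clone fitness from monocultures:

```r
gs <- gen_growth_curves(clone_presets(noise_cv = 0.05),
                        n_replicates = 4, seed = 1)
growth_summary(gs$curves, threshold = 50)$summary
#>             clone       r     K     x0   t_d t_thresh    rss n_replicates converged
#> 1 fusion_negative 0.03186 101.1 0.9564 21.76    145.5 117.04            4      TRUE
#> 2 fusion_positive 0.01612 105.2 0.9680 43.00    298.2  11.46            4      TRUE
```

`t_thresh` is the time to 50% confluence: ~146 h for the sensitive clone —
the resistant clone needs twice as long. Comparing per-clone growth rates
between groups:

```r
compare_fitness(c(0.030, 0.031, 0.032, 0.029, 0.033),
                c(0.0150, 0.0160, 0.0140, 0.0155, 0.0165))
#> <fitness_comparison> mean A = 0.031, mean B = 0.0154 (ratio 2.013)
#>   pooled t = 18.849, df = 8, p = 6.489e-08
```

And the division-rate-corrected drug effect for a well that grew from 100 to
200 cells while controls reached 800:

```r
compute_gr(200, 100, 800)
#> [1] 0.259921
```

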