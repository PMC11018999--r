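---
title: "Methods: two-sample Mendelian randomization with mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here the motivating application is serum urate, measured in SD
units, 1 SD = 80.3 umol/L) on an outcome (stroke risk or prognosis, on the
log-odds scale) using genetic variants as instrumental variables. For
instrument $j$, let $\gamma_j$ ($\sigma_{xj}$) be its estimated effect on
the exposure and $\Gamma_j$ ($\sigma_{\Gamma j}$) its effect on the
outcome, taken from two non-overlapping GWAS. If the instrument is valid
(relevance, independence, exclusion restriction), every Wald ratio
$\Gamma_j / \gamma_j$ estimates the same causal effect $\beta$.

`mrpipe` implements the summary-data estimator stack around this model:

* **IVW with multiplicative random effects** (`ivw_mre()`, the primary
  estimator): weighted regression of $\Gamma_j$ on $\gamma_j$ through the
  origin with weights $w_j = 1/\sigma_{\Gamma j}^2$. Cochran's
  $Q = \sum_j w_j(\Gamma_j - \hat\beta\gamma_j)^2$ measures per-SNP
  heterogeneity; the SE is inflated by $\sqrt{\max(1, Q/(J-1))}$ so the
  random-effects SE never undercuts the fixed-effect one. P-values use the
  standard normal, the summary-data MR convention at large $J$.
* **MR-Egger** (`egger()`): the same weighted regression with an
  intercept, after orienting every instrument to a non-negative exposure
  effect (Egger is not orientation-invariant, so the convention must be
  fixed). The slope remains consistent under directional pleiotropy that
  is independent of instrument strength; the intercept (with SE scaled by
  $\sqrt{\max(1, Q_E/(J-2))}$) is the pleiotropy test.
* **Weighted median** (`weighted_median()`): the inverse-variance-weighted
  median of the ordered Wald ratios, i.e. linear interpolation at
  cumulative weight midpoint one half, with weights
  $(\gamma_j/\sigma_{\Gamma j})^2$. Consistent while valid instruments
  carry more than half of the weight. Its SE comes from a parametric
  bootstrap redrawing $(\gamma_j, \Gamma_j)$ from their normal sampling
  laws (1000 draws by default, seed exposed).
* **MR-PRESSO** (`presso()`): residual-sum-of-squares outlier machinery.
  Residuals are measured against leave-one-out IVW slopes for both the
  global and the per-SNP test; observed statistics are compared against
  `n_sim` parametric simulations under the fitted model, per-SNP p-values
  are Bonferroni-corrected, and the corrected estimate is the IVW fit on
  the non-outliers. The distortion test compares the estimate shift
  against removals of random subsets of the same size. Per-SNP empirical
  p-values use the $(r+1)/(n+1)$ convention, so with the default 1000
  simulations the smallest attainable p is about $10^{-3}$.

## Instrument selection

`select_instruments()` runs a fixed, logged order in which every stage can
only remove SNPs: genome-wide significance ($p < 5\times10^{-8}$, strict) →
greedy LD clumping ($r^2 < 0.001$ within 10,000 kb; ranked by ascending p,
ties broken lexicographically for determinism) → harmonization with
unconditional exclusion of A/T and G/C palindromes (no frequency-based
rescue: strand cannot be resolved reliably for them) → exclusion of SNPs
associated with the outcome ($p < 5\times10^{-5}$) → Steiger directionality
filtering → the per-SNP weak-instrument screen.

Variance explained and instrument strength use
$R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\,\beta^2$ and
$F = \frac{N-k-1}{k}\frac{R^2}{1-R^2}$. The F *screen* uses per-SNP F
($k=1$) with the conventional $F < 10$ cut; the overall-F form with the
full $k$ is a reported diagnostic only. Because "mean F" is ambiguous
(mean of per-SNP F and the overall formula disagree numerically), the
diagnostics report carries both `f_overall` and `f_mean`.

The Steiger filter removes SNPs explaining more variance in the outcome
than in the exposure. For quantitative traits the allele-frequency form
above is used; for binary traits we use the liability-free approximation
$r^2 \approx z^2/(z^2 + n_\mathrm{eff})$ with
$n_\mathrm{eff} = 4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})$, which is
monotone in $|z|$ and requires no prevalence input. Whether Steiger
filtering runs before or after the outcome-association exclusion is not
identified by practice; the pipeline fixes the order above and logs it.
Proxy-SNP lookup is deliberately absent: instruments missing from the
outcome GWAS are dropped with a reason code.

Clumping consumes a user-supplied pairwise $r^2$ lookup (`ld_lookup()` on a
3-column table) or an explicit independence assertion (`ld_independent()`);
the package does not bundle an LD reference panel.

## Multivariable MR, mediation, meta-analysis

`mvmr_ivw()` fits the weighted multiple regression of $\Gamma_j$ on the
matrix of exposure effects without intercept, weights $1/\sigma_{\Gamma
j}^2$, SEs scaled by $\sqrt{\max(1, Q/(J-m))}$; with one exposure it
reduces exactly to `ivw_mre()`. The instrument set is the union of the
per-exposure selections, jointly re-clumped and harmonized to one
orientation (`mvmr_instrument_union()`); the union rule is logged since no
single convention is universal. Confounder adjustment can be run
one-covariate-set-at-a-time or jointly via `study_config(mvmr_sets =)`.

Two-step mediation (`two_step_mediation()`) estimates
$\beta_1$ (exposure → mediator, univariable IVW on the exposure's
instruments) and $\beta_2$ (mediator → outcome conditional on the
exposure, multivariable IVW on the joint set). The indirect effect is
$\beta_1\beta_2$ with delta-method SE
$\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$, and the proportion mediated
is $\beta_1\beta_2/\beta \times 100\%$ with $\beta$ the univariable total
effect from the same data. The proportion CI uses the delta method on the
ratio treating the three estimates as independent; because that
independence is an approximation (numerator and denominator share
instruments), a seedable parametric-bootstrap percentile CI is also
provided (`n_boot`).

`meta_ivw()` pools per-consortium IVW estimates: fixed-effect by default
(reporting $Q$, its p, and $I^2 = \max(0, (Q-(k-1))/Q)\cdot100$), with a
DerSimonian–Laird random-effects option. The default is fixed effect
because a single pooled estimate plus $I^2$ is the most common reporting
style for two-study consortium pairs; neither model is asserted as
canonical, and both are exposed.

Reverse-direction MR (`reverse_mr()`) reruns the entire selection and
estimation chain with the trait roles swapped, and returns an explicit
`no_instruments` status (not an error) when the outcome trait has no
genome-wide-significant instruments — the expected situation for modest
binary-trait GWAS.

## Power and sample overlap

`mr_power_binary()` is the closed-form power of the two-sided Wald test
for a binary outcome: the hypothesized OR is attenuated to the
risk-difference scale, $b = K(\mathrm{OR}/(1+K(\mathrm{OR}-1)) - 1)$ with
case fraction $K$; the estimator variance is $(K(1-K)-b^2)/(NR^2)$; power
is $\Phi(-z_{1-\alpha/2}+|b|/\mathrm{sd}) +
\Phi(-z_{1-\alpha/2}-|b|/\mathrm{sd})$. The test suite checks it against a
numerical-integration oracle rather than against any published table,
because published power columns rarely state their OR and $\alpha$ inputs.

`overlap_bias()` quantifies the weak-instrument bias induced by
exposure/outcome sample overlap: bias $= \mathrm{overlap} \times
\mathrm{confounded\ effect} / \bar F$, and the inflated type-I error is
the rejection rate of the nominal level-$\alpha$ test when the estimator
is centred at that bias. The confounded observational association and
$\bar F$ are required inputs — there is no defensible silent default for
an observational association.

## The synthetic-data generator

All validation runs on `sim_truth()` scenarios: summary-level simulation
with no individual genotypes, because every estimator consumes summary
data only. Defaults emulate the motivating study's conditions: a
quantitative exposure GWAS of $n = 437{,}354$ with ~300 instruments
jointly explaining ~6% of variance (instrument-effect scale
`gamma_sd = 0.025` was chosen to reproduce that $R^2$ sum), and a binary
outcome GWAS of $n = 311{,}635$ with case fraction $K = 0.1278$
(FinnGen-scale any-stroke). Mediator traits default to a blood-pressure
scale GWAS of $n = 450{,}000$. Per-SNP SEs follow
$1/\sqrt{n\cdot2p(1-p)}$ (quantitative) and
$1/\sqrt{n\,K(1-K)\,2p(1-p)}$ (binary, log-odds; documented as an
approximation); EAFs are uniform on $[0.05, 0.95]$; p-values follow the
normal law exactly.

Design choices worth noting:

* **Instrument orientation.** True effects are half-normal (positive,
  i.e. aligned to the exposure-increasing allele), matching how the MR
  simulation literature injects directional pleiotropy; allele labels and
  reported orientations are then scrambled so harmonization has real work
  to do. With symmetric effects around zero, "directional" pleiotropy
  would average itself away and no estimator comparison would be
  informative.
* **Exact invalid fraction.** A scenario's invalid-instrument fraction is
  applied as an exact count at random positions, not a binomial draw, so
  a "40% invalid" scenario never silently crosses the weighted-median
  50% breakdown point through sampling noise.
* **Overlap.** Overlapping samples are modelled as correlated estimation
  noise with correlation `overlap_fraction * overlap_confounding`. This
  reproduces the qualitative bias behaviour without individual-level
  data; it is not calibrated to any specific cohort pair.
* **LD blocks** (`simulate_ld_block()`) are equicorrelated with
  estimate-level correlation $\sqrt{r^2}$ (the genotype correlation), at
  fixed EAF so the equicorrelation is exact, together with the matching
  3-column LD table.

What the generator does *not* emulate: realistic allele-frequency spectra,
chromosome-scale LD maps, population stratification, or winner's-curse
selection from a discovery scan. Passing recovery tests on this generator
therefore shows the estimators and plumbing are correct under their
stated assumptions, not that any particular real-data finding is right.

## Validation scenarios and problem sizes

The acceptance-style checks in `tests/testthat/test-acceptance.R` (also
recomputed by `scripts/acceptance.R`) use these scenarios, chosen to be
informative at desk scale:

* Null calibration: $\beta = 0$, $J = 100$, 1000 replicates; IVW rejection
  at $\alpha = 0.05$ must sit in the exact binomial 99% band
  $[0.033, 0.069]$.
* Recovery: $\beta = 0.1$, $J = 300$, balanced pleiotropy SD 0.01 (all
  instruments), 200 replicates, after genome-wide selection; and Egger
  recovery of directional pleiotropy mean 0.02. The selection step is part
  of the scenario: instruments indistinguishable from zero would otherwise
  be mis-oriented by the $\gamma_j \ge 0$ convention and dilute the
  injected intercept — precisely why real pipelines only ever feed
  selected instruments to Egger.
* Weighted-median robustness: 40% invalid with directional pleiotropy
  mean 0.15 (SD 0.05) on strong instruments (`gamma_sd = 0.1`), $J = 300$:
  pleiotropic ratio shifts must stand clear of the Wald-ratio noise for
  the median's breakdown advantage to be measurable at all.
* MR-PRESSO: one injected outlier with a 10x Wald ratio at a
  typical-strength (median) instrument among 20, 100 seeded runs,
  `n_sim = 1000`.
* Mediation: $\delta = 0.5$, $\tau = 0.2$, direct 0.1 (true proportion
  50%), 200 replicates; delta-method SE vs a $10^4$-draw Monte Carlo.

## Numerical conventions and degenerate inputs

Estimates are produced on the log-odds scale; ORs are `exp(beta)` with
95% CI `exp(beta ± 1.96 se)`. Results TSVs print 10 significant digits and
round-trip losslessly. Fewer than 2/3/4 instruments raise explicit errors
for IVW/Egger-median/PRESSO respectively; a zero exposure effect makes the
Wald ratio an error, while an all-zero exposure *column* in MVMR is
reported as a zero effect rather than a failure. A zero total effect makes
the proportion mediated undefined (`NA`) while the indirect effect is
still reported. Duplicate SNP ids keep the lowest-p row; clumping ties at
equal p resolve lexicographically; every generator and every stochastic
method (median bootstrap, PRESSO, mediation bootstrap) is fully
determined by its seed, and `run_study()` reruns are byte-identical.

## Known limitations

Mode-based estimators, MR-RAPS, MVMR-Egger and conditional-F diagnostics
are out of scope. The binary-trait Steiger approximation ignores liability
scaling. The proportion-mediated delta CI assumes independence of its
three components. The overlap-bias tool is a first-order screening
approximation, and its inputs (confounded effect, mean F) must come from
the analyst. The generator's simplifications are listed above.
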