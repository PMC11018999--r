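# mrpipe

Two-sample Mendelian randomization (MR) pipelines from GWAS summary
statistics, in base R.

MR uses genetic variants as instrumental variables to estimate the causal
effect of an exposure on an outcome from two independent GWAS — for
example, whether genetically predicted serum urate (per SD, 1 SD =
80.3 µmol/L) changes stroke risk or post-stroke prognosis, and how much of
that effect runs through blood pressure. The package covers the full
analysis cycle a summary-data MR study needs:

* **I/O and harmonization** — tab-delimited GWAS readers with configurable
  header dialects, row validation, and allele harmonization to a shared
  effect allele (sign flips, strand complements, unconditional exclusion
  of A/T and G/C palindromes).
* **Instrument selection** — genome-wide significance (*p* < 5×10⁻⁸),
  greedy LD clumping (*r*² < 0.001, 10,000 kb window) against a
  user-supplied LD table, outcome-association exclusion (*p* < 5×10⁻⁵),
  Steiger directionality filtering, and the per-SNP *F* < 10 weak
  instrument screen, with stage-by-stage attrition logging.
* **Estimators** — multiplicative random-effects IVW (primary), with
  β̂ = Σwⱼγⱼ Γⱼ / Σwⱼγⱼ² (wⱼ = 1/σ²_Γⱼ) and SE inflation √max(1, Q/(J−1));
  MR-Egger with its intercept test; the bootstrap weighted median;
  MR-PRESSO global/outlier/distortion tests with post-removal correction;
  Cochran's Q; Bonferroni thresholds across outcomes.
* **Multivariable MR** — random-effects IVW multiple regression for
  direct effects conditional on co-exposures, on a jointly re-clumped
  instrument union.
* **Two-step mediation** — β₁ (exposure→mediator, UVMR) × β₂
  (mediator→outcome given exposure, MVMR), delta-method inference, and
  proportion mediated = β₁β₂/β × 100%.
* **Meta-analysis** — fixed-effect (default) or DerSimonian–Laird pooling
  of per-consortium IVW estimates with Q and I².
* **Diagnostics** — binary-outcome power calculation and sample-overlap
  bias / type-I-error estimation; reverse-direction MR.
* **Synthetic data** — a fully seeded summary-statistic generator with
  known causal truth (pleiotropy laws, mediator pathways, LD blocks,
  sample overlap) so every stage is testable without consortium downloads.

## Worked example

A synthetic urate-scale exposure GWAS (n = 437,354) against a
FinnGen-scale any-stroke outcome (n = 311,635; 39,818 cases), true causal
OR 1.09 per SD:

```r
library(mrpipe)
sim <- simulate_two_sample(sim_truth(beta_causal = log(1.09),
                                     n_snp = 300, seed = 2024))
urate  <- study_meta("urate", "quantitative", n = 437354, sd_unit = 80.3)
stroke <- study_meta("finngen_as", "binary", n = 311635, n_cases = 39818)

inst <- select_instruments(sim$exposure, sim$outcome, urate, stroke)
attr(inst, "diagnostics")
#> Instruments: k = 176, R2 sum = 0.06533, overall F = 173.6, mean per-SNP F = 162.5

mr_fit(inst, methods = c("ivw_mre", "egger", "weighted_median", "presso"),
       seed = 1)
#> Univariable MR fit - 176 instruments
#> ivw_mre: beta = 0.0866 (SE 0.0210), OR = 1.090 [1.047, 1.136], p = 3.68e-05, nSNP = 176
#>   Cochran's Q = 169.577 (df 175, p = 0.601)
#> egger: beta = 0.0901 (SE 0.0523), OR = 1.094 [0.988, 1.213], p = 0.0852, nSNP = 176
#>   Cochran's Q = 169.572 (df 174, p = 0.581)
#>   Egger intercept = -0.0001 (SE 0.0016, p = 0.942)
#> weighted_median: beta = 0.0666 (SE 0.0308), OR = 1.069 [1.006, 1.135], p = 0.0305, nSNP = 176
#> ivw_post_presso: beta = 0.0866 (SE 0.0210), OR = 1.090 [1.047, 1.136], p = 3.68e-05, nSNP = 176
#>   Cochran's Q = 169.577 (df 175, p = 0.601)
```

Reading it: of 300 simulated SNPs, 176 survive the selection chain and
jointly explain 6.5% of exposure variance (well-powered instruments, mean
per-SNP F ≈ 162). The primary IVW estimate recovers the true OR 1.09 with
p = 3.7×10⁻⁵; Egger and the weighted median agree in direction and
magnitude; the Egger intercept is indistinguishable from zero (no
directional pleiotropy, as simulated); MR-PRESSO finds no outliers, so the
corrected estimate equals the primary one.

Whole studies (several outcomes and consortia, confounder-adjusted MVMR,
mediation, meta-analysis, reverse MR, TSV reports) run through
`study_config()` + `run_study()`; see `vignette("mr-methods")` for the
model, assumptions and design decisions.

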