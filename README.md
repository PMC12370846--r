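# mrmediate

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
SMR/HEIDI validation and two-step mediation MR.

## Who this is for

Genetic epidemiologists asking whether a molecular exposure (gene
expression, a protein, CpG methylation, an immune-cell trait) causally
influences a disease outcome, using only published summary statistics from
non-overlapping samples. The package implements the full three-stage screen
common in molecular-QTL studies of complex disease:

1. **Stage 1 — causal screen.** For each candidate exposure, select
   instrumental variables (IVs), harmonize them with the outcome GWAS, and
   estimate the causal effect with five estimators; validate candidates
   with the SMR test and the HEIDI test to rule out LD-driven (linkage)
   artifacts.
2. **Stage 2 — upstream mediation.** Does methylation act on the outcome
   *through* the gene? Two-step mediation MR with directional filtering.
3. **Stage 3 — downstream mediation.** Does the gene act *through* an
   intermediate trait (e.g. immune-cell phenotype)?

A synthetic summary-statistics generator with known truth (LD blocks,
instrument effects, pleiotropy, causal chains, shared-causal vs linkage
regions) makes every stage testable without downloading any external data.

## The statistics

**Instrument selection** (per exposure): keep SNPs with p < 5×10⁻⁸ and
MAF > 1%, LD-clump greedily (r² < 0.001 within a 10,000 kb window), and
drop weak instruments, where

R² = β² / (β² + N·SE²)  (the 2·EAF·(1−EAF) factors cancel),
F = R²(N − 1 − K) / (K(1 − R²)),  excluding F < 20.

**Estimators** on harmonized pairs (β̂ₓⱼ, β̂ᵧⱼ) with weights wⱼ = 1/se(β̂ᵧⱼ)²:

- Wald ratio β̂ⱼ = β̂ᵧⱼ/β̂ₓⱼ; IVW = weighted regression of β̂ᵧ on β̂ₓ through
  the origin (fixed, and multiplicative random effects inflating the SE by
  max(1, √(Q/(n−1))) — the headline);
- MR-Egger: weighted regression *with* intercept after orienting β̂ₓ ≥ 0; a
  nonzero intercept signals directional pleiotropy;
- weighted median (cumulative-weight interpolation at 50%) and
  weighted/simple mode (kernel density argmax), SEs by parametric bootstrap.

**Sensitivity**: Cochran's Q, leave-one-out IVW, and MR-PRESSO
(simulation-based residual test with outlier removal).

**SMR/HEIDI**: T_SMR = z²_QTL·z²_GWAS/(z²_QTL + z²_GWAS) ~ χ²₁; HEIDI tests
whether b_xy is constant across SNPs in LD with the top QTL
(shared-causal-variant null) via a seeded Monte Carlo reference
distribution. Decision rule: p_SMR < 0.05 **and** p_HEIDI > 0.05.

**Mediation**: total effect β (exposure→outcome), β₁ (exposure→mediator),
β₂ (mediator→outcome), each by univariable MR with its own instruments;
indirect = β₁β₂ (delta-method SE), proportion mediated = β₁β₂/β, direct =
β − β₁β₂. Reported only when all legs have IVW p < 0.05, IVW/Egger signs
agree, and sign(β₁β₂) = sign(β).

## Worked example

Simulate a causal chain (β₁ = 0.4, β₂ = 0.3, direct = 0.08, so total = 0.2
and true proportion mediated = 60%), then run the screen:

```r
library(mrmediate)
st <- simulate_study(sim_config(seed = 42, n_variants = 120, n_blocks = 40,
  within_block_r = 0.5, n_instruments = 15, n_med_instruments = 15,
  effect_sd = 0.08, n_exp = 1e5, n_med = 1e5, n_out = 1e5,
  beta1_true = 0.4, beta2_true = 0.3, direct_true = 0.08))

dat <- build_instruments(st$exposure, st$outcome, st$ld)
res <- mr_all(dat, n_boot = 200, seed = 1)
res[, c("method", "nsnp", "beta", "se", "pval", "odds_ratio")]
#>            method nsnp  beta     se     pval odds_ratio
#> 1         ivw_mre   11 0.204 0.0102 1.00e-88       1.23
#> 2       ivw_fixed   11 0.204 0.0102 1.00e-88       1.23
#> 3           egger   11 0.193 0.0242 2.28e-05       1.21
#> 4 weighted_median   11 0.208 0.0124 5.21e-63       1.23
#> 5   weighted_mode   11 0.204 0.0151 7.07e-42       1.23
#> 6     simple_mode   11 0.205 0.0177 4.63e-31       1.23

sensitivity_report(dat, n_sim = 500, seed = 1)
#> Cochran Q = 6.8916 (df 10), p = 0.7356
#> Egger intercept = 0.00110 (se 0.00226), p = 0.637
#> MR-PRESSO global p = 0.8443; outliers: none

two_step_mediation(st$exposure, st$mediator, st$outcome, st$ld,
                   config = list(n_boot = 0))
#> <mediation_result> exposure -> mediator -> outcome
#>   total 0.2038, indirect 0.1387 (68.08%), direct 0.0651, consistent: TRUE
```

Reading: 11 of the 15 planted instruments survive selection; every
estimator recovers the true total effect 0.2 (log-odds scale, OR ≈ 1.23
per SD of exposure); the diagnostics are quiet (no heterogeneity, no
intercept, no PRESSO outliers — correct, nothing was planted); and the
mediated proportion estimate 68% brackets the true 60% within sampling
error.

The full pipeline (all three stages from a JSON config, including a
simulated SMR/HEIDI region) runs with:

```r
run_pipeline("config.json", "out/")   # or: mr_cli(c("pipeline", "--config", "config.json"))
```

writing `stage1_mr.tsv`, `stage1_sensitivity.tsv`, `stage1_smr.tsv`,
`stage2_mediation.tsv`, `stage3_mediation.tsv`, `summary.txt`, and a
reproducibility `manifest.json`. Reruns with the same config and seed are
byte-identical.

## Not in scope

Downloading or re-analyzing real QTL/GWAS datasets, colocalization,
Steiger filtering, multivariable MR, proxy-SNP search, plotting.
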