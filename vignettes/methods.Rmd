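---
title: "Models, assumptions and design choices in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, assumptions and design choices in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The causal model

Two-sample summary-data MR treats each SNP $j$ as an instrument: its
association with the exposure ($\hat\beta_{xj}$, from one GWAS) and with
the outcome ($\hat\beta_{yj}$, from an independent GWAS) identify the
causal effect $\beta = \beta_{yj}/\beta_{xj}$ under the three instrumental
assumptions (relevance, independence from confounders, exclusion
restriction). All estimators here consume a harmonized table of
$(\hat\beta_{xj}, \hat\beta_{yj})$ pairs with their standard errors;
binary outcomes are handled on the log-odds scale and reported as odds
ratios.

The mediation extension decomposes a total effect $\beta$ into an indirect
path through a mediator, $\beta_1\beta_2$, and a direct remainder
$\beta - \beta_1\beta_2$, with each of the three coefficients estimated by
its own univariable MR leg. $\beta_2$ is deliberately **not** estimated by
multivariable MR adjusting for the exposure: the two-step univariable
design is the procedure this package models, and the choice is surfaced
here because it matters — when the exposure's instruments also reach
significance for the mediator, the direct path acts as horizontal
pleiotropy in the mediator→outcome leg. The significance and
weak-instrument filters remove most such SNPs in practice (see the
parameter-recovery tests), but users should know the bias direction:
contamination pulls $\hat\beta_2$ toward
$\beta_2 + \text{direct}/\beta_1$.

# Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `p_threshold` | 5e-8 | p-value | genome-wide significance; strict `<` |
| `maf_min` | 0.01 | frequency | rare-variant instability; strict `>` |
| `clump_r2` / `clump_kb` | 0.001 / 10000 | r², kb | near-independence of IVs |
| `f_min` | 20 | F statistic | weak-instrument bias; excluded when `F < 20`, so F = 20 is retained |
| `palindrome_window` | 0.08 | EAF half-width | A/T and C/G SNPs with EAF in [0.42, 0.58] are strand-unresolvable; 0.08 is the field-standard default (the procedure being modeled states frequency inference but no window) |
| `alpha` | 0.05 | p-value | every decision cascade uses uncorrected 0.05; an optional BH flag exists but is off by default, matching the modeled procedure |
| `n_boot` | 1000 | replicates | bootstrap SEs for median/mode; `0` skips them in large simulations |
| `phi` | 1 | multiplier | mode bandwidth knob |
| HEIDI `r2_min`,`r2_max`,`max_snps`,`min_snps`,`qtl_p_max` | 0.05, 0.9, 20, 3, 1.57e-3 | — | defaults of the reference SMR implementation; the QTL significance floor keeps the first-order delta-method covariance valid |

# Numerical choices

- **IVW.** The headline estimator is multiplicative random effects: the
  fixed-effect SE inflated by $\max(1, \sqrt{Q/(n-1)})$ — never deflated.
  A single instrument reduces exactly to the Wald ratio.
- **Wald-ratio SE** is first-order (`se_out/|beta_exp|`); the second-order
  correction is omitted.
- **MR-Egger** orients instruments so $\hat\beta_x \ge 0$, floors the
  residual scale at 1, and uses $t_{n-2}$ quantiles for CI and p — material
  at the small instrument counts where Egger is typically read.
- **Weighted median** interpolates the cumulative weight function at 0.5;
  ties in ratios are handled by ordered interpolation.
- **Mode estimators** evaluate a Gaussian kernel on a fixed 512-point grid
  (determinism; grid density is the precision knob), ties resolved to the
  lowest grid value. The bandwidth
  $h = \phi\,0.9\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,n^{-1/5}$ collapses
  to zero when quartiles tie but ratios differ (e.g. a 4-vs-1 cluster);
  the implementation then falls back to the sd term. All-identical ratios
  return that ratio with zero SE.
- **MR-PRESSO** uses the +1/(n+1)-smoothed global p (never exactly 0),
  Bonferroni-adjusted per-SNP outlier tests at $\alpha = 0.05$, and an
  informational distortion test. On data with one extreme outlier the
  contaminated leave-one-out fits can flag *every* SNP (the corrected
  estimate is then unavailable and a warning is logged); this is inherent
  to the residual-simulation design, which is implemented as specified
  rather than iterated.
- **HEIDI** propagates the covariance of $d_i = b_{xy}(i) - b_{xy}(\text{top})$
  to first order from the signed LD matrix and per-study SEs, then obtains
  the null distribution of $\sum_i d_i^2/\mathrm{var}(d_i)$ by seeded
  Monte Carlo (simpler to verify than a sum-of-dependent-$\chi^2$
  approximation; accuracy is controlled by `n_mc`). A non-PSD covariance
  gets one ridge of `1e-8` before failing with diagnostics.
- **Decomposition identity.** `direct` is *defined* as `total − indirect`,
  so `direct == total − indirect` holds bit-exactly; the re-summed form
  holds to machine rounding (floating point does not guarantee
  `(a−b)+b == a`). Proportions outside [0, 1] are reported as computed,
  with a warning — truncation would hide directionally inconsistent
  decompositions.
- **Harmonization order.** Palindromic (A/T, C/G) pairs are routed to
  frequency-based resolution *before* the identical-allele match: for such
  SNPs the allele letters carry no strand information, so an "identical"
  match is not evidence of shared orientation. Frequencies on the same
  side of 0.5 keep the pair, opposite sides flip it, missing or
  near-0.5 frequencies drop it.

# What the synthetic generator emulates — and what it does not

`simulate_study()` generates three traits (exposure, mediator, outcome)
over LD-blocked variants directly at the summary level: joint
(causal-scale) standardized effects are placed on instrument variants,
marginal effects are $R\gamma$ (LD propagation), and observed effects add
independent $N(0, 1/n)$ noise with $\mathrm{se} = 1/\sqrt{n}$. This
suffices for every estimator under test and is orders of magnitude faster
than genotype-level simulation. Stated simplifications:

- the binary outcome lives on a continuous liability/log-odds scale (no
  case-control ascertainment);
- sampling noise is independent across variants in `simulate_study()`
  (adequate because estimation always happens after clumping to
  near-independent instruments), while `simulate_smr_region()` draws
  $z \sim \mathrm{MVN}(R\lambda, R)$ — LD-correlated noise — because the
  HEIDI covariance model requires it;
- **directional pleiotropy is directional with respect to the
  exposure-increasing allele**: the mean shift is multiplied by the sign
  of the instrument's exposure effect. With random allele coding a raw
  mean shift is balanced by construction after Egger's orientation, which
  would make the scenario vacuous;
- no attempt is made to match real allele-frequency spectra, genomic
  inflation, or sample overlap.

Consequently, a green simulation test establishes the *arithmetic and
calibration* of the pipeline under its stated model — not robustness to
ascertainment, stratification, or overlapping samples.

The mediator carries its own instruments (`n_med_instruments`), without
which the mediator→outcome leg has no valid instruments at all (every
mediator-associated SNP would act through the exposure).

## Simulation worlds fixed for the acceptance tests

Where the acceptance criteria state only part of a generative world, the
remainder was fixed once, before measuring any rate, at values a
summary-data MR practitioner would call realistic, and not revisited:

- *Type-I / recovery*: 50 independent instruments, standardized effect
  spread 0.05, n = 50,000 (null) or 100,000 (recovery).
- *Egger power*: a 150-instrument polygenic exposure (intercept SE scales
  as $K^{-1/2}$, and pleiotropy detection at mean 0.02 is underpowered for
  oligogenic exposures — a known property of MR-Egger, not of this
  implementation), effect spread 0.08, n = 200,000.
- *Mediation recovery*: 20 exposure + 20 mediator-specific instruments,
  effect spread 0.06, n = 100,000 per trait, $\beta_1 = 0.4$,
  $\beta_2 = 0.3$, direct 0.08 (true proportion 60%).
- *SMR regions*: 50 variants, AR1 LD (decay 0.9/kb), causal z = 12, QTL
  n = 20,000, GWAS n = 400,000.

HEIDI Monte Carlo runs at `n_mc = 20000` in tests (default `1e5`) purely
for runtime; the resulting p-value resolution (5e-5) is far below every
decision threshold.

# Degenerate inputs and tie-breaks

- Clumping breaks p-value ties by rsid lexicographic order (determinism);
  SNPs absent from the LD reference are assumed independent with a logged
  warning (configurable to `drop`).
- `harmonize()` raises an error on an empty rsid intersection rather than
  returning an empty table silently.
- Zero exposure effects make the Wald ratio undefined: an explicit error.
- A zero coefficient anywhere in the directional filter fails the filter
  with a logged reason.
- Every stochastic operation takes an explicit seed, restores the caller's
  RNG state, and is byte-reproducible; derived child seeds stay below
  $2^{31}$.

# Known limitations

- No multivariable MR, colocalization, or Steiger filtering — the
  mediation legs inherit the univariable design's contamination behavior
  described above.
- MR-PRESSO is single-pass (no iterative outlier re-testing).
- The HEIDI covariance is first-order; candidates with weak QTL signal are
  excluded (`qtl_p_max`) precisely because the approximation degrades
  there.
- The pipeline's configuration format is JSON (nested sections per stage);
  no TOML parser is available in the supported dependency set.
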