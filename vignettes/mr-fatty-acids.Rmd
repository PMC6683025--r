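---
title: "Two-sample Mendelian randomization for plasma fatty acids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization for plasma fatty acids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mrfa)
library(dplyr)
```

## The question and the design

Whether circulating fatty acid levels influence the risk of atrial
fibrillation (AF) is hard to settle observationally: fatty acid intake is
measured with error, and both diet and AF share confounders (adiposity,
alcohol, lifestyle). Mendelian randomization (MR) sidesteps part of this by
using genetic variants as instrumental variables: alleles are fixed at
conception, so a SNP robustly associated with plasma linoleic acid levels
provides a randomized, lifelong "dose" of higher linoleic acid whose
association with AF can be read off GWAS summary statistics.

The design is *two-sample*: per-SNP effects on each fatty acid come from
plasma phospholipid fatty acid GWASs (beta in % of total plasma fatty acids
per effect allele), and per-SNP effects on AF come from a separate GWAS of
65,446 cases and 522,744 non-cases (beta as log odds ratio per allele). Only
the summary table of (beta, SE) pairs is needed; `fa_af_associations()`
ships this table: 22 rows, 16 distinct SNPs, 10 fatty acids, each instrument
genome-wide significant (p < 5e-8) for its exposure.

Three assumptions underpin every result: the instrument is associated with
the exposure (enforced by the p < 5e-8 threshold), independent of
confounders (not testable from summary data), and affects the outcome only
through the exposure (probed here by MR-Egger and leave-one-out analysis).

## Estimators

**Wald ratio.** For SNP $i$, the causal log OR per unit of exposure is
$\hat\beta_{Yi}/\hat\beta_{Xi}$. Because fatty acid concentrations live on
very different scales, each ratio is multiplied by the exposure's SD scale
factor (e.g. 2.69% of total fatty acids per SD of linoleic acid;
`fa_sd_scales()`), giving a log OR per 1 SD. The standard error is first
order, $\sigma_{Yi}/|\hat\beta_{Xi}|$ times the scale: the convention of
summary-data MR, which treats the exposure beta as measured without error.
This is what published confidence intervals in this literature use; the full
delta-method SE is available via `wald_ratios(..., se_method = "delta")` and
is always at least as large.

**IVW.** The fixed-effects inverse-variance weighted estimate pools ratios
$r_i$ with weights $w_i = 1/se_i^2$:
$\hat\beta = \sum w_i r_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$ —
numerically identical to a $1/\sigma_{Yi}^2$-weighted regression of outcome
betas on exposure betas through the origin (a tested invariant). Cochran's
$Q = \sum w_i (r_i - \hat\beta)^2$ on $k-1$ df measures heterogeneity and
$I^2 = \max(0, 100(Q - df)/Q)$ expresses it as a percentage. The
random-effects variant is *multiplicative*: the point estimate is unchanged
and the fixed SE is inflated by $\sqrt{\max(1, Q/(k-1))}$. The additive
(DerSimonian–Laird) model was deliberately not used: with the bundled
linoleic acid instruments only the multiplicative model keeps the published
point estimate (OR 0.97 under both effects models) and reproduces the
published random-effects p of 0.55.

**Weighted median.** Order the ratios, form cumulative-weight percentiles
$p_j = (S_j - w_j/2)/S_{total}$, and linearly interpolate the ratio at
$p = 0.5$ (clamped at the extreme ratios; ties in the sort are broken by
rsid so iteration order is fixed). The estimate is consistent as long as
valid instruments carry more than half the weight. Its SE comes from a
parametric bootstrap — redraw $r_i^\ast \sim N(r_i, se_i)$, weights held
fixed, and take the SD of the replicated medians — with 10,000 replicates by
default and a user seed, because the original analysis does not state its
bootstrap count or seed; the point estimate is deterministic either way.

**MR-Egger.** After orienting every SNP so its exposure beta is positive,
regress outcome betas on exposure betas with weights $1/\sigma_{Yi}^2$ and a
free intercept. The intercept estimates average directional pleiotropy (log
OR per allele, left unscaled); the slope, rescaled per SD, is a
pleiotropy-corrected causal estimate. Residual overdispersion is handled
multiplicatively with the scale floored at 1, $\phi = \max(1, RSS_w/(k-2))$.
Inference is normal (z) for both coefficients: with three linoleic acid
instruments this yields a directional-pleiotropy p of 0.20, matching the
published 0.22 up to input rounding, whereas a $t_{k-2}$ reference (1 df)
would give 0.42 — the z reference is what the Stata summary-MR tooling this
package parallels reports, so it is the package's choice.

**Leave-one-out.** `mr_leave_one_out()` repeats the fixed-effects IVW with
each instrument omitted, the standard probe for single-SNP dominance — here
relevant because rs10740118 (linoleic acid) and rs603424 (palmitoleic acid)
are strongly associated with AF in their own right.

**Significance tiers.** With ten fatty acids tested, p < 0.005 (0.05/10)
counts as significant and 0.005 ≤ p < 0.05 as suggestive. Both boundary
points are assigned to the weaker tier — the conservative reading of an
open-interval rule.

**Power.** For a binary outcome the IVW log OR per SD has approximate
variance $1/(N \cdot R^2 \cdot cf(1-cf))$, giving power
$\Phi(\sqrt{N R^2 cf(1-cf)}\,|\log OR| - z_{1-\alpha/2})$, the standard
non-centrality approximation for two-sample MR. `mr_power()` implements it;
it is symmetric in OR vs 1/OR and returns the no-information value
$\alpha/2$ at $R^2 = 0$. Where a published table reports a *range* of
variance explained per SNP, `instrument_r2()` reduces each interval with a
caller-chosen rule, midpoint by default, since published power statements
rarely say which bound was used — which is also why those statements are
checked qualitatively (e.g. >85% power for an OR of 0.9 with the
eicosapentaenoic acid instruments) rather than digit by digit.

## Harmonization and the input dialect

Multi-exposure SNPs can be reported on opposite effect alleles by different
exposure GWASs (rs174547 appears on C for alpha-linolenic and linoleic acid
but on T for docosapentaenoic and arachidonic acid). `harmonize_alleles()`
re-orients rows by swapping alleles and negating both betas; it is
involutive, and every estimator is invariant under re-orientation of any
subset of rows (both tested). No palindromic-SNP or strand-flip inference is
attempted — without allele frequencies any such guess risks silent sign
errors — so the bundled table is taken as already internally harmonized per
exposure, preserving the orientations as published.

Input is tab-separated with a fixed header (`assoc_columns()`); a YAML
column map adapts foreign headers. Two parsing choices are worth noting:

* p-values are carried as printed text plus a derived log10 column, because
  exposure p-values as small as 3.3e-971 underflow doubles;
* variance-explained entries may be ranges ("0.2-0.7", en dashes accepted)
  and are stored as `[lo, hi]` intervals.

Validation is strict (positive SEs, A/C/G/T alleles, chromosome 1–22,
p in (0,1], no duplicate (exposure, SNP) pairs) with row-indexed messages.
A softer diagnostic, `check_p_consistency()`, checks each printed p against
the printed |beta|/SE as a factor-of-two band on the implied z — a band that
wide is necessary because one-significant-figure SEs leave the true z
uncertain by more than that (for arachidonic acid's rs174547 the printed
p implies z ≈ 67 while the rounded beta/SE gives 84).

## The synthetic-data generator

`simulate_mr_data()` generates summary tables with known ground truth:
exposure betas drawn uniformly from a positive interval (uniform rather than
normal so no beta sits near zero and degenerates a ratio), outcome betas as
`beta_causal * beta_exp + alpha + N(0, se_outcome)`, with per-SNP pleiotropy
`alpha` of zero, random sign, or constant sign, optionally restricted to a
fraction of instruments. Exposure betas are reported without error by
default, mirroring the first-order Wald convention; `exposure_noise = TRUE`
adds measurement error for exercising the delta-method SE. Identical seeds
give byte-identical tables and the caller's RNG stream is never disturbed.

What it emulates: the structure of a real instrument table (magnitudes,
SEs, dialect) under the textbook MR assumptions. What it does not: linkage
disequilibrium between instruments, correlated (InSIDE-violating)
pleiotropy, winner's-curse in instrument selection, or sample overlap
between the two GWASs. Passing parameter-recovery tests therefore
demonstrates correctness of the estimators under the assumed model, not
robustness to those real-data pathologies.

Simulation-based checks in the test suite (sizes chosen to give stable
binomial noise at negligible runtime):

* 95% CI coverage of the fixed-effects IVW over 500 seeded replicates at
  k = 20 with the generator's default noise is required to land in 93–97%
  (binomial SD at 500 replicates is about 1 point);
* with 40% of 20 instruments given large constant-sign pleiotropy, the
  weighted median stays within 3 bootstrap SEs of truth while IVW is tens of
  SEs off. The test first asserts the estimator's own validity condition —
  valid instruments holding >50% of total weight — because when a random
  contaminated subset happens to capture the weight majority the weighted
  median is *expected* to break, which is a property of the estimator, not
  a bug;
* at k = 50, IVW recovers the causal slope within 3 SEs without pleiotropy,
  and under directional pleiotropy MR-Egger recovers both slope and
  intercept within 3 SEs while IVW is biased; on noise-free linear data
  Egger recovery is exact to machine precision;
* IVW and weighted-median outputs match independent brute-force evaluations
  of their defining formulas on 1,000 random small problems, and metafor's
  fixed-effect meta-analysis cross-checks IVW on the bundled data.

## Numerical and rendering choices

Estimates are kept at full precision inside `mr_analysis` objects and
rounded only in `render_report()` (OR and CI to two decimals, p to two
significant figures, the presentation convention of this literature).
Confidence intervals use the normal 1.96 critical value. Degenerate inputs
are handled explicitly: a zero exposure beta is an undefined-ratio error;
zero-SE (exact) instruments are pooled only if they agree; random-effects
IVW with one instrument falls back to fixed effects with a note; a
weighted-median bootstrap below 100 replicates is flagged rather than
refused.

## Worked analysis

```{r analysis}
fit <- mr_analyze(loo = c("linoleic acid", "palmitoleic acid"),
                  n_boot = 10000, seed = 1)
glance(fit)
render_report(fit) |> filter(exposure == "linoleic acid")
```

Linoleic acid is the one suggestive signal (fixed-effects IVW OR 0.96, 95%
CI 0.94–0.99, p 0.0075), and the sensitivity battery shows why it should
not be over-read: heterogeneity is extreme (I² = 95%), so the
multiplicative random-effects CI spans 1 (p 0.55); the weighted median is
attenuated (OR 0.98); and omitting the AF-associated rs10740118 moves the
estimate to 0.98 with CI spanning 1. The same logic applies to palmitoleic
acid once rs603424 is dropped (OR 0.94, p 0.068).

```{r forest, fig.width = 6, fig.height = 4}
autoplot(fit)
```

## Limitations

Pooled estimates inherit whatever bias the source GWASs carry (sample
overlap between exposure and outcome GWASs, population structure). With two
or fewer instruments the sensitivity battery is undefined, so four of the
ten fatty acids rest on the fixed-effects IVW alone. The bundled table
stores betas and SEs as published (2–3 significant digits), which caps
agreement with the published odds ratios at about ±0.01 — the tolerance the
package's own end-to-end tests assert. External phenome-scan lookups for
instrument pleiotropy are out of scope; the MR-Egger intercept is the
in-package pleiotropy probe.
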