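---
title: "Models and methods behind hemegwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemegwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemegwas)
```

hemegwas reimplements, at desk scale, the statistical machinery used by
large haematological genome-wide association studies: phenotype adjustment
for instrument and environmental effects, per-study association testing
pooled by inverse-variance meta-analysis under double genomic control, a
geometric cross-study heterogeneity filter, block-wise stepwise conditional
selection with LD clumping, and multivariable Mendelian randomization. This
vignette explains the models, the tunable parameters, the synthetic world
the generators emulate, and the numerical choices that were genuinely open.

## Adjustment scales and the index registry

Full-blood-count indices split into positively supported variables (counts,
concentrations, volumes), modelled on the **log** scale, and
proportion-supported variables (percentages of a parent count or of blood
volume), modelled on the **logit** scale (`to_adjustment_scale()`). All
covariate modelling happens on these *adjustment scales*, where technical
and biological effects are closer to additive and inverse transforms always
return valid physical values.

`blood_index_registry()` fixes the canonical *measured* subset — the five
white-cell counts, RBC#, MCV, HGB, RDW, RET%, PLT#, MPV, PDW — from which
every *derived* index (HCT, MCH, MCHC, PCT, RET#, WBC#, the percentages, …)
is deterministically recomputed by `derive_indices()` using the clinical
identities (e.g. HCT = RBC# × MCV / 10, MCH = 10 × HGB / RBC#). The original
instrument documentation of measured-versus-derived sets per analyzer model
is not available to this package, so one canonical registry is used for both
simulated analyzer families; this is a synthetic choice. Platelet and red
cell distribution widths are carried as measured log-scale indices; the
detour through volume-distribution standard deviations that a real analyzer
performs is not emulated, since analyzer-internal distributions are not
simulated.

## The synthetic cohort: a stated world

`simulate_genotypes()` draws, per haplotype copy and LD block, a latent
standard normal factor shared by the block's variants with loading
`sqrt(block_rho)`; allele indicators are the latent values thresholded at the
allele-frequency quantile. Margins are therefore exactly Bernoulli(MAF), and
within-block dosage correlation is controlled by one number. This is the
simplest controllable LD model; it does not emulate coalescent haplotype
structure or imputation-panel LD, so tests of clumping and conditional
analysis exercise the algorithms, not population-genetic realism. Note the
realized dosage r² lies below the latent `block_rho` (tetrachoric
attenuation); `block_rho >= 0.95` is needed to exceed the 0.8 clumping
threshold for common variants.

`simulate_cohort()` composes, per measured index on its adjustment scale:

* baseline + `sd_a` × (genetic + polygenic + residual biology), where planted
  per-allele effects are in phenotype-SD units so a variant contributes
  2p(1−p)β² of biological variance (validated at construction);
* covariate effects (`covariate_effects()`): sex/menopause offsets (largest
  on HGB and RBC#, as observed clinically), smooth age trends, a log-BMI
  effect, pack-years and alcohol effects, and a menstrual-cycle sinusoid for
  premenopausal women;
* technical artifacts (`technical_artifacts()`): per-instrument linear drift
  with step discontinuities at calibration events, a within-day sinusoid, a
  linear venipuncture-delay effect, weekday offsets, a seasonal sinusoid, and
  aberrant (day, instrument) shifts;
* white technical noise.

Recruitment spans a two-year window with day batching (about 60 samples per
active day) so day × instrument cells hold enough points for aberrant-day
statistics. Venipuncture-to-acquisition delays are gamma distributed
(mean ≈ 21 h, about 2–3% beyond 36 h), matching overnight-transport
logistics. Raw-index noise magnitudes per analyzer are not published
anywhere we can draw on, so `sd_a` per index (roughly the between-person
coefficient of variation) and the default artifact amplitudes (a few
hundredths on the log scale; technical shares of a few percent, up to tens
of percent under strong drift) are labelled synthetic choices. Every planted
component is retained in `$truth`, which is what makes artifact-removal and
effect-recovery tests possible; a green test establishes that the pipeline
removes *this* kind of structure, not that it would remove every artifact a
real analyzer produces.

## Two-stage phenotype adjustment

Stage 1 (`technical_adjust()`) fits, on the central data only (within 3.5
scaled MADs of the median), a penalized-spline additive model with
per-instrument drift P-splines, a per-instrument bivariate thin-plate smooth
in time-of-day × venipuncture delay, a cyclic seasonal spline, and weekday
and instrument offsets. Residuals (plus the grand mean, so location is
preserved and values remain physical) adjust all data. Day × instrument
cells are then scored by `aberrant_day_scores()`,

z = √n · |mean(cell) − median(all)| / MAD(all),

with cells of fewer than 10 points or z > 8 excluded, and the model is
refitted without them. The √n (standard-error) scaling is used by default
because the alternative reading (a leading factor of n) makes the score grow
linearly with batch size for a fixed shift; `scale = "n"` is available.
The MAD in this denominator is the raw median absolute deviation; the
3.5/4.5 thresholds expressed in "deviations" elsewhere use the 1.4826
SD-consistent scaling (configurable everywhere).

Two numerical choices differ from a literal first reading and are deliberate:

* **Penalty selection is REML**, not GCV. With desk-scale cohorts GCV
  visibly overfits the no-artifact limit (the raw/adjusted correlation drops
  below 0.99 even with nothing to remove); REML keeps the no-op limit clean.
* **Each instrument gets its own smoothing parameter** for its drift smooth.
  A shared penalty lets one machine's gentle drift over-smooth another
  machine's calibration discontinuity.

Knot defaults follow the full-scale design (50 drift / 30 bivariate / 30
seasonal) and are capped by the available support; the desk-scale pipeline
configuration reduces them (12/10/8) purely for runtime — the adjustment is
qualitative at 20–40 active days either way. Instruments with fewer than
three distinct days of data lose their drift term (it degenerates to a
constant absorbed by the instrument offset) with a warning.

Derived indices are recomputed from adjusted measured indices *between* the
stages — the two-stage contract. Stage 2 (`environmental_adjust()`) then
adjusts measured and derived indices alike for age (smooth, by menopause
category), log-height × log-weight (bivariate smooth, by menopause
category), pack-years, and categorical smoking/drinking variables; "B"-style
studies add days-since-last-period (restricted to premenopausal women via a
numeric indicator interaction, so male records are provably untouched) and
previous-day alcohol quantity. Missing covariate values are mean-imputed
with a missingness dummy; an all-missing covariate degrades to the dummy
alone.

Outlier removal then proceeds: raw-versus-adjusted differences beyond 3.5
scaled MADs; univariate values beyond 4.5 scaled MADs; and per index group,
the sum of squares of the leading *d* **whitened** PC scores compared to the
upper 10⁻⁷ tail of χ²_d, with strict inequality at the boundary. Whitening
(dividing each PC score by its standard deviation) is required for the
χ² reference to apply; *d* is the number of independent analyzer
measurements behind the group, computed from the registry's parent relation
when only part of a group is simulated (derived indices make the naive
covariance rank-deficient — log HCT is exactly log RBC# + log MCV — and
whitening near-null components would explode). Finally values are
quantile-inverse-normal transformed within analyzer × sex/menopause strata
with scores Φ⁻¹((rank − 0.5)/n) and average ranks for ties; the (rank −
0.5)/n offset and tie rule are common conventions, fixed here for
determinism.

## Association, meta-analysis and heterogeneity

`run_gwas()` is deliberately ordinary least squares with covariates
(principal components, centre dummies) projected out by QR — synthetic
cohorts contain no relatedness, so a mixed model would add cost without
changing the estimand; p-values are normal Wald, matching the summary-stats
contract. `ivw_meta()` harmonizes effect alleles (flips, strand flips;
strand-ambiguous A/T–C/G variants above MAF 0.4 are dropped with a warning),
applies the inclusion filter (per-study MAF > 0.01%, info > 0.4, complete
estimates, strict inequalities), then pools by inverse variance. Genomic
control is *double*: per-study standard errors are inflated by
√max(λ, 1) before pooling, and the pooled statistics are corrected again
with their own λ, where λ is the median association χ² divided by 0.4549.
λ is floored at 1 (no deflation); the flooring convention is standard
practice where the original description is silent.

The heterogeneity statistic replaces Cochran's Q: the three-study effect
vector is tolerated if it lies in the double cone whose faces are normal to
(1, −¼, −¼) and its permutations — directionally concordant effects with
bounded coordinate ratios. Otherwise `het_score()` returns the
SE-standardized distance to the nearest point of the region (the radius of
the smallest confidence ellipsoid touching it), computed exactly by
enumerating the cone's faces and edges in SE-whitened coordinates; the
between-study covariance is taken diagonal (the confidence surface of
independent per-study estimators). Scores above 5.2 are filtered. The test
suite cross-checks the closed form against an independent Dykstra
alternating-projection oracle on 10⁴ random inputs to 10⁻⁶.

## Conditional selection, clumping, variance accounting

Genome-wide significant variants (α = 8.31 × 10⁻⁹) are partitioned into
blocks split exactly at 10 Mb gaps (`partition_blocks()`), and each block is
searched by bidirectional stepwise regression on pooled individual-level
data with study dummies (`stepwise_select()`): add the candidate with the
smallest residual-association p below α, then prune members whose removal p
exceeds α, largest first; a cross-block rerun from the saturated model over
the union enforces mutual conditional significance. The add-step p is the
*partial* (Frisch–Waugh) regression of current residuals on the candidate
residualized against the current model — equivalent to the joint-model add
test. The alternative reading (raw candidate) loses power under LD in a way
the procedure's published behaviour contradicts. Ties are broken by genomic
position for determinism; perfectly collinear candidates are skipped and
logged. At desk sample sizes the genome-wide α is attainable only by large
planted effects, so tests and examples may relax α (a configurable
parameter); the default stays 8.31 × 10⁻⁹.

`clump()` forms connected components of the r² > 0.8 graph (squared Pearson
correlation of dosages against the pooled synthetic reference) across all
(variant, trait) associations and marks as sentinel the variant with the
smallest univariable p across member associations. Variance explained
(`variance_explained_by_group()`) reports the unadjusted phenotypic R² of
the full selected set and both group-only and sequential shares, because an
attribution rule for correlated annotation groups is not well defined —
shares are flagged non-additive when they disagree with the total.
`gc_h2_adjustment_factor()` implements the algebraic correction
λ_meta · Σnᵢλᵢ / Σnᵢλᵢ² that undoes genomic-control attenuation of
summary-statistic heritability estimates.

## Multivariable Mendelian randomization

With instrument effects Bx (variants × indices) and disease effects by,
`mvmr_ivw()` solves the weighted regression through the origin with weights
1/sey² — only the disease-side standard errors enter, the first-order
convention of the IVW estimator — and reports fixed-effect standard errors
from (BxᵀWBx)⁻¹; a multiplicative overdispersion scaling (floored at 1) is
exposed as an option but off by default. `mvmr_egger()` realigns instruments
so their effect on a chosen index is non-negative (disease and other index
effects flip along), then frees the intercept, which estimates unbalanced
directional pleiotropy with respect to that index; the fit is invariant to
sign flips of input rows, and the procedure runs once per index.
`prune_indices()` reduces a correlated index panel greedily in a declared
priority order (the thirteen classic sentinel indices first), dropping an
index only when its r² with an already-retained one exceeds 0.8 — tie
handling in the original selection is unstated, so priority order plus the
strict threshold makes the rule deterministic. Sensitivity filters remove
the MHC region (chr6:20–40 Mb, inclusive), flagged known-disease loci, or
instruments whose clumps associate with all five index classes.

## Pipeline, reproducibility, limitations

`run_pipeline()` chains the stages on a validated configuration, writes
every artifact as TSV with a checksummed manifest, and derives per-stage
seeds from the master seed, so reruns are bit-identical. The MR stage
constructs its exposure matrix from the discovered sentinels' meta-analytic
effects and simulates a disease outcome under configured causal effects —
it is plumbing for end-to-end exercise, not an epidemiological claim.

Known limitations: no relatedness or mixed models; no X chromosome; no
imputation-panel LD; single-chromosome variant layout by default; the MR
stage's disease outcome is synthetic; and desk-scale sample sizes mean
genome-wide discovery operates on planted effects far larger than those the
full-scale design can detect. Every empirical number quoted in the package
documentation is produced by the test suite or the acceptance script.
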