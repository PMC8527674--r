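---
title: "Models and design of the adiposity-methylation analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the adiposity-methylation analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
design choices made where the methodology left the design open.

## 1. Quality control of intensity data

Raw input is per-probe, per-sample methylated (M) and unmethylated (U)
fluorescence, beadcounts, and typed control probes including negative
controls.

**Background correction.** For each sample, the 5th percentile *b* of the
negative-control signal is subtracted from M, U and the control probes,
flooring at zero. Illumina's channel-aware correction needs per-channel
data, which this data model does not carry; subtracting a per-sample
background quantile preserves the method's intent (removing dye
background) with the information available. Correcting the controls too
makes the operation nearly idempotent: the corrected negatives' 5th
percentile is (close to) zero.

**Detection P.** The probability that total signal M + U would arise
from background is the upper tail of Normal(mean, sd) of the per-sample
negative controls. The published threshold 1×10⁻¹⁶ is applied after
background correction (the method description does not fix the order; we
state ours). A zero background SD degenerates to a 0/1 step function and
warns.

**Filters.** Samples: probe missingness (> 5% of autosomal probes with
detection P > 1×10⁻¹⁶), then a sex check: log2 median(chrY) − log2
median(chrX) total intensity, male if > −2. The orientation (Y minus X)
is chosen so that males, who have real chrY signal, sit near 0 > −2;
missingness takes precedence when both fail, so each exclusion carries
one primary reason. Sex-chromosome probes are excluded from the
missingness denominator because chrY probes sit at background in females
by biology, not by sample quality — on a real 850k array they are a
negligible fraction, in a small synthetic array they are not. Probes:
detection-P failure in > 5% of samples, beadcount < 3 in > 5% of
samples, and all sex-chromosome probes; both "> 5%" rules are strict
inequalities. Cross-reactive and SNP-affected probes are flagged but
retained, and the flags travel with downstream outputs.

**Quantile normalization** operates on the beta scale,
beta = M/(M + U + 100), within user-defined groups (by default the
analysis strata per visit, mirroring the per-laboratory, per-ethnicity
design). Each sample's values are mapped onto the mean of the group's
sorted columns. Two tie policies exist: averaging over tied ranks keeps
equal inputs equal, while position-breaking ("first") makes every
sample's sorted vector exactly the group reference. The QC chain uses
"first" because background-floored signals produce exact zeros, and we
want the normalized groups to share their sorted columns exactly; the
exported function defaults to "average".

## 2. Covariates

**Control-probe PCs.** PCA of the column-scaled control matrix; the
first five scores (k = 5 by default) serve as batch covariates.
Component signs are fixed by making each component's largest-magnitude
loading positive, so results are machine-independent.

**Cell-type deconvolution.** Each sample's beta vector over the
reference probes is projected onto reference profiles R by non-negative
least squares, min‖β − Rp‖² s.t. p ≥ 0 (solved by Lawson–Hanson NNLS).
No sum-to-one constraint is imposed — the constrained-projection
formulation leaves the row sum free, and it is reported; an optional
renormalization divides by it. Any probe-compatible reference TSV can be
supplied; the synthetic generator ships its own six-type reference.

## 3. Stratified EWAS and meta-analysis

Per stratum and per CpG, ordinary least squares with the **trait as the
dependent variable**: trait ~ beta + age + sex + smoking + 6 cell
fractions + 5 control PCs, untransformed trait and beta for
interpretability (effects are trait units per unit beta). The
implementation residualizes trait and beta on the covariates
(Frisch–Waugh) and is tested to equal the per-probe `lm` fit to 1×10⁻⁸.
Constant probes yield NA with a recorded reason; collinear or constant
covariates are dropped with a warning (stratum-constant covariates such
as smoking in an all-never-smoker stratum are dropped silently when
assembling stratum data).

Stratum estimates are pooled by inverse-variance fixed-effect
meta-analysis (weights 1/SE²; P from the normal approximation, which is
what standard fixed-effect software reports), with Cochran's Q on k − 1
df for heterogeneity. The hierarchical scheme pools the two Chinese
strata first, then all four base strata; the two-stage pooled effect and
SE are algebraically identical to pooling the Chinese-stage result with
the remaining strata, and heterogeneity is computed over the four base
strata — this choice reproduces the published heterogeneity P-values,
whereas treating the Chinese-stage pool as a single stratum does not.
Discovery is BH-FDR < 0.05 per trait and stage.

Surrounding analyses: loci are formed by clumping significant CpGs
within 500 kb (the methodology never defines "locus"; we reuse the
novelty window, configurable); conditional analysis refits the
non-sentinel CpG jointly with the sentinel, pools, and calls a secondary
signal below a Bonferroni threshold 0.05/n_loci (none is stated in the
source; Bonferroni is the conservative default). CpG–expression pairs
use a closed ≤ 1 Mb window from CpG position to transcript start (start,
not midpoint — a decision), expression prepared by low-expression
filtering against a control-derived threshold, quantile normalization,
residualization on sex, batch and five expression PCs (a surrogate for
latent-factor methods such as PEER, which is out of scope; the count is
configurable), then rank-inverse-normal transformation with the Blom
offset 3/8. Biomarker values below detection limits are imputed at 0.9 ×
the minimum observed value of that biomarker. Novelty requires strictly
more than 500 kb to the nearest same-trait catalog entry on the same
chromosome. Direction consistency against external tables uses the exact
two-sided binomial test against 0.5, with zero effects excluded from
both counts.

## 4. Cross-lagged panel models

For standardized X, Y at two waves the saturated path model is

    Y_f = a_y Y_b + c_xy X_b + e1
    X_f = a_x X_b + c_yx Y_b + e2

plus the baseline correlation and cor(e1, e2). One of the source's three
printed structural equations repeats the same left-hand side twice — an
apparent typo — and is implemented as the standard second regression
above. For the saturated model, maximum-likelihood path estimates equal
the OLS multiple-regression coefficients (the test suite checks this
against an independent covariance-moment solver), the model chi-square
is zero, and the comparative fit index is exactly 1; CFI is still
reported to mirror conventional output. Path SEs are OLS SEs
(`df_adjust = TRUE`; the ML variant divides by n instead of n − p).
Inputs must be residualized and Z-standardized: BMI on age and sex;
methylation additionally on cell fractions and control PCs; in the
MRS–biomarker models, biomarkers on age, sex and batch, the MRS on age,
sex, cells and control PCs, and the follow-up wave additionally on
follow-up time. Non-standardized input (mean or SD off by more than
1×10⁻⁶) is an error rather than a silent renormalization.

## 5. Mendelian randomization

Forward: for each significant CpG, every non-monomorphic SNP within a
closed 1 Mb window is regressed (beta ~ dosage + discovery covariates)
per stratum and pooled; the smallest-P SNP is the instrument, excluded
if pooled P > 0.05, if it lies within 50 bp of the CpG (the synthetic
proxy for the probe-binding sequence), or if it associates with BMI at
P < 0.05 conditional on the CpG. The causal estimate is the Wald ratio
with the delta-method SE

    SE = sqrt( (eff_BMI-SNP² / eff_CpG-SNP²) ·
               (SE_BMI-SNP²/eff_BMI-SNP² + SE_CpG-SNP²/eff_CpG-SNP²) )

The source prints the predicted effect in squared form, which cannot
carry sign; the signed ratio (square-root magnitude) is implemented
because the predicted-versus-observed correlation requires signed
values. The delta approximation is accurate for strong instruments — the
tests verify the SE within 2% of a Monte-Carlo oracle at |eff/SE| ≥ 10
on both axes; near-weak instruments make the ratio distribution
heavy-tailed and no first-order SE is reliable there. External summary
statistics are harmonized to the dosage-counted allele (flipping betas
when the stated effect allele is the other allele); harmonization is an
involution. Causal calls use the Bonferroni-style threshold 5×10⁻⁴.

Backward: a polygenic risk score (weighted dosage sum, missing dosages
mean-imputed per SNP) instruments BMI; predicted BMI→CpG effects are
eff(CpG~PRS)/eff(BMI~PRS) with the mirrored delta SE, compared with the
observed regression of methylation on BMI plus discovery covariates —
the only dimensionally consistent reading of the published comparison.
A PRS–BMI association P > 0.05 flags every estimate as weak-instrument.
The methylation risk score is the weighted beta sum over discovery CpGs
(weights = trans-ethnic meta effects by default, since the source does
not state its weights; an unweighted sum is available), Z-standardized,
and errors when fewer than half the weighted CpGs are present.

## 6. The synthetic cohort generator

`simulate_study()` draws four strata (a longitudinal Chinese set
and three multi-omic strata: Chinese, Malay, Indian; 102/86/98 per
stratum in the emulated design, a single `n_per_stratum` here), two
visits separated by Normal(6.8, 1.39) years truncated at 1. Per probe,
methylation is logistic in a baseline logit plus cell, batch, mQTL and
BMI terms; the configured beta-scale effect sizes are divided by the
local logistic derivative so they remain interpretable in beta units.
Cell proportions are Dirichlet on a six-type simplex (concentration 30
around realistic blood fractions); batch scores drive both the
non-negative control probes and the analytic probes; intensities are
M = β·T and U = (1 − β)·T with log-normal total signal T (mean 5000) and
shifted-Poisson beadcounts; measurement noise (`noise_sd`, default 0.02
beta units) is added before the intensity split.

**Cross-lagged structure.** BMI residuals follow a stationary AR(1)
between waves (tracking 0.8) and per-probe biological noise follows its
own AR(1) (0.3, SD 0.01); causal probes respond *contemporaneously* to
BMI (`effect_scale_bmi_to_cpg`, default 0.002 beta per kg/m²). This
yields, in closed form, a forward cross-lagged path k(a_BMI − a_probe)
(k the cross-sectional partial correlation) and an exactly zero reverse
path — the cleanest possible ground truth for direction-recovery tests.
Reverse causation (CpG→BMI, at the mQTL probes so instruments exist) is
available via `effect_scale_cpg_to_bmi` and off by default.

**Recorded truth.** The per-probe "implied" EWAS effect is the estimand
of the analysis model: the partial linear regression slope of the trait
residual on the realized beta values given the true confounders entered
linearly. Defining truth this way (rather than as the generative
coefficient) makes the recovery criterion well-posed under the logistic
nonlinearity and the +100 beta offset, both of which attenuate the
generative coefficient slightly.

**Corruption.** `n_corrupt_background` samples get high background
(8% of probes replaced by background-level signal, raised negative
controls) and fail the missingness filter; `n_sex_swap` samples get
their reported sex flipped and fail the sex check. Injection is explicit
in the config so QC tests have a deterministic surface.

**What is not emulated:** IDAT/channel structure (so dye-bias and Noob
corrections are out of scope), linkage disequilibrium beyond single
cis-SNPs, probe-type (I/II) chemistry differences, genomic clustering of
CpGs, and realistic metabolite covariance. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
generative structure, not robustness to artefacts the generator does not
produce.

## 7. Problem sizes and numerical choices

The acceptance computations use problem sizes chosen to make the checks
sharp but cheap: type-I error on 10,000 null probes in a cohort of 4×107
samples (the emulated study's post-QC size) over 20 seeds;
effect-recovery at 500 per stratum and 2,000 probes over 20 seeds
(2,000 probes keep quantile-normalization rank distortion small);
cross-lagged direction recovery at 1,000 two-wave samples and 100 causal
probes, with path recovery at n = 100,000; Monte-Carlo oracles at 10⁶
draws. Deconvolution uses the solver's native tolerance (~1e−8 on exact
mixtures). Degenerate inputs error loudly rather than silently: empty
post-QC probe sets, zero residual variance in standardization,
zero-weight risk scores, singular references.

Significance in the cross-lagged scan is declared at P_FDR < 0.05 across
the scanned CpGs (both cross paths adjusted separately), matching how
the source reports its forward-path count.

## 8. Known limitations

Fixed-effect meta-analysis only (heterogeneity is tested, not modelled);
one instrument per CpG (no multi-SNP MR estimators); the saturated
two-wave CLPM only (no latent-variable or >2-wave models); expression
latent factors approximated by PCs; and the generator's independence
assumptions listed above. The published cohort-dependent headline counts
(e.g. numbers of significant CpGs) depend on restricted data and are
deliberately covered by calibration/recovery properties instead of
numeric reproduction; the meta-analysis stage is the quantitatively
reproduced surface, from the printed per-stratum inputs.
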