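# adipomethyl

Epigenome-wide association (EWAS) and causal inference for adiposity
traits in multi-ethnic, two-wave cohorts, with a synthetic cohort
generator so that every stage is testable without restricted data.

The package is aimed at epigenetic epidemiologists who analyse Illumina
methylation-array data against body-mass index (BMI, kg/m²) and waist
circumference (WC, cm). It covers the full chain a study of this design
needs:

1. **Intensity-level QC and normalization** — background correction by the
   5th percentile of negative-control signal; detection P-values as the
   normal upper tail of total signal against the per-sample background;
   sample filters (probe missingness at detection P > 1×10⁻¹⁶ in > 5% of
   probes; a chrY-vs-chrX log2-median-intensity sex check with male
   declared above −2) and probe filters (detection P, beadcount < 3 in
   > 5% of samples, sex chromosomes removed; cross-reactive and
   SNP-affected probes flagged, not dropped); within-group quantile
   normalization of beta = M/(M + U + 100).
2. **Covariate inference** — principal components of the array control
   probes as batch surrogates, and reference-based blood cell-type
   deconvolution (non-negative constrained projection onto six reference
   profiles: granulocytes, monocytes, B, CD4⁺ T, CD8⁺ T, NK).
3. **Stratified EWAS and meta-analysis** — per-stratum OLS of the
   untransformed trait on beta plus age, sex, smoking, six cell fractions
   and five control-probe PCs; inverse-variance fixed-effect pooling
   (effect = Σwᵢeᵢ/Σwᵢ, SE = (Σwᵢ)^(−1/2), wᵢ = 1/SEᵢ²) with Cochran's Q
   heterogeneity on k−1 df, in a hierarchical scheme (Chinese strata
   first, then trans-ethnic); BH-FDR discovery at P_FDR < 0.05;
   conditional analysis of multi-CpG loci; novelty annotation against
   user-supplied catalogs (novel requires > 500 kb distance); cis
   expression association within 1 Mb; direction-consistency binomial
   tests against external studies.
4. **Temporal inference** — two-wave cross-lagged panel models (CLPM) on
   residualized, Z-standardized variables, where the cross path from
   baseline X to follow-up Y indexes temporal precedence; and
   bidirectional Mendelian randomization: forward with one cis-mQTL
   instrument per CpG and the Wald ratio
   eff(CpG→BMI) = eff(BMI–SNP)/eff(CpG–SNP) with delta-method SE,
   backward with a polygenic risk score instrumenting BMI; methylation
   risk scores (MRS) feeding biomarker CLPMs.

The synthetic generator (`simulate_study()`) emulates the target design:
four analysis strata (a longitudinal Chinese set plus Chinese, Malay and
Indian multi-omic strata), two visits ~6.8 years apart, cell-mixture and
batch confounding visible through control probes, cis-mQTL effects,
contemporaneous BMI→CpG effects with autoregressive BMI tracking (which
induces a forward-only cross-lagged structure), biomarkers downstream of
the methylation risk score, and deliberately corrupted samples to
exercise the QC filters. Truth tables record every injected effect.

## Worked example

```r
library(adipomethyl)

cfg <- list(synth = synth_config(n_per_stratum = 80, n_probes = 400,
                                 frac_causal_bmi_to_cpg = 0.1,
                                 frac_mqtl = 0.1, seed = 2))
res <- run_pipeline(cfg, out_dir = "demo_run")
readLines("demo_run/pipeline.log")
```

```
simulate: seed 2
qc baseline: 320 samples, 400 probes retained
qc followup: 320 samples, 400 probes retained
ewas bmi: 41 FDR-significant CpGs
ewas wc: 28 FDR-significant CpGs
conditional: 0 loci tested, 0 secondary
clpm: 1/41 significant forward paths (FDR)
forward MR: 0 instruments, 0 causal calls, r = NA
backward MR: r = 0.777 (weak instrument: FALSE)
scores: MRS->IL-6 path p = 0.0123
pipeline complete
```

Reading the log: all 320 samples per visit pass QC (no corruption was
injected); of 400 probes, the EWAS recovers 41 BMI-associated CpGs at
P_FDR < 0.05 (40 causal probes were injected), most of which also
associate with WC through its correlation with BMI. The backward MR
correlation of 0.78 between PRS-predicted and observed BMI→CpG effects
reflects the generating direction (BMI causes methylation in this world),
while forward MR finds no instruments for these CpGs because, in this
configuration, the causal and mQTL probe pools are disjoint. The
MRS→IL-6 cross-lagged path (P = 0.012) recovers the planted downstream
inflammation effect. Stage outputs are TSVs with JSON provenance
sidecars in `demo_run/`.

The meta-analysis stage can also be driven directly from published
per-stratum estimates:

```r
pub <- published_novel_cpg_estimates()
hm <- hierarchical_meta(pub$strata)
subset(hm$trans, cpg == "cg02871985",
       select = c(cpg, trait, effect, se, p, p_het))
#>          cpg trait    effect       se           p     p_het
#> 1 cg02871985   bmi -47.87443 10.46394 4.75805e-06 0.5835344
```

i.e. a pooled effect of −47.9 kg/m² per unit beta (SE 10.5) across the
four strata, with no evidence of heterogeneity.

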