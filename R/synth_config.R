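#' Configuration for the synthetic two-wave multi-ethnic cohort
#'
#' Builds and validates the parameter set of the cohort generator
#' ([simulate_study()]). Defaults emulate the design of a two-wave
#' multi-ethnic Asian methylation study: four analysis strata (one
#' longitudinal Chinese sample set plus three single-platform strata of
#' Chinese, Malay and Indian participants), a mean follow-up interval of
#' 6.8 years (SD 1.39, truncated at 1 year), 635 array control probes, and
#' six blood cell types.
#'
#' @param n_per_stratum samples per analysis stratum (four strata are
#'   generated, so total n is `4 * n_per_stratum`).
#' @param n_probes number of autosomal analytic CpG probes.
#' @param n_snps number of SNPs with genotype dosages.
#' @param n_control_probes number of technical control probes (default 635).
#' @param n_cell_types number of blood cell types on the reference simplex
#'   (default 6: granulocytes, monocytes, B, CD4T, CD8T, NK).
#' @param frac_causal_bmi_to_cpg fraction of probes carrying a true
#'   BMI-to-methylation effect.
#' @param effect_scale_bmi_to_cpg causal effect scale in beta-units per
#'   kg/m^2.
#' @param frac_mqtl fraction of probes with a cis-SNP (mQTL) effect.
#' @param batch_sd beta-scale standard deviation of the batch term.
#' @param cell_sd beta-scale standard deviation of the cell-composition term.
#' @param noise_sd beta-scale standard deviation of i.i.d. measurement noise.
#' @param followup_years_mean,followup_years_sd follow-up interval in years
#'   (normal, truncated at 1 year).
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @param n_sex_probes number of chrX and chrY probes each (used by the sex
#'   check, removed by probe QC).
#' @param n_cell_ref_probes number of cell-type-discriminating probes whose
#'   methylation is a direct mixture of the reference profiles.
#' @param mqtl_effect per-allele cis-SNP effect on beta.
#' @param bmi_track_ar autoregressive (tracking) coefficient of the BMI
#'   residual between waves.
#' @param probe_noise_ar autoregressive coefficient of the per-probe
#'   biological noise between waves.
#' @param probe_noise_sd beta-scale SD of the autoregressive biological
#'   probe noise.
#' @param effect_scale_cpg_to_bmi reverse-causal effect scale (kg/m^2 per
#'   unit beta) applied at the mQTL probes; 0 disables reverse causation.
#' @param n_trait_snps number of SNPs with a direct BMI effect (polygenic
#'   component; instruments for the backward analysis).
#' @param trait_snp_effect_sd SD of per-allele BMI effects (kg/m^2).
#' @param bmi_mean,bmi_resid_sd mean and residual SD of BMI (kg/m^2).
#' @param n_transcripts number of expression transcripts.
#' @param n_metabolites number of metabolite biomarker columns (default 155).
#' @param mrs_il6_path standardized cross-lagged path from the baseline
#'   methylation risk score to follow-up IL-6.
#' @param n_corrupt_background number of samples injected with high
#'   background signal (exercises the missingness filter).
#' @param n_sex_swap number of samples whose self-reported sex is swapped
#'   (exercises the sex-mismatch filter).
#' @param total_signal_mean mean total fluorescence intensity per probe.
#' @param allow_overlap allow the BMI-causal and mQTL probe pools to overlap
#'   when their fractions sum above 1.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_per_stratum = 100,
                         n_probes = 2000,
                         n_snps = 200,
                         n_control_probes = 635,
                         n_cell_types = 6,
                         frac_causal_bmi_to_cpg = 0.05,
                         effect_scale_bmi_to_cpg = 0.002,
                         frac_mqtl = 0.05,
                         batch_sd = 0.02,
                         cell_sd = 0.02,
                         noise_sd = 0.02,
                         followup_years_mean = 6.8,
                         followup_years_sd = 1.39,
                         seed = 1L,
                         n_sex_probes = 40,
                         n_cell_ref_probes = 60,
                         mqtl_effect = 0.05,
                         bmi_track_ar = 0.8,
                         probe_noise_ar = 0.3,
                         probe_noise_sd = 0.01,
                         effect_scale_cpg_to_bmi = 0,
                         n_trait_snps = 20,
                         trait_snp_effect_sd = 0.25,
                         bmi_mean = 23,
                         bmi_resid_sd = 3.5,
                         n_transcripts = 300,
                         n_metabolites = 155,
                         mrs_il6_path = 0.3,
                         n_corrupt_background = 0,
                         n_sex_swap = 0,
                         total_signal_mean = 5000,
                         allow_overlap = FALSE) {
  cfg <- as.list(environment())
  fracs <- c(cfg$frac_causal_bmi_to_cpg, cfg$frac_mqtl)
  assert_that(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0, 1]")
  sds <- c(cfg$batch_sd, cfg$cell_sd, cfg$noise_sd, cfg$probe_noise_sd,
           cfg$followup_years_sd, cfg$trait_snp_effect_sd, cfg$bmi_resid_sd)
  assert_that(all(sds >= 0), "all standard deviations must be >= 0")
  counts <- c(cfg$n_per_stratum, cfg$n_probes, cfg$n_snps,
              cfg$n_control_probes, cfg$n_cell_types)
  assert_that(all(counts >= 1), "all counts must be >= 1")
  assert_that(abs(cfg$bmi_track_ar) < 1 && abs(cfg$probe_noise_ar) < 1,
              "autoregressive coefficients must lie in (-1, 1)")
  if (cfg$frac_causal_bmi_to_cpg + cfg$frac_mqtl > 1 && !cfg$allow_overlap) {
    stop("frac_causal_bmi_to_cpg + frac_mqtl > 1 requires allow_overlap = TRUE",
         call. = FALSE)
  }
  assert_that(cfg$n_corrupt_background + cfg$n_sex_swap <=
                cfg$n_per_stratum * 4,
              "more corrupted samples requested than samples generated")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  strata: 4 x %d samples, two visits\n", x$n_per_stratum))
  cat(sprintf("  probes: %d autosomal (+%d X, +%d Y), %d control probes\n",
              x$n_probes, x$n_sex_probes, x$n_sex_probes,
              x$n_control_probes))
  cat(sprintf("  SNPs: %d (%d with BMI effects), causal probes: %.0f%%, mQTL: %.0f%%\n",
              x$n_snps, x$n_trait_snps, 100 * x$frac_causal_bmi_to_cpg,
              100 * x$frac_mqtl))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
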