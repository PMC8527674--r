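# Bidirectional Mendelian randomization. Forward: one cis-mQTL instrument
# per CpG (top associated SNP within 1 Mb, after the exclusion rules), Wald
# ratio of the external SNP-BMI effect over the SNP-CpG effect with a
# delta-method standard error. Backward: a polygenic risk score of
# BMI-associated SNPs instruments BMI, and the predicted BMI-to-CpG effect
# is compared with the observed regression of methylation on BMI.

#' Select one cis-SNP instrument per CpG
#'
#' For every candidate SNP on the same chromosome within `window_bp`
#' (closed interval) of the CpG: regress beta on dosage plus the discovery
#' covariates per stratum and pool by inverse-variance meta-analysis. The
#' smallest-P SNP is retained, then excluded with a recorded reason when
#' (a) its meta P exceeds 0.05 ("nonsignificant"), (b) it lies within the
#' probe-binding sequence, taken as <= `binding_bp` from the CpG position
#' ("probe_binding"), or (c) it associates with BMI (P < 0.05) in a model
#' adjusting for the CpG ("pleiotropy_bmi"). Monomorphic SNPs are never
#' candidates.
#'
#' @param cpg_hits data frame with cpg, chr, pos.
#' @param genotypes list with `dosage` (sample x SNP) and `info` (snp,
#'   chr, pos).
#' @param strata_data named per-stratum list with `beta`, `pheno`,
#'   `covars` (discovery covariates).
#' @param window_bp cis window (default 1 Mb).
#' @param binding_bp probe-binding exclusion distance (default 50 bp).
#' @return data frame with one row per CpG: cpg, snp, eff_cpg_snp,
#'   se_cpg_snp, p_select, exclusion_reason ("none" for retained
#'   instruments; "no_cis_snp" when the window is empty).
#' @export
select_cis_iv <- function(cpg_hits, genotypes, strata_data,
                          window_bp = 1e6, binding_bp = 50) {
  info <- genotypes$info
  dos <- genotypes$dosage
  rows <- lapply(seq_len(nrow(cpg_hits)), function(i) {
    h <- cpg_hits[i, ]
    cand <- info[info$chr == h$chr & abs(info$pos - h$pos) <= window_bp, ]
    cand <- cand[apply(dos[, cand$snp, drop = FALSE], 2, stats::sd) > 0, ,
                 drop = FALSE]
    if (nrow(cand) == 0) {
      return(data.frame(cpg = h$cpg, snp = NA_character_, eff_cpg_snp = NA,
                        se_cpg_snp = NA, p_select = NA,
                        exclusion_reason = "no_cis_snp",
                        stringsAsFactors = FALSE))
    }
    metas <- lapply(cand$snp, function(sn) {
      ests <- do.call(rbind, lapply(strata_data, function(d) {
        ids <- d$pheno$sample_id
        snp_assoc(d$beta[h$cpg, ids], dos[ids, sn], d$covars)
      }))
      ivw_meta(ests$effect, ests$se)
    })
    ps <- vapply(metas, function(m) m$p, numeric(1))
    best <- which.min(ps)
    m <- metas[[best]]
    sn <- cand$snp[best]
    reason <- "none"
    if (m$p > 0.05) {
      reason <- "nonsignificant"
    } else if (abs(cand$pos[best] - h$pos) <= binding_bp) {
      reason <- "probe_binding"
    } else {
      # pleiotropy: SNP-BMI association conditional on the CpG
      ests <- do.call(rbind, lapply(strata_data, function(d) {
        ids <- d$pheno$sample_id
        cov2 <- cbind(as.matrix(d$covars), cpg_beta = d$beta[h$cpg, ids])
        snp_assoc(d$pheno$bmi, dos[ids, sn], cov2)
      }))
      mp <- ivw_meta(ests$effect, ests$se)
      if (mp$p < 0.05) reason <- "pleiotropy_bmi"
    }
    data.frame(cpg = h$cpg, snp = sn, eff_cpg_snp = m$effect,
               se_cpg_snp = m$se, p_select = m$p,
               exclusion_reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# single-stratum OLS of y on x + covariates (effect and SE for x)
snp_assoc <- function(y, x, covars) {
  des <- build_design(covars)
  ry <- qr.resid(des$qr, y)
  rx <- qr.resid(des$qr, x)
  sxx <- sum(rx^2)
  if (sxx < 1e-20) return(data.frame(effect = NA_real_, se = NA_real_))
  slope <- sum(rx * ry) / sxx
  df <- length(y) - ncol(des$X) - 1
  rss <- sum(ry^2) - slope * sum(rx * ry)
  data.frame(effect = slope, se = sqrt(max(rss, 0) / df / sxx))
}

#' Wald-ratio causal estimate with delta-method standard error
#'
#' predicted effect = eff_bmi_snp / eff_cpg_snp (the signed square root of
#' the squared-form expression), and
#' predicted SE = sqrt( (eff_bmi^2/eff_cpg^2) *
#'                      (se_bmi^2/eff_bmi^2 + se_cpg^2/eff_cpg^2) ).
#' When eff_bmi_snp = 0 the estimate is 0 and the SE reduces to its limit
#' |se_bmi / eff_cpg_snp|.
#'
#' @param eff_bmi_snp,se_bmi_snp instrument-outcome effect and SE.
#' @param eff_cpg_snp,se_cpg_snp instrument-exposure effect and SE
#'   (eff_cpg_snp must be nonzero).
#' @return list with `effect` and `se`.
#' @export
wald_ratio <- function(eff_bmi_snp, se_bmi_snp, eff_cpg_snp, se_cpg_snp) {
  if (any(eff_cpg_snp == 0, na.rm = TRUE)) {
    stop("eff_cpg_snp must be nonzero", call. = FALSE)
  }
  eff <- eff_bmi_snp / eff_cpg_snp
  se <- ifelse(
    eff_bmi_snp == 0,
    abs(se_bmi_snp / eff_cpg_snp),
    sqrt((eff_bmi_snp^2 / eff_cpg_snp^2) *
           (se_bmi_snp^2 / eff_bmi_snp^2 + se_cpg_snp^2 / eff_cpg_snp^2))
  )
  list(effect = eff, se = se)
}

# flip external effects onto the coded (dosage-counted) allele
harmonize_sumstats <- function(iv_alleles, sumstats) {
  m <- sumstats[match(iv_alleles$snp, sumstats$snp), ]
  flip <- !is.na(m$effect_allele) & m$effect_allele != iv_alleles$coded_allele &
    m$other_allele == iv_alleles$coded_allele
  m$beta[flip] <- -m$beta[flip]
  ea <- m$effect_allele
  m$effect_allele[flip] <- m$other_allele[flip]
  m$other_allele[flip] <- ea[flip]
  m
}

#' Forward Mendelian randomization (methylation as putative cause)
#'
#' Per retained instrument, computes the Wald-ratio predicted CpG-to-BMI
#' effect with delta-method SE, declares a causal call when the two-sided
#' normal P falls below `alpha`, and correlates predicted against observed
#' EWAS effects (Pearson, with test). Instruments absent from the summary
#' statistics get reason "no_sumstats". Effect alleles are harmonized to
#' the dosage-counted allele before use.
#'
#' @param iv output of [select_cis_iv()] (rows with exclusion_reason
#'   "none" are used), plus a `coded_allele` column or a `genotypes$info`
#'   table via `coded_alleles`.
#' @param sumstats external GWAS table (snp, effect_allele, other_allele,
#'   beta, se).
#' @param ewas_meta meta-analysis EWAS table (cpg, effect) supplying the
#'   observed effects.
#' @param alpha multiple-testing-adjusted causal-call threshold (default
#'   5e-4).
#' @param coded_alleles optional data frame (snp, alt) naming the allele
#'   counted by the dosages (defaults to sumstats orientation, i.e. no
#'   flips).
#' @return list with `estimates` (per-CpG table) and `correlation`
#'   (estimate, p, n).
#' @export
forward_mr <- function(iv, sumstats, ewas_meta, alpha = 5e-4,
                       coded_alleles = NULL) {
  keep <- iv[iv$exclusion_reason == "none", , drop = FALSE]
  coded <- if (is.null(coded_alleles)) {
    sumstats$effect_allele[match(keep$snp, sumstats$snp)]
  } else {
    coded_alleles$alt[match(keep$snp, coded_alleles$snp)]
  }
  ss <- harmonize_sumstats(data.frame(snp = keep$snp, coded_allele = coded,
                                      stringsAsFactors = FALSE), sumstats)
  missing <- is.na(ss$beta)
  est <- data.frame(cpg = keep$cpg, snp = keep$snp,
                    eff_bmi_snp = ss$beta, se_bmi_snp = ss$se,
                    eff_cpg_snp = keep$eff_cpg_snp,
                    se_cpg_snp = keep$se_cpg_snp,
                    stringsAsFactors = FALSE)
  est$reason <- ifelse(missing, "no_sumstats", "none")
  wr <- wald_ratio(ifelse(missing, NA, est$eff_bmi_snp), est$se_bmi_snp,
                   est$eff_cpg_snp, est$se_cpg_snp)
  est$predicted_effect <- wr$effect
  est$predicted_se <- wr$se
  est$p <- z_pvalue(est$predicted_effect, est$predicted_se)
  est$causal_call <- !is.na(est$p) & est$p < alpha
  est$observed_effect <- ewas_meta$effect[match(est$cpg, ewas_meta$cpg)]
  ok <- !missing & !is.na(est$observed_effect)
  corr <- if (sum(ok) >= 3) {
    ct <- stats::cor.test(est$predicted_effect[ok], est$observed_effect[ok])
    list(estimate = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  } else {
    list(estimate = NA_real_, p = NA_real_, n = sum(ok))
  }
  list(estimates = est, correlation = corr)
}

#' Polygenic risk score from dosages and published weights
#'
#' PRS_i = sum_j w_j * dosage_ij of the stated effect allele; dosages coded
#' on the other allele are flipped (2 - dosage), and missing dosages are
#' mean-imputed per SNP before scoring.
#'
#' @param genotypes list with `dosage` (sample x SNP) and `info`
#'   (snp, ref, alt) where `alt` is the allele the dosage counts.
#' @param weights data frame with snp, effect_allele, weight.
#' @return named per-sample score vector.
#' @export
compute_prs <- function(genotypes, weights) {
  info <- genotypes$info
  w <- weights[weights$snp %in% info$snp, , drop = FALSE]
  if (nrow(w) == 0) stop("no overlapping SNPs between weights and genotypes",
                         call. = FALSE)
  D <- genotypes$dosage[, w$snp, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    if (anyNA(D[, j])) D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  }
  coded <- info$alt[match(w$snp, info$snp)]
  flip <- w$effect_allele != coded
  D[, flip] <- 2 - D[, flip, drop = FALSE]
  drop(D %*% w$weight)
}

#' Backward Mendelian randomization (BMI as putative cause) via PRS
#'
#' Per CpG: predicted BMI-to-CpG effect = eff(CpG ~ PRS) / eff(BMI ~ PRS)
#' with the mirror of the Wald delta-method SE; the observed effect is the
#' regression of methylation on BMI plus the discovery covariates.
#' Predicted and observed effects are correlated with a test. A weak
#' instrument (PRS-BMI association P > 0.05) attaches a warning flag to
#' every estimate.
#'
#' @param prs named per-sample score vector.
#' @param cpgs probes to assess.
#' @param strata_data per-stratum list with `beta`, `pheno`, `covars`.
#' @param alpha causal-call threshold (default 5e-4).
#' @return list with `estimates`, `correlation`, `instrument` (PRS-BMI
#'   effect, SE, P) and `weak_instrument` flag.
#' @export
backward_mr <- function(prs, cpgs, strata_data, alpha = 5e-4) {
  # instrument strength: BMI ~ PRS (+ covariates), pooled
  inst <- do.call(rbind, lapply(strata_data, function(d) {
    ids <- d$pheno$sample_id
    snp_assoc(d$pheno$bmi, prs[ids], d$covars)
  }))
  im <- ivw_meta(inst$effect, inst$se)
  weak <- im$p > 0.05
  if (weak) warning("weak instrument: PRS-BMI association P > 0.05")

  rows <- lapply(cpgs, function(cpg) {
    num <- do.call(rbind, lapply(strata_data, function(d) {
      ids <- d$pheno$sample_id
      snp_assoc(d$beta[cpg, ids], prs[ids], d$covars)
    }))
    nm <- ivw_meta(num$effect, num$se)
    obs <- do.call(rbind, lapply(strata_data, function(d) {
      ids <- d$pheno$sample_id
      snp_assoc(d$beta[cpg, ids], d$pheno$bmi, d$covars)
    }))
    om <- ivw_meta(obs$effect, obs$se)
    wr <- wald_ratio(nm$effect, nm$se, im$effect, im$se)
    data.frame(cpg = cpg, eff_cpg_prs = nm$effect, se_cpg_prs = nm$se,
               predicted_effect = wr$effect, predicted_se = wr$se,
               p = z_pvalue(wr$effect, wr$se),
               observed_effect = om$effect, observed_se = om$se,
               weak_instrument = weak, stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  est$causal_call <- est$p < alpha
  ok <- stats::complete.cases(est[, c("predicted_effect", "observed_effect")])
  corr <- if (sum(ok) >= 3) {
    ct <- stats::cor.test(est$predicted_effect[ok], est$observed_effect[ok])
    list(estimate = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  } else list(estimate = NA_real_, p = NA_real_, n = sum(ok))
  list(estimates = est, correlation = corr,
       instrument = list(effect = im$effect, se = im$se, p = im$p),
       weak_instrument = weak)
}

#' Methylation risk score
#'
#' MRS_i = sum_j w_j * beta_ij over the weighted CpGs, Z-standardized.
#' Errors when fewer than half of the weighted CpGs are present or when
#' all weights are zero.
#'
#' @param beta probe x sample matrix (or `beta_matrix`).
#' @param weights data frame with cpg, weight (typically trans-ethnic
#'   meta-analysis effects).
#' @param standardize Z-standardize the score (default TRUE).
#' @return named per-sample score vector.
#' @export
compute_mrs <- function(beta, weights, standardize = TRUE) {
  if (inherits(beta, "beta_matrix")) beta <- beta$beta
  if (all(weights$weight == 0)) stop("all MRS weights are zero", call. = FALSE)
  present <- weights$cpg %in% rownames(beta)
  if (mean(present) < 0.5) {
    stop("fewer than 50% of the weighted CpGs are present in the beta matrix",
         call. = FALSE)
  }
  w <- weights[present, , drop = FALSE]
  score <- drop(crossprod(beta[w$cpg, , drop = FALSE], w$weight))
  if (standardize) score <- as.numeric(scale(score))
  names(score) <- colnames(beta)
  score
}
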