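# Synthetic two-wave multi-ethnic cohort generator.
#
# Generative model (beta-scale terms are mapped onto the logit scale through
# the local derivative of the logistic, so that configured effect scales are
# interpretable in beta units):
#
#   eta[p,s,v] = l0[p] + ( cell[p,s] + batch[p,s,v] + mqtl[p,s]
#                          + u[p,s,v] + delta[p] * (BMI[s,v] - mean) ) / g[p]
#   mu  = logistic(eta),  g[p] = mu0[p] * (1 - mu0[p])
#   beta_obs = clamp(mu + N(0, noise_sd));  M = beta_obs * T, U = (1-beta_obs) * T
#
# BMI residuals follow a stationary AR(1) between waves (tracking), and the
# per-probe biological noise u follows its own AR(1); with contemporaneous
# BMI->CpG effects this yields a cross-lagged structure with a strictly zero
# reverse (CpG->BMI) path unless effect_scale_cpg_to_bmi is set.

STRATA <- data.frame(
  stratum    = c("longitudinal_chinese", "multiomic_chinese", "multiomic_malay", "multiomic_indian"),
  ethnicity  = c("chinese", "chinese", "malay", "indian"),
  sample_set = c("longitudinal", "multiomic", "multiomic", "multiomic"),
  stringsAsFactors = FALSE
)

CELL_TYPE_NAMES <- c("granulocytes", "monocytes", "bcells", "cd4t", "cd8t", "nk")

# Dirichlet draw via independent gammas
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a complete synthetic methylation study
#'
#' Generates raw intensity data (with control probes and beadcounts) for two
#' visits, genotype dosages, a two-wave phenotype sheet, an expression
#' matrix with transcript coordinates, inflammation/metabolite biomarkers,
#' and truth tables recording every injected effect, so the full analysis
#' pipeline can be exercised and validated without external data.
#'
#' @param config a [synth_config()] object.
#' @return a `study_bundle` list with elements `intensities` (per visit),
#'   `genotypes`, `phenotypes`, `expression`, `biomarkers`, `cell_reference`
#'   and `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cfg <- config

  n_strat <- nrow(STRATA)
  n <- cfg$n_per_stratum * n_strat
  sample_id <- sprintf("S%04d", seq_len(n))
  stratum <- rep(STRATA$stratum, each = cfg$n_per_stratum)
  ethnicity <- rep(STRATA$ethnicity, each = cfg$n_per_stratum)
  sample_set <- rep(STRATA$sample_set, each = cfg$n_per_stratum)

  ## ---- sample-level biology -------------------------------------------
  age_base <- round(stats::runif(n, 35, 65), 1)
  male <- stats::rbinom(n, 1, 0.5)
  # the longitudinal Chinese set is all never-smokers, mirroring the design
  smoking <- ifelse(sample_set == "longitudinal", 0L, stats::rbinom(n, 1, 0.25))
  fu_years <- pmax(stats::rnorm(n, cfg$followup_years_mean,
                                cfg$followup_years_sd), 1)

  cell_alpha <- c(0.55, 0.08, 0.08, 0.15, 0.08, 0.06)[seq_len(cfg$n_cell_types)]
  cell_alpha <- cell_alpha / sum(cell_alpha)
  conc <- 30
  cellp <- rdirichlet(n, conc * cell_alpha)
  colnames(cellp) <- CELL_TYPE_NAMES[seq_len(cfg$n_cell_types)]
  rownames(cellp) <- sample_id

  batch <- cbind(baseline = stats::rnorm(n), followup = stats::rnorm(n))
  rownames(batch) <- sample_id

  ## ---- genotypes -------------------------------------------------------
  n_snps <- cfg$n_snps
  snp_id <- sprintf("rs%06d", seq_len(n_snps))
  maf <- stats::runif(n_snps, 0.1, 0.5)
  dosage <- sapply(maf, function(f) stats::rbinom(n, 2, f))
  dimnames(dosage) <- list(sample_id, snp_id)

  n_trait_snps <- min(cfg$n_trait_snps, n_snps)
  trait_snps <- seq(n_snps - n_trait_snps + 1, n_snps)
  snp_bmi_effect <- numeric(n_snps)
  snp_bmi_effect[trait_snps] <- stats::rnorm(n_trait_snps, 0,
                                             cfg$trait_snp_effect_sd)
  prs_true <- drop(dosage %*% snp_bmi_effect)

  ## ---- probe layout ----------------------------------------------------
  n_probes <- cfg$n_probes
  probe_id <- sprintf("cg%07d", seq_len(n_probes))
  probe_chr <- as.character(sample(1:22, n_probes, replace = TRUE))
  probe_pos <- sample.int(2e8, n_probes) + 1e6

  n_ref <- min(cfg$n_cell_ref_probes, n_probes)
  ref_idx <- seq_len(n_ref)
  pool <- setdiff(seq_len(n_probes), ref_idx)

  n_causal <- round(cfg$frac_causal_bmi_to_cpg * n_probes)
  n_mqtl <- round(cfg$frac_mqtl * n_probes)
  causal_idx <- if (n_causal > 0) sample(pool, min(n_causal, length(pool))) else integer(0)
  mqtl_pool <- if (cfg$allow_overlap) pool else setdiff(pool, causal_idx)
  mqtl_idx <- if (n_mqtl > 0) sample(mqtl_pool, min(n_mqtl, length(mqtl_pool))) else integer(0)

  delta_beta <- numeric(n_probes)
  if (length(causal_idx) > 0) {
    delta_beta[causal_idx] <- cfg$effect_scale_bmi_to_cpg *
      sample(c(-1, 1), length(causal_idx), replace = TRUE) *
      stats::runif(length(causal_idx), 0.5, 1.5)
  }

  # assign one cis SNP per mQTL probe (trait SNPs are kept separate)
  mqtl_eff <- numeric(n_probes)
  mqtl_snp <- rep(NA_character_, n_probes)
  snp_chr <- as.character(sample(1:22, n_snps, replace = TRUE))
  snp_pos <- sample.int(2e8, n_snps) + 1e6
  avail_snps <- setdiff(seq_len(n_snps), trait_snps)
  n_assign <- min(length(mqtl_idx), length(avail_snps))
  mqtl_idx <- mqtl_idx[seq_len(n_assign)]
  if (n_assign > 0) {
    snps_used <- avail_snps[seq_len(n_assign)]
    offs <- round(stats::runif(n_assign, -5e5, 5e5))
    # a couple of instruments are planted inside the probe-binding sequence
    n_bind <- min(2, n_assign)
    offs[seq_len(n_bind)] <- sample(5:45, n_bind) *
      sample(c(-1, 1), n_bind, replace = TRUE)
    snp_chr[snps_used] <- probe_chr[mqtl_idx]
    snp_pos[snps_used] <- pmax(probe_pos[mqtl_idx] + offs, 1)
    mqtl_eff[mqtl_idx] <- cfg$mqtl_effect *
      sample(c(-1, 1), n_assign, replace = TRUE) *
      stats::runif(n_assign, 0.5, 1.5)
    mqtl_snp[mqtl_idx] <- snp_id[snps_used]
  }

  # reverse-causal (CpG -> BMI) effects live at the mQTL probes so that the
  # forward MR design has instrumented exposures
  kappa <- numeric(n_probes)
  if (cfg$effect_scale_cpg_to_bmi != 0 && length(mqtl_idx) > 0) {
    kappa[mqtl_idx] <- cfg$effect_scale_cpg_to_bmi *
      sample(c(-1, 1), length(mqtl_idx), replace = TRUE) *
      stats::runif(length(mqtl_idx), 0.5, 1.5)
  }

  ## ---- probe baselines and loadings -----------------------------------
  comp <- sample(1:3, n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  l0 <- ifelse(comp == 1, stats::rnorm(n_probes, -2.5, 0.5),
        ifelse(comp == 2, stats::rnorm(n_probes, 2.5, 0.5),
               stats::rnorm(n_probes, 0, 1)))
  mu0 <- logistic(l0)
  gder <- mu0 * (1 - mu0)

  # cell loadings calibrated so the beta-scale cell term has SD ~ cell_sd
  cell_var <- sum(cell_alpha * (1 - cell_alpha)) / (conc + 1)
  gamma <- matrix(stats::rnorm(n_probes * cfg$n_cell_types, 0,
                               cfg$cell_sd / sqrt(cell_var)),
                  n_probes, cfg$n_cell_types)
  lambda <- stats::rnorm(n_probes, 0, cfg$batch_sd)

  cell_dev <- sweep(cellp, 2, cell_alpha)        # n x k
  cell_term <- gamma %*% t(cell_dev)             # probes x samples

  cell_ref <- matrix(stats::runif(n_ref * cfg$n_cell_types, 0.05, 0.95),
                     n_ref, cfg$n_cell_types,
                     dimnames = list(probe_id[ref_idx],
                                     colnames(cellp)))

  ## ---- BMI at two waves ------------------------------------------------
  a <- cfg$bmi_track_ar
  z_b <- stats::rnorm(n, 0, cfg$bmi_resid_sd)
  z_f <- a * z_b + stats::rnorm(n, 0, cfg$bmi_resid_sd * sqrt(1 - a^2))

  # AR(1) probe-level biological noise (beta scale)
  rho <- cfg$probe_noise_ar
  u_b <- matrix(stats::rnorm(n_probes * n, 0, cfg$probe_noise_sd), n_probes, n)
  u_f <- rho * u_b + matrix(stats::rnorm(n_probes * n, 0,
                                         cfg$probe_noise_sd * sqrt(1 - rho^2)),
                            n_probes, n)

  strat_shift <- c(longitudinal_chinese = 0, multiomic_chinese = 0,
                   multiomic_malay = 1.0, multiomic_indian = 0.5)[stratum]
  agesex <- 0.04 * (age_base - 50) + 0.8 * male - 0.3 * smoking

  mqtl_term <- matrix(0, n_probes, n)
  if (length(mqtl_idx) > 0) {
    snp_of <- match(mqtl_snp[mqtl_idx], snp_id)
    dos_dev <- t(dosage[, snp_of, drop = FALSE]) - 2 * maf[snp_of]
    mqtl_term[mqtl_idx, ] <- mqtl_eff[mqtl_idx] * dos_dev
  }
  rev_term <- if (any(kappa != 0)) {
    # uses the BMI-independent part of the mQTL probes' methylation
    drop(crossprod(mqtl_term, kappa))
  } else numeric(n)

  bmi_base <- cfg$bmi_mean + strat_shift + agesex + prs_true + rev_term + z_b
  bmi_fu   <- cfg$bmi_mean + strat_shift + agesex + prs_true + rev_term + z_f
  wc_base <- 35 + 2.3 * bmi_base + stats::rnorm(n, 0, 5)
  wc_fu   <- 35 + 2.3 * bmi_fu + stats::rnorm(n, 0, 5)

  ## ---- corruption injection -------------------------------------------
  corrupt_bg <- sample_id[sample.int(n, cfg$n_corrupt_background)]
  swap_pool <- setdiff(sample_id, corrupt_bg)
  sex_swap <- swap_pool[sample.int(length(swap_pool), cfg$n_sex_swap)]
  reported_sex <- ifelse(male == 1, "male", "female")
  flip <- sample_id %in% sex_swap
  reported_sex[flip] <- ifelse(reported_sex[flip] == "male", "female", "male")

  ## ---- manifest --------------------------------------------------------
  n_sex <- cfg$n_sex_probes
  sexp_id <- c(sprintf("cgX%05d", seq_len(n_sex)), sprintf("cgY%05d", seq_len(n_sex)))
  manifest <- data.frame(
    probe_id = c(probe_id, sexp_id),
    chr = c(probe_chr, rep("X", n_sex), rep("Y", n_sex)),
    pos = c(probe_pos, sample.int(1e8, 2 * n_sex) + 1e6),
    relation_to_island = sample(c("Island", "N_Shore", "S_Shore", "OpenSea"),
                                n_probes + 2 * n_sex, replace = TRUE),
    nearest_gene = sprintf("GENE%05d", sample.int(5e4, n_probes + 2 * n_sex)),
    cross_reactive = stats::rbinom(n_probes + 2 * n_sex, 1, 0.05) == 1,
    snp_affected = FALSE,
    stringsAsFactors = FALSE
  )
  # flag probes with a SNP inside the probe-binding sequence (<= 50 bp)
  if (length(mqtl_idx) > 0) {
    d <- abs(probe_pos[mqtl_idx] - snp_pos[match(mqtl_snp[mqtl_idx], snp_id)])
    manifest$snp_affected[mqtl_idx[d <= 50]] <- TRUE
  }

  ## ---- intensities per visit ------------------------------------------
  make_visit <- function(visit) {
    bmi <- if (visit == "baseline") bmi_base else bmi_fu
    u <- if (visit == "baseline") u_b else u_f
    b <- batch[, visit]
    beta_term <- cell_term + outer(lambda, b) + mqtl_term + u +
      outer(delta_beta, bmi - cfg$bmi_mean)
    eta <- l0 + beta_term / gder
    mu <- logistic(eta)
    mu[ref_idx, ] <- t(clamp(cellp %*% t(cell_ref), 0.02, 0.98))
    beta_meas <- clamp(mu + matrix(stats::rnorm(n_probes * n, 0, cfg$noise_sd),
                                   n_probes, n), 1e-4, 1 - 1e-4)

    tot <- matrix(stats::rlnorm(n_probes * n, log(cfg$total_signal_mean), 0.2),
                  n_probes, n)
    # sex probes: X intensity halves in males, Y collapses to background in
    # females
    tot_x <- matrix(stats::rlnorm(n_sex * n, log(cfg$total_signal_mean), 0.2),
                    n_sex, n)
    tot_x <- sweep(tot_x, 2, ifelse(male == 1, 0.5, 1), `*`)
    tot_y <- matrix(stats::rlnorm(n_sex * n, log(cfg$total_signal_mean), 0.2),
                    n_sex, n)
    bgy <- matrix(abs(stats::rnorm(n_sex * n, 120, 20)), n_sex, n)
    tot_y[, male == 0] <- bgy[, male == 0]

    neg_mean <- ifelse(sample_id %in% corrupt_bg, 300, 100)
    for (s in which(sample_id %in% corrupt_bg)) {
      bad <- sample.int(n_probes, round(0.08 * n_probes))
      tot[bad, s] <- abs(stats::rnorm(length(bad), 130, 15))
    }

    beta_all <- rbind(beta_meas,
                      matrix(0.5, 2 * n_sex, n))
    tot_all <- rbind(tot, tot_x, tot_y)
    M <- beta_all * tot_all
    U <- (1 - beta_all) * tot_all
    dimnames(M) <- dimnames(U) <- list(manifest$probe_id, sample_id)
    beadcount <- matrix(1L + stats::rpois((n_probes + 2 * n_sex) * n, 13),
                        n_probes + 2 * n_sex, n,
                        dimnames = dimnames(M))

    nq <- cfg$n_control_probes
    n_neg <- max(2, min(60, nq - 1))
    ctrl_type <- c(rep("NEGATIVE", n_neg),
                   sample(c("BISULFITE_CONVERSION", "NORM_C", "HYBRIDIZATION",
                            "STAINING", "EXTENSION"), nq - n_neg,
                          replace = TRUE))
    ctrl_base <- stats::rlnorm(nq, log(1000), 0.3)
    phi <- stats::runif(nq, 0.5, 1.5)
    ctrl <- exp(log(ctrl_base) + 0.2 * outer(phi, b) +
                  matrix(stats::rnorm(nq * n, 0, 0.05), nq, n))
    ctrl[seq_len(n_neg), ] <- matrix(
      abs(stats::rnorm(n_neg * n, rep(neg_mean, each = n_neg), 20)), n_neg, n)
    dimnames(ctrl) <- list(sprintf("ctrl%04d", seq_len(nq)), sample_id)

    intensity_data(M, U, beadcount, ctrl, ctrl_type, manifest)
  }

  intens <- list(baseline = make_visit("baseline"),
                 followup = make_visit("followup"))

  ## ---- realized truth: implied cross-sectional EWAS slope -------------
  beta_obs_fu <- with(intens$followup,
                      (M[probe_id, ] / (M[probe_id, ] + U[probe_id, ] + 100)))
  beta_obs_b <- with(intens$baseline,
                     (M[probe_id, ] / (M[probe_id, ] + U[probe_id, ] + 100)))
  # the implied per-unit-beta EWAS effect is the estimand of the linear
  # analysis model: the partial regression slope of trait on beta given the
  # true confounders (cell proportions, batch) entered linearly
  X_true <- cbind(1, cellp[, -1], batch[, "followup"])
  qx_fu <- qr(X_true)
  E_fu <- qr.resid(qx_fu, t(beta_obs_fu))          # samples x probes
  zr_fu <- qr.resid(qx_fu, z_f)
  X_true_b <- cbind(1, cellp[, -1], batch[, "baseline"])
  qx_b <- qr(X_true_b)
  E_b <- qr.resid(qx_b, t(beta_obs_b))
  zr_b <- qr.resid(qx_b, z_b)
  implied <- drop(crossprod(E_fu, zr_fu)) / colSums(E_fu^2)
  implied[!seq_len(n_probes) %in% causal_idx] <- 0

  # standardized forward cross-lagged path implied by the AR structure
  k_cor <- drop(crossprod(E_b, zr_b)) /
    (sqrt(colSums(E_b^2)) * sqrt(sum(zr_b^2)))
  sigy2 <- colSums(E_b^2) / (n - 1)
  qfrac <- cfg$probe_noise_sd^2 / sigy2
  cxy_true <- k_cor * (a * (1 - k_cor^2) - rho * qfrac) / (1 - k_cor^2)
  cxy_true[!seq_len(n_probes) %in% causal_idx] <- 0

  ## ---- phenotype sheet -------------------------------------------------
  pheno <- rbind(
    data.frame(sample_id, stratum, ethnicity, sample_set, visit = "baseline",
               age = age_base, sex = reported_sex, smoking,
               bmi = round(bmi_base, 2), wc = round(wc_base, 1),
               followup_years = round(fu_years, 2), stringsAsFactors = FALSE),
    data.frame(sample_id, stratum, ethnicity, sample_set, visit = "followup",
               age = round(age_base + fu_years, 1), sex = reported_sex, smoking,
               bmi = round(bmi_fu, 2), wc = round(wc_fu, 1),
               followup_years = round(fu_years, 2), stringsAsFactors = FALSE)
  )

  ## ---- expression ------------------------------------------------------
  n_tr <- cfg$n_transcripts
  tr_id <- sprintf("tr%05d", seq_len(n_tr))
  n_cis <- min(round(0.5 * n_tr), n_probes)
  # put cis transcripts preferentially near causal probes
  near <- c(causal_idx, sample(setdiff(seq_len(n_probes), causal_idx)))
  near <- near[seq_len(n_cis)]
  tr_chr <- as.character(sample(1:22, n_tr, replace = TRUE))
  tr_start <- sample.int(2e8, n_tr) + 1e6
  tr_chr[seq_len(n_cis)] <- probe_chr[near]
  tr_start[seq_len(n_cis)] <- pmax(probe_pos[near] +
                                     round(stats::runif(n_cis, -9e5, 9e5)), 1)
  tr_effect <- numeric(n_tr)
  n_eff <- min(length(causal_idx), n_cis)
  if (n_eff > 0) {
    tr_effect[seq_len(n_eff)] <- sample(c(-1, 1), n_eff, replace = TRUE) *
      stats::runif(n_eff, 1, 3)
  }
  base_expr <- stats::rnorm(n_tr, 7, 0.5)
  n_low <- min(40, n_tr)
  low_idx <- seq(n_tr - n_low + 1, n_tr)
  base_expr[low_idx] <- stats::rnorm(n_low, 2, 0.3)
  expr <- matrix(base_expr, n_tr, n) +
    outer(rep(0.3, n_tr), male) +
    outer(stats::runif(n_tr, 0, 0.3), batch[, "followup"]) +
    matrix(stats::rnorm(n_tr * n, 0, 0.5), n_tr, n)
  if (n_eff > 0) {
    dev <- beta_obs_fu[near[seq_len(n_eff)], , drop = FALSE]
    dev <- dev - rowMeans(dev)
    expr[seq_len(n_eff), ] <- expr[seq_len(n_eff), ] +
      tr_effect[seq_len(n_eff)] * dev
  }
  dimnames(expr) <- list(tr_id, sample_id)

  ## ---- biomarkers downstream of the methylation risk score -------------
  if (length(causal_idx) > 0) {
    mrs_raw <- drop(crossprod(beta_obs_b[causal_idx, , drop = FALSE],
                              implied[causal_idx]))
    zmrs <- drop(scale(mrs_raw))
  } else {
    zmrs <- numeric(n)
  }
  ar_bio <- 0.5
  lat_bio <- function(path) {
    lb <- stats::rnorm(n)
    resid_sd <- sqrt(max(1 - ar_bio^2 - path^2, 0.1))
    lf <- ar_bio * lb + path * zmrs + stats::rnorm(n, 0, resid_sd)
    cbind(lb, lf)
  }
  il6 <- lat_bio(cfg$mrs_il6_path)
  tnf <- lat_bio(0)
  n_met <- cfg$n_metabolites
  met_path <- c(rep(0.25, min(4, n_met)), rep(0, max(0, n_met - 4)))
  mets <- lapply(met_path, lat_bio)
  bio_frame <- function(w) {
    df <- data.frame(sample_id, visit = if (w == 1) "baseline" else "followup",
                     il6 = exp(0.5 + 0.4 * il6[, w]),
                     tnf_alpha = exp(0.3 + 0.4 * tnf[, w]),
                     stringsAsFactors = FALSE)
    metm <- sapply(mets, function(m) exp(0.3 * m[, w]))
    colnames(metm) <- sprintf("metab_%03d", seq_len(n_met))
    cbind(df, metm)
  }
  biomarkers <- rbind(bio_frame(1), bio_frame(2))

  ## ---- truth tables ----------------------------------------------------
  truth <- list(
    probes = data.frame(
      probe_id, chr = probe_chr, pos = probe_pos,
      causal_bmi = seq_len(n_probes) %in% causal_idx,
      delta_beta, implied_effect_bmi = implied, clpm_cxy_true = cxy_true,
      is_mqtl = seq_len(n_probes) %in% mqtl_idx,
      mqtl_snp, mqtl_effect = mqtl_eff, cpg_to_bmi_effect = kappa,
      cell_ref = seq_len(n_probes) %in% ref_idx,
      stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id, stratum,
      batch_baseline = batch[, "baseline"], batch_followup = batch[, "followup"],
      cellp, prs_true,
      corrupt_background = sample_id %in% corrupt_bg,
      sex_swapped = sample_id %in% sex_swap,
      true_sex = ifelse(male == 1, "male", "female"),
      z_bmi_base = z_b, z_bmi_fu = z_f, zmrs_base = zmrs,
      stringsAsFactors = FALSE),
    snps = data.frame(
      snp = snp_id, chr = snp_chr, pos = snp_pos, maf,
      bmi_effect = snp_bmi_effect,
      is_mqtl_snp = snp_id %in% mqtl_snp,
      stringsAsFactors = FALSE),
    config = cfg
  )

  structure(list(
    intensities = intens,
    genotypes = list(dosage = dosage,
                     info = data.frame(snp = snp_id, chr = snp_chr,
                                       pos = snp_pos, ref = "A", alt = "G",
                                       maf, stringsAsFactors = FALSE)),
    phenotypes = pheno,
    expression = list(values = expr,
                      coords = data.frame(transcript_id = tr_id, chr = tr_chr,
                                          start = tr_start,
                                          stringsAsFactors = FALSE),
                      ctrl_mean = 4,
                      covars = data.frame(sample_id, sex = reported_sex,
                                          batch = batch[, "followup"],
                                          stringsAsFactors = FALSE),
                      truth_effect = data.frame(transcript_id = tr_id,
                                                cis_probe = c(probe_id[near],
                                                              rep(NA, n_tr - n_cis))[seq_len(n_tr)],
                                                effect = tr_effect,
                                                stringsAsFactors = FALSE)),
    biomarkers = biomarkers,
    cell_reference = cell_ref,
    truth = truth
  ), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic study bundle\n")
  cat(sprintf("  %d samples x 2 visits, %d analytic probes, %d SNPs\n",
              nrow(x$truth$samples), nrow(x$truth$probes),
              nrow(x$truth$snps)))
  cat(sprintf("  causal BMI->CpG probes: %d; mQTL probes: %d; seed %d\n",
              sum(x$truth$probes$causal_bmi), sum(x$truth$probes$is_mqtl),
              cfg$seed))
  invisible(x)
}

#' Simulate external GWAS summary statistics
#'
#' Emulates a large external biobank GWAS of BMI: per-SNP effect estimates
#' are drawn around the generator's true per-allele effects with sampling
#' error appropriate for `n_external` samples, so that the table can stand
#' in for published summary statistics in the Mendelian randomization
#' stages.
#'
#' @param truth truth tables from [simulate_study()] (needs `truth$snps`).
#' @param n_external external GWAS sample size.
#' @param seed integer seed for the sampling error draws.
#' @param trait_sd phenotypic SD of the external trait (kg/m^2).
#' @return data frame with columns snp, chr, pos, effect_allele,
#'   other_allele, beta, se, p, n.
#' @export
simulate_gwas_sumstats <- function(truth, n_external, seed = 1L,
                                   trait_sd = 4) {
  assert_that(!is.null(truth$snps), "truth must contain a snps table")
  assert_that(n_external >= 1, "n_external must be >= 1")
  set.seed(as.integer(seed))
  s <- truth$snps
  se <- trait_sd / sqrt(n_external * 2 * s$maf * (1 - s$maf))
  beta <- s$bmi_effect + stats::rnorm(nrow(s), 0, se)
  data.frame(
    snp = s$snp, chr = s$chr, pos = s$pos,
    effect_allele = "G", other_allele = "A",
    beta = beta, se = se, p = z_pvalue(beta, se), n = n_external,
    stringsAsFactors = FALSE
  )
}
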