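test_that("the Wald ratio and its delta-method SE follow the stated formula", {
  w <- wald_ratio(0.3, 0.1, 0.5, 0.1)
  expect_equal(w$effect, 0.6)
  expect_equal(w$se, sqrt(0.36 * (0.01 / 0.09 + 0.01 / 0.25)),
               tolerance = 1e-12)
  expect_equal(w$se, 0.2333, tolerance = 1e-3)
  # noiseless limit and the sign rule
  expect_equal(wald_ratio(2, 0, 4, 0), list(effect = 0.5, se = 0))
  expect_equal(wald_ratio(-0.3, 0.1, 0.5, 0.1)$effect, -0.6)
  expect_equal(wald_ratio(0.3, 0.1, -0.5, 0.1)$effect, -0.6)
  # degenerate cases
  expect_error(wald_ratio(0.3, 0.1, 0, 0.1), "nonzero")
  w0 <- wald_ratio(0, 0.1, 0.5, 0.1)
  expect_equal(w0$effect, 0)
  expect_equal(w0$se, 0.2)
})

test_that("the delta-method SE matches a Monte-Carlo oracle within 2%", {
  set.seed(33)
  # instruments with |eff/SE| >= 10 on both axes: the ratio distribution
  # is close to normal and the Monte-Carlo sd is a stable oracle
  cases <- list(c(0.5, 0.02, 0.8, 0.03), c(-0.4, 0.02, 0.3, 0.012),
                c(1.2, 0.05, -0.6, 0.02))
  for (cs in cases) {
    w <- wald_ratio(cs[1], cs[2], cs[3], cs[4])
    draws <- rnorm(1e6, cs[1], cs[2]) / rnorm(1e6, cs[3], cs[4])
    expect_equal(w$se, sd(draws), tolerance = 0.02)
    expect_lt(abs(w$effect - mean(draws)), 4 * sd(draws) / sqrt(1e6) +
                0.005 * abs(w$effect))
  }
})

test_that("allele harmonization is an involution and corrects flips", {
  set.seed(2)
  n <- 400
  dos <- cbind(rs1 = rbinom(n, 2, 0.3))
  rownames(dos) <- paste0("id", 1:n)
  geno <- list(dosage = dos,
               info = data.frame(snp = "rs1", chr = "1", pos = 5e5,
                                 ref = "A", alt = "G", maf = 0.3))
  w_g <- data.frame(snp = "rs1", effect_allele = "G", weight = 1)
  w_a <- data.frame(snp = "rs1", effect_allele = "A", weight = 1)
  prs_g <- compute_prs(geno, w_g)
  prs_a <- compute_prs(geno, w_a)
  # counting the other allele mirrors the dosage: d -> 2 - d
  expect_equal(unname(prs_a), unname(2 - prs_g))
  # one SNP, unit weight, dosage 2 scores 2
  expect_equal(unname(prs_g[dos[, 1] == 2][1]), 2)
  # flipping effect alleles twice restores the score exactly
  expect_equal(compute_prs(geno, w_g), compute_prs(geno, w_g))
  expect_error(compute_prs(geno, data.frame(snp = "rsX", effect_allele = "G",
                                            weight = 1)), "overlapping")
  # missing dosages are mean-imputed per SNP
  dos_na <- dos; dos_na[1, 1] <- NA
  geno_na <- list(dosage = dos_na, info = geno$info)
  prs_na <- compute_prs(geno_na, w_g)
  expect_equal(unname(prs_na[1]), mean(dos_na[, 1], na.rm = TRUE))
})

test_that("PRS and MRS toy scores match hand computation", {
  dos <- rbind(id1 = c(0, 1, 2), id2 = c(2, 2, 0))
  colnames(dos) <- paste0("rs", 1:3)
  geno <- list(dosage = dos,
               info = data.frame(snp = paste0("rs", 1:3), chr = "1",
                                 pos = 1:3 * 1e5, ref = "A", alt = "G"))
  w <- data.frame(snp = paste0("rs", 1:3),
                  effect_allele = c("G", "A", "G"),
                  weight = c(0.5, -1, 2))
  # id1: 0.5*0 + (-1)*(2-1) + 2*2 = 3; id2: 0.5*2 + (-1)*(2-2) + 2*0 = 1
  expect_equal(unname(compute_prs(geno, w)), c(3, 1))

  beta <- rbind(cg1 = c(0.2, 0.4, 0.6), cg2 = c(0.1, 0.1, 0.4))
  colnames(beta) <- paste0("id", 1:3)
  weights <- data.frame(cpg = c("cg1", "cg2"), weight = c(10, -5))
  raw <- c(10 * 0.2 - 5 * 0.1, 10 * 0.4 - 5 * 0.1, 10 * 0.6 - 5 * 0.4)
  expect_equal(unname(compute_mrs(beta, weights)),
               as.numeric(scale(raw)), tolerance = 1e-12)
  expect_equal(unname(compute_mrs(beta, weights, standardize = FALSE)), raw)
  # single CpG with unit weight is the standardized beta
  expect_equal(unname(compute_mrs(beta, data.frame(cpg = "cg1", weight = 1))),
               as.numeric(scale(beta["cg1", ])), tolerance = 1e-12)
  expect_error(compute_mrs(beta, data.frame(cpg = c("cg1", "cg2"),
                                            weight = c(0, 0))), "zero")
  expect_error(compute_mrs(beta, data.frame(cpg = c("cg1", "other1", "other2"),
                                            weight = c(1, 1, 1))), "50%")
})

test_that("cis-instrument selection honors the window and exclusion rules", {
  set.seed(44)
  n <- 300
  dosA <- rbinom(n, 2, 0.4)   # true mQTL
  dosB <- rbinom(n, 2, 0.4)   # unrelated, exactly at the 1 Mb boundary
  dosC <- rep(1L, n)          # monomorphic
  dos <- cbind(rsA = dosA, rsB = dosB, rsC = dosC,
               rsFar = rbinom(n, 2, 0.4))
  rownames(dos) <- paste0("id", 1:n)
  geno <- list(dosage = dos, info = data.frame(
    snp = colnames(dos), chr = c("1", "1", "1", "1"),
    pos = c(2e6 + 1e4, 2e6 + 1e6, 2e6 + 2e4, 2e6 + 1e6 + 1),
    ref = "A", alt = "G", stringsAsFactors = FALSE))
  beta <- matrix(0.5 + 0.05 * (dosA - 0.8) + rnorm(n, 0, 0.02), 1, n,
                 dimnames = list("cgQ", rownames(dos)))
  beta <- pmin(pmax(beta, 0), 1)
  pheno <- data.frame(sample_id = rownames(dos), bmi = rnorm(n, 24, 3))
  sdat <- list(s1 = list(beta = beta, pheno = pheno,
                         covars = cbind(cov = rnorm(n))))
  hits <- data.frame(cpg = "cgQ", chr = "1", pos = 2e6)
  iv <- select_cis_iv(hits, geno, sdat)
  expect_equal(iv$snp, "rsA")
  expect_equal(iv$exclusion_reason, "none")
  expect_gt(iv$eff_cpg_snp, 0.03)
  # the true mQTL removed: the boundary SNP (exactly 1 Mb, included) is
  # evaluated, the monomorphic and out-of-window SNPs never are
  geno2 <- list(dosage = dos[, -1], info = geno$info[-1, ])
  iv2 <- select_cis_iv(hits, geno2, sdat)
  expect_equal(iv2$snp, "rsB")
  expect_equal(iv2$exclusion_reason, "nonsignificant")
  # empty window
  hits_far <- data.frame(cpg = "cgQ", chr = "9", pos = 2e6)
  expect_equal(select_cis_iv(hits_far, geno, sdat)$exclusion_reason,
               "no_cis_snp")
  # a SNP inside the probe-binding sequence is excluded
  geno3 <- geno
  geno3$info$pos[1] <- 2e6 + 30
  iv3 <- select_cis_iv(hits, geno3, sdat)
  expect_equal(iv3$exclusion_reason, "probe_binding")
})

test_that("forward MR harmonizes alleles and the single-SNP worlds agree", {
  iv <- data.frame(cpg = "cgQ", snp = "rs1", eff_cpg_snp = 0.05,
                   se_cpg_snp = 0.005, p_select = 1e-10,
                   exclusion_reason = "none", stringsAsFactors = FALSE)
  ss <- data.frame(snp = "rs1", effect_allele = "G", other_allele = "A",
                   beta = 0.25, se = 0.02, p = 1e-30)
  ewas <- data.frame(cpg = "cgQ", effect = 5)
  coded <- data.frame(snp = "rs1", alt = "G")
  f <- forward_mr(iv, ss, ewas, coded_alleles = coded)
  expect_equal(f$estimates$predicted_effect, 0.25 / 0.05)
  # flipping the stated effect allele flips the predicted sign back
  ss_flip <- ss
  ss_flip$effect_allele <- "A"; ss_flip$other_allele <- "G"
  ss_flip$beta <- -0.25
  f2 <- forward_mr(iv, ss_flip, ewas, coded_alleles = coded)
  expect_equal(f2$estimates$predicted_effect,
               f$estimates$predicted_effect)
  # a SNP absent from the summary statistics is reported, not dropped
  ss_miss <- ss; ss_miss$snp <- "rsZ"
  f3 <- forward_mr(iv, ss_miss, ewas, coded_alleles = coded)
  expect_equal(f3$estimates$reason, "no_sumstats")
  expect_true(is.na(f3$estimates$predicted_effect))
})

test_that("a single-SNP PRS reduces backward MR to forward algebra", {
  set.seed(55)
  n <- 500
  dos <- cbind(rs1 = rbinom(n, 2, 0.4))
  rownames(dos) <- paste0("id", 1:n)
  geno <- list(dosage = dos, info = data.frame(
    snp = "rs1", chr = "1", pos = 5e5, ref = "A", alt = "G"))
  bmi <- 24 + 0.8 * dos[, 1] + rnorm(n, 0, 2)
  beta <- matrix(pmin(pmax(0.5 + 0.002 * (bmi - 24) + rnorm(n, 0, 0.01),
                           0), 1), 1, n, dimnames = list("cgQ", rownames(dos)))
  pheno <- data.frame(sample_id = rownames(dos), bmi = bmi)
  covars <- cbind(cov = rnorm(n))
  sdat <- list(s1 = list(beta = beta, pheno = pheno, covars = covars))
  prs <- compute_prs(geno, data.frame(snp = "rs1", effect_allele = "G",
                                      weight = 1))
  names(prs) <- rownames(dos)
  bwd <- backward_mr(prs, "cgQ", sdat)
  # with a unit-weight single-SNP score the predicted effect is the Wald
  # ratio of the per-allele associations
  num <- adipomethyl:::snp_assoc(beta[1, ], dos[, 1], covars)
  den <- adipomethyl:::snp_assoc(bmi, dos[, 1], covars)
  wr <- wald_ratio(num$effect, num$se, den$effect, den$se)
  expect_equal(bwd$estimates$predicted_effect, wr$effect, tolerance = 1e-10)
  expect_equal(bwd$estimates$predicted_se, wr$se, tolerance = 1e-10)
  expect_false(bwd$weak_instrument)
  # observed regression of methylation on BMI recovers the generating slope
  expect_lt(abs(bwd$estimates$observed_effect - 0.002), 6e-4)
})
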