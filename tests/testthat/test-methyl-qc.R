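test_that("background correction subtracts the 5th percentile of negatives", {
  # negative controls 10, 20, ..., 100: the 5th percentile (type-7
  # interpolation) is 14.5, cross-checked by sorting
  neg <- matrix(seq(10, 100, 10), ncol = 1)
  expect_equal(unname(stats::quantile(neg[, 1], 0.05)), 14.5)
  M <- matrix(c(114.5, 50, 5), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
  d <- toy_intensity(M, U = matrix(1000, 3, 1, dimnames = dimnames(M)),
                     neg = neg)
  bc <- background_correct(d)
  expect_equal(unname(bc$M[, 1]), c(100, 35.5, 0))  # floors at zero
  # all-zero negatives leave the data unchanged
  d0 <- toy_intensity(M, neg = matrix(0, 2, 1))
  expect_equal(background_correct(d0)$M, d0$M)
  # controls are corrected too, so the re-estimated background is tiny and
  # a second pass is near-idempotent
  b2 <- stats::quantile(bc$controls[, 1], 0.05)
  expect_lt(b2, 3)
  expect_equal(background_correct(bc)$M[1, 1], bc$M[1, 1] - b2,
               ignore_attr = TRUE)
  # missing negative controls is a hard error
  d$control_type <- rep("NORM_C", length(d$control_type))
  expect_error(background_correct(d), "NEGATIVE")
})

test_that("detection P is the normal upper tail against the background", {
  M <- matrix(c(50, 1e6, 119.6 - 50), 3, 1,
              dimnames = list(paste0("p", 1:3), "s1"))
  U <- matrix(50, 3, 1, dimnames = dimnames(M))
  # background: mean 100, sd 10
  negs <- c(100 - 10 * sqrt(1 / 2), 100 + 10 * sqrt(1 / 2))
  d <- toy_intensity(M, U = U, neg = matrix(negs, 2, 1))
  detp <- detection_pvalues(d)
  expect_equal(detp["p1", 1], 0.5)                  # signal equals background mean
  expect_lt(detp["p2", 1], 1e-300)                  # strong signal
  expect_equal(detp["p3", 1],
               pnorm(119.6, 100, 10, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(detp["p3", 1], 0.025, tolerance = 1e-3)
  # detP is monotone non-increasing in total signal
  ord <- order(M + U)
  expect_true(all(diff(detp[ord, 1]) <= 0))
  # zero-sd background degenerates with a warning
  d2 <- toy_intensity(M, U = U, neg = matrix(c(100, 100), 2, 1))
  expect_warning(detection_pvalues(d2), "step function")
})

test_that("sample filters implement the missingness and sex-check rules", {
  set.seed(1)
  n_auto <- 100
  probes <- c(paste0("a", 1:n_auto), paste0("x", 1:10), paste0("y", 1:10))
  samples <- c("good", "miss6", "sexswap")
  M <- matrix(3000, 120, 3, dimnames = list(probes, samples))
  U <- matrix(3000, 120, 3, dimnames = dimnames(M))
  # miss6 fails 6% of autosomal probes (background-level signal)
  M[1:6, "miss6"] <- 10; U[1:6, "miss6"] <- 10
  # male-like intensities for good & miss6 (diff 0 > -2), female-like for
  # sexswap (chrY at background)
  M[101:110, ] <- 1500; U[101:110, ] <- 1500
  M[111:120, "sexswap"] <- 40; U[111:120, "sexswap"] <- 40
  d <- toy_intensity(M, U = U, chr = rep(c("1", "X", "Y"), c(100, 10, 10)),
                     neg = matrix(c(80, 120), 2, 3))
  detp <- detection_pvalues(d)
  sheet <- data.frame(sample_id = samples, sex = "male",
                      stringsAsFactors = FALSE)
  fs <- filter_samples(d, detp, sheet)
  tab <- fs$samples
  expect_false(tab$excluded[tab$sample_id == "good"])  # sexcheck_diff = 0, male: retained
  expect_equal(tab$reason[tab$sample_id == "miss6"], "missingness")
  expect_equal(tab$reason[tab$sample_id == "sexswap"], "sex_mismatch")
  expect_lt(tab$sexcheck_diff[tab$sample_id == "sexswap"], -2)
  expect_equal(colnames(fs$data$M), "good")
})

test_that("probe filters apply thresholds strictly and drop sex chromosomes", {
  # 10 probes x 20 samples: p1 fails detP in 25% of samples, p2 exactly 5%
  # (retained: rule is strictly greater), p3 fails beadcount, p4-p5 on
  # chrX, rest clean -> 6 retained
  probes <- paste0("p", 1:10)
  samples <- sprintf("s%02d", 1:20)
  M <- matrix(3000, 10, 20, dimnames = list(probes, samples))
  U <- M
  M["p1", 1:5] <- 10; U["p1", 1:5] <- 10
  M["p2", 1] <- 10; U["p2", 1] <- 10
  bead <- matrix(10L, 10, 20, dimnames = dimnames(M))
  bead["p3", 1:2] <- 1L
  d <- toy_intensity(M, U = U, beadcount = bead,
                     chr = c(rep("1", 3), "X", "X", rep("2", 5)),
                     neg = matrix(c(80, 120), 2, 20))
  detp <- detection_pvalues(d)
  fp <- filter_probes(d, detp)
  tab <- fp$probes
  expect_equal(tab$reason[tab$probe_id == "p1"], "detection_p")
  expect_false(tab$excluded[tab$probe_id == "p2"])
  expect_equal(tab$reason[tab$probe_id == "p3"], "beadcount")
  expect_equal(tab$reason[tab$probe_id == "p4"], "sex_chromosome")
  expect_equal(nrow(fp$data$M), 6)
  expect_false(any(fp$data$manifest$chr %in% c("X", "Y")))
})

test_that("quantile normalization matches the sort-average-unsort oracle", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  qn <- quantile_normalize(m, c("g", "g"))
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical samples are a fixed point
  m2 <- matrix(rep(c(5, 1, 3), 3), 3, 3,
               dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  expect_equal(quantile_normalize(m2, rep("g", 3)), m2)
  # ties: average of tied ranks, against a brute-force oracle
  set.seed(9)
  m3 <- matrix(sample(1:3, 20, replace = TRUE), 5, 4,
               dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  ref <- rowMeans(apply(m3, 2, sort))
  oracle <- apply(m3, 2, function(x) {
    r <- rank(x, ties.method = "average")
    sapply(r, function(ri) mean(ref[c(floor(ri), ceiling(ri))]))
  })
  dimnames(oracle) <- dimnames(m3)
  expect_equal(quantile_normalize(m3, rep("g", 4)), oracle)
  # groups are normalized independently and size-1 groups warn
  expect_warning(quantile_normalize(m3, c("g", "g", "g", "solo")), "single")
})

test_that("beta values follow M/(M+U+100)", {
  M <- matrix(c(0, 100, 900), 3, 1, dimnames = list(paste0("p", 1:3), "s"))
  U <- matrix(0, 3, 1, dimnames = dimnames(M))
  d <- toy_intensity(M, U = U)
  expect_equal(unname(compute_beta(d)[, 1]), c(0, 0.5, 0.9))
  d$M[1, 1] <- -5
  expect_error(compute_beta(d), "negative")
})

test_that("end-to-end QC excludes exactly the injected corrupt samples", {
  b <- shared_bundle()
  proc <- shared_processed()
  truth <- b$truth$samples
  for (v in c("baseline", "followup")) {
    rep <- proc[[v]]$report
    excl <- rep$samples[rep$samples$excluded, ]
    expect_setequal(excl$sample_id[excl$reason == "missingness"],
                    truth$sample_id[truth$corrupt_background])
    expect_setequal(excl$sample_id[excl$reason == "sex_mismatch"],
                    truth$sample_id[truth$sex_swapped])
    # default thresholds are echoed in the report
    expect_equal(rep$thresholds$detp, 1e-16)
    expect_equal(rep$thresholds$sample_missing_frac, 0.05)
    expect_equal(rep$thresholds$beadcount_min, 3)
    expect_equal(rep$thresholds$probe_fail_frac, 0.05)
    expect_equal(rep$thresholds$sexcheck_cutoff, -2)
    # no sex-chromosome probes and no out-of-range values post-QC
    bm <- proc[[v]]$beta
    expect_false(any(bm$manifest$chr %in% c("X", "Y")))
    expect_true(all(bm$beta >= 0 & bm$beta < 1))
  }
})

test_that("QC is order-stable under sample permutation", {
  b <- shared_bundle()
  d <- b$intensities$followup
  ph <- b$phenotypes[b$phenotypes$visit == "followup", ]
  groups <- setNames(ph$stratum[match(colnames(d$M), ph$sample_id)],
                     colnames(d$M))
  set.seed(11)
  perm <- sample(ncol(d$M))
  d2 <- d
  d2$M <- d$M[, perm]; d2$U <- d$U[, perm]
  d2$beadcount <- d$beadcount[, perm]; d2$controls <- d$controls[, perm]
  q1 <- run_qc(d, ph, groups)
  q2 <- run_qc(d2, ph, groups)
  common <- colnames(q1$beta$beta)
  expect_setequal(common, colnames(q2$beta$beta))
  expect_equal(q1$beta$beta[, common], q2$beta$beta[, common])
})
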