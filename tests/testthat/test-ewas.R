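make_stratum <- function(n = 40, p = 6, seed = 1, effect = 0,
                         stratum = "s1") {
  set.seed(seed)
  beta <- matrix(runif(p * n, 0.2, 0.8), p, n,
                 dimnames = list(paste0("cg", 1:p), paste0("id", 1:n)))
  covars <- cbind(age = runif(n, 30, 70), sex = rbinom(n, 1, 0.5),
                  smoking = rbinom(n, 1, 0.3))
  trait <- 24 + 0.05 * covars[, "age"] + effect * beta[1, ] + rnorm(n, 0, 2)
  pheno <- data.frame(sample_id = colnames(beta), bmi = trait,
                      stringsAsFactors = FALSE)
  list(beta = beta, pheno = pheno, covars = covars, stratum = stratum)
}

test_that("fit_ewas equals the per-probe lm fit", {
  d <- make_stratum(n = 30, p = 5, seed = 4, effect = 8)
  est <- fit_ewas(d$beta, d$pheno, d$covars, "bmi", "s1")
  for (j in 1:5) {
    fit <- lm(d$pheno$bmi ~ d$beta[j, ] + d$covars)
    cf <- summary(fit)$coefficients[2, ]
    expect_equal(est$effect[j], unname(cf["Estimate"]), tolerance = 1e-8)
    expect_equal(est$se[j], unname(cf["Std. Error"]), tolerance = 1e-8)
    expect_equal(est$p[j], unname(cf["Pr(>|t|)"]), tolerance = 1e-8)
  }
  expect_true(all(est$n == 30))
  expect_equal(est$beta_mean, unname(rowMeans(d$beta)))
})

test_that("the noise-free limit recovers the generating slope", {
  set.seed(2)
  n <- 200
  beta <- matrix(runif(n, 0.2, 0.8), 1, n,
                 dimnames = list("cg1", paste0("id", 1:n)))
  pheno <- data.frame(sample_id = colnames(beta),
                      bmi = 10 * beta[1, ] + rnorm(n, 0, 1e-8))
  est <- fit_ewas(beta, pheno, cbind(cov = rnorm(n)), "bmi")
  expect_equal(est$effect, 10, tolerance = 1e-6)
})

test_that("effects are equivariant under trait scaling", {
  d <- make_stratum(n = 50, p = 4, seed = 6, effect = 5)
  e1 <- fit_ewas(d$beta, d$pheno, d$covars, "bmi")
  d$pheno$bmi <- 3 * d$pheno$bmi
  e2 <- fit_ewas(d$beta, d$pheno, d$covars, "bmi")
  expect_equal(e2$effect, 3 * e1$effect, tolerance = 1e-10)
  expect_equal(e2$se, 3 * e1$se, tolerance = 1e-10)
  expect_equal(e2$p, e1$p, tolerance = 1e-10)
})

test_that("degenerate probes and covariates are handled explicitly", {
  d <- make_stratum(n = 30, p = 3, seed = 7)
  d$beta[2, ] <- 0.5
  est <- fit_ewas(d$beta, d$pheno, d$covars, "bmi")
  expect_true(is.na(est$effect[2]))
  expect_equal(est$reason[2], "constant_beta")
  expect_false(any(is.na(est$effect[c(1, 3)])))
  # collinear covariate is dropped with a warning
  cov2 <- cbind(d$covars, dup = 2 * d$covars[, "age"])
  expect_warning(fit_ewas(d$beta, d$pheno, cov2, "bmi"), "collinear")
})

test_that("null EWAS P-values are uniform", {
  set.seed(30)
  n <- 150; p <- 2000
  beta <- matrix(runif(p * n, 0.2, 0.8), p, n,
                 dimnames = list(paste0("cg", 1:p), paste0("id", 1:n)))
  pheno <- data.frame(sample_id = colnames(beta), bmi = rnorm(n, 24, 3))
  est <- fit_ewas(beta, pheno, cbind(cov = rnorm(n)), "bmi")
  frac <- mean(est$p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / p))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / p))
})

test_that("conditional analysis distinguishes mediated from independent signals", {
  set.seed(21)
  n <- 1500
  x1 <- runif(n, 0.2, 0.8)
  x2_med <- x1 + rnorm(n, 0, 0.06)          # shares x1's signal entirely
  x2_ind <- runif(n, 0.2, 0.8)              # independent causal CpG
  x_dup <- x1                               # exact duplicate
  trait <- 24 + 20 * x1 + 15 * x2_ind + rnorm(n, 0, 2)
  beta <- rbind(cgA = x1, cgB = x2_med, cgC = x2_ind, cgD = x_dup)
  colnames(beta) <- paste0("id", 1:n)
  pheno <- data.frame(sample_id = colnames(beta), bmi = trait)
  covars <- cbind(cov = rnorm(n))
  sdat <- list(s1 = list(beta = beta, pheno = pheno, covars = covars))
  hits <- data.frame(cpg = c("cgA", "cgB", "cgC", "cgD"),
                     chr = c("1", "1", "2", "3"),
                     pos = c(1e6, 1.2e6, 5e6, 1e6),
                     p = c(1e-10, 1e-4, 1e-6, 1e-9))
  # lone-locus CpGs (cgC, cgD alone on their chromosomes) are not tested
  res <- conditional_scan(sdat, hits, "bmi")
  expect_equal(res$cpg, "cgB")
  expect_false(res$secondary)               # fully mediated by the sentinel
  # an independent causal CpG in the same locus is detected
  hits2 <- hits
  hits2$chr <- "1"; hits2$pos <- c(1e6, 1.2e6, 1.3e6, 1.4e6)
  res2 <- conditional_scan(sdat, hits2, "bmi")
  expect_true(res2$secondary[res2$cpg == "cgC"])
  expect_equal(res2$flag[res2$cpg == "cgD"], "collinear")
})

test_that("cis windows are closed, chromosome-matched and symmetric", {
  set.seed(12)
  n <- 200
  beta <- matrix(runif(2 * n, 0.2, 0.8), 2, n,
                 dimnames = list(c("cgA", "cgB"), paste0("id", 1:n)))
  expr <- rbind(trA = 2 - 3 * beta["cgA", ] + rnorm(n, 0, 0.2),
                trFar = rnorm(n), trOther = rnorm(n))
  colnames(expr) <- colnames(beta)
  coords <- data.frame(transcript_id = c("trA", "trFar", "trOther"),
                       chr = c("1", "1", "2"),
                       start = c(2e6 + 1e6, 2e6 + 1e6 + 1, 2e6))
  hits <- data.frame(cpg = c("cgA", "cgB"), chr = c("1", "2"),
                     pos = c(2e6, 99e6))
  es <- list(s1 = list(expr = expr, beta = beta,
                       covars = cbind(age = runif(n, 30, 70))))
  res <- cis_expression_assoc(hits, es, coords)
  # exactly 1 Mb away is included; 1 bp beyond and other chromosomes are not
  expect_equal(res$transcript[res$cpg == "cgA"], "trA")
  expect_false("trFar" %in% res$transcript)
  expect_false("trOther" %in% res$transcript)
  expect_true("cgB" %in% attr(res, "untested"))
  # simulated negative effect is recovered with the correct sign
  expect_lt(res$effect[res$cpg == "cgA"], 0)
  expect_lt(res$p[res$cpg == "cgA"], 1e-6)
  expect_true(all(res$p_fdr >= res$p))
})

test_that("expression preparation filters, residualizes and normalizes", {
  set.seed(5)
  n <- 100
  expr <- matrix(rnorm(12 * n, 8, 1), 12, n,
                 dimnames = list(paste0("tr", 1:12), paste0("id", 1:n)))
  expr[11, ] <- 0                                   # all-zero transcript
  expr[12, ] <- c(rep(1, 95), rep(8, 5))            # low in 95% of samples
  covars <- data.frame(sex = sample(c("male", "female"), n, TRUE),
                       batch = rnorm(n))
  out <- prepare_expression(expr, ctrl_mean = 4, covars)
  expect_equal(nrow(out), 10)                       # both low ones dropped
  expect_false(any(c("tr11", "tr12") %in% rownames(out)))
  # rank-inverse-normal columns: mean 0 and exact normal quantile spacing
  expect_equal(unname(rowMeans(out)), rep(0, 10), tolerance = 1e-10)
  expect_equal(sort(out[1, ]), sort(out[2, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(sort(out[1, ])),
               qnorm((1:n - 3 / 8) / (n + 1 - 3 / 4)), tolerance = 1e-12)
  expect_error(prepare_expression(expr[11:12, , drop = FALSE], 4, covars),
               "fewer than 10")
})

test_that("below-detection-limit biomarkers are imputed at 0.9 x minimum", {
  tab <- data.frame(a = c(2, 4, 0.1), b = c(1, 2, 3), c = c(0.1, 0.2, 0.1))
  lim <- c(a = 1, c = 5)
  expect_warning(out <- prepare_biomarkers(tab, lim), "below the detection")
  expect_equal(out$a, c(2, 4, 1.8))
  expect_equal(out$b, tab$b)                        # untouched column
  expect_true(all(is.na(out$c)))                    # everything below limit
  # logical-mask interface, two entries below with observed minimum 5
  tab2 <- data.frame(m = c(5, 9, 0.5, 0.2))
  mask <- cbind(m = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(prepare_biomarkers(tab2, mask)$m, c(5, 9, 4.5, 4.5))
  # no below-limit entries: identity
  expect_equal(prepare_biomarkers(tab2, cbind(m = rep(FALSE, 4)))$m, tab2$m)
})
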