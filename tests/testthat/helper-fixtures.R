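# Shared fixtures and independent oracles. Bundles are built once per test
# run and cached, since several test files exercise the same cohort.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# moderate cohort with injected QC failures and both causal and mQTL probes
shared_bundle <- function() {
  cached("shared_bundle", function() {
    simulate_study(synth_config(
      n_per_stratum = 60, n_probes = 400, n_snps = 150,
      frac_causal_bmi_to_cpg = 0.1, frac_mqtl = 0.1,
      n_corrupt_background = 2, n_sex_swap = 2, seed = 42))
  })
}

shared_processed <- function() {
  cached("shared_processed", function() {
    suppressWarnings(process_bundle(shared_bundle()))
  })
}

# larger two-wave cohort for cross-lagged and biomarker models
clpm_bundle <- function() {
  cached("clpm_bundle", function() {
    simulate_study(synth_config(
      n_per_stratum = 200, n_probes = 300, frac_causal_bmi_to_cpg = 0.2,
      mrs_il6_path = 0.4, seed = 77))
  })
}

clpm_processed <- function() {
  cached("clpm_processed", function() {
    suppressWarnings(process_bundle(clpm_bundle()))
  })
}

longitudinal_waves <- function(processed) {
  lapply(c(baseline = "baseline", followup = "followup"), function(v) {
    p <- processed[[v]]
    ids <- p$pheno$sample_id[p$pheno$stratum == "longitudinal_chinese"]
    list(beta = p$beta$beta[, ids, drop = FALSE],
         pheno = p$pheno[match(ids, p$pheno$sample_id), ],
         covars_meth = p$covars[ids, !colnames(p$covars) %in%
                                  c("age", "sex", "smoking"), drop = FALSE])
  })
}

# hand-built tiny intensity object for QC unit tests
toy_intensity <- function(M, U = NULL, beadcount = NULL, chr = NULL,
                          neg = NULL) {
  if (is.null(neg)) neg <- matrix(c(10, 20), 2, ncol(M))
  if (is.null(U)) U <- matrix(1000, nrow(M), ncol(M), dimnames = dimnames(M))
  if (is.null(beadcount)) {
    beadcount <- matrix(10L, nrow(M), ncol(M), dimnames = dimnames(M))
  }
  if (is.null(chr)) chr <- rep("1", nrow(M))
  manifest <- data.frame(probe_id = rownames(M), chr = chr,
                         pos = seq_len(nrow(M)) * 1000,
                         relation_to_island = "OpenSea",
                         nearest_gene = "G", cross_reactive = FALSE,
                         snp_affected = FALSE, stringsAsFactors = FALSE)
  colnames(neg) <- colnames(M)
  intensity_data(M, U, beadcount, neg, rep("NEGATIVE", nrow(neg)), manifest)
}

# brute-force BH definition: q_i = min over j with p_(j) >= p_i of m p_(j)/j
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- sapply(seq_len(m), function(i) min(m * ps[i:m] / (i:m)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided binomial P by pmf enumeration
binom_p_enum <- function(k, n, p0 = 0.5) {
  pmf <- stats::dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# independent CLPM oracle: path coefficients solved from the empirical
# covariance matrix (moment/GLS route), not from residual-based OLS
clpm_moment_oracle <- function(x_b, x_f, y_b, y_f) {
  S <- stats::cov(cbind(x_b, y_b, x_f, y_f))
  Sbb <- S[1:2, 1:2]
  byf <- solve(Sbb, S[1:2, "y_f"])
  bxf <- solve(Sbb, S[1:2, "x_f"])
  list(c_xy = byf["x_b"], a_y = byf["y_b"],
       a_x = bxf["x_b"], c_yx = bxf["y_b"])
}
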