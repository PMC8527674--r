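# Two-wave cross-lagged panel models (CLPM). For two standardized
# variables X and Y observed at baseline (b) and follow-up (f), the
# saturated path model is
#
#   Y_f = a_y Y_b + c_xy X_b + e1
#   X_f = a_x X_b + c_yx Y_b + e2
#
# together with the baseline correlation rho = cor(X_b, Y_b) and the
# residual correlation cor(e1, e2). For this saturated model, maximum
# likelihood path estimates coincide with the OLS multiple-regression
# coefficients, and the comparative fit index is exactly 1.

#' Residualize on covariates and Z-standardize
#'
#' OLS residuals of `values` on the covariates (with intercept), then
#' centered and scaled to unit variance.
#'
#' @param values numeric vector.
#' @param covars optional data frame / matrix of covariates (NULL for an
#'   intercept-only model, i.e. a plain z-score).
#' @return standardized residual vector (mean 0, sd 1).
#' @export
residualize_standardize <- function(values, covars = NULL) {
  assert_that(!anyNA(values), "values must be complete")
  if (is.null(covars)) {
    r <- values - mean(values)
  } else {
    X <- cbind(1, as.matrix(covars))
    r <- qr.resid(qr(X), values)
  }
  s <- stats::sd(r)
  if (s < 1e-12) stop("zero residual variance; cannot standardize",
                      call. = FALSE)
  as.numeric((r - mean(r)) / s)
}

#' Fit the saturated two-wave cross-lagged panel model
#'
#' @param x_base,x_fu,y_base,y_fu standardized vectors (mean 0, sd 1 to
#'   1e-6) over the same samples.
#' @param df_adjust use the OLS small-sample denominator n - p for path
#'   standard errors (TRUE, default) or the ML denominator n.
#' @return a `clpm_fit` object: rho_baseline, a_x, a_y, c_xy, c_yx with
#'   SEs and two-sided P-values, residual correlation, CFI and n.
#' @export
fit_clpm <- function(x_base, x_fu, y_base, y_fu, df_adjust = TRUE) {
  n <- length(x_base)
  assert_that(all(lengths(list(x_fu, y_base, y_fu)) == n),
              "all four vectors must have equal length")
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  for (v in list(x_base, x_fu, y_base, y_fu)) {
    if (abs(mean(v)) > 1e-6 || abs(stats::sd(v) - 1) > 1e-6) {
      stop("inputs must be standardized (mean 0, sd 1); see residualize_standardize()",
           call. = FALSE)
    }
  }
  X <- cbind(x_base = x_base, y_base = y_base)
  fit_one <- function(y) {
    qx <- qr(X)
    b <- qr.coef(qx, y)
    r <- qr.resid(qx, y)
    denom <- if (df_adjust) n - ncol(X) else n
    sigma2 <- sum(r^2) / denom
    vc <- sigma2 * chol2inv(qr.R(qx))
    se <- sqrt(diag(vc))
    list(coef = b, se = se, resid = r,
         p = 2 * stats::pt(-abs(b / se), n - ncol(X)))
  }
  fy <- fit_one(y_fu)   # y_f ~ x_b + y_b
  fx <- fit_one(x_fu)   # x_f ~ x_b + y_b
  structure(list(
    rho_baseline = stats::cor(x_base, y_base),
    a_x = fx$coef["x_base"], a_x_se = fx$se[1], a_x_p = fx$p[1],
    a_y = fy$coef["y_base"], a_y_se = fy$se[2], a_y_p = fy$p[2],
    c_xy = fy$coef["x_base"], c_xy_se = fy$se[1], c_xy_p = fy$p[1],
    c_yx = fx$coef["y_base"], c_yx_se = fx$se[2], c_yx_p = fx$p[2],
    resid_cor = stats::cor(fy$resid, fx$resid),
    cfi = 1,  # saturated model: model chi-square is 0 by construction
    n = n), class = "clpm_fit")
}

#' @export
print.clpm_fit <- function(x, ...) {
  cat(sprintf("Two-wave CLPM (n = %d, CFI = %g)\n", x$n, x$cfi))
  cat(sprintf("  baseline correlation: %.3f\n", x$rho_baseline))
  cat(sprintf("  autoregressive: a_x = %.3f (p=%.3g), a_y = %.3f (p=%.3g)\n",
              x$a_x, x$a_x_p, x$a_y, x$a_y_p))
  cat(sprintf("  cross paths: X->Y %.3f (p=%.3g), Y->X %.3f (p=%.3g)\n",
              x$c_xy, x$c_xy_p, x$c_yx, x$c_yx_p))
  invisible(x)
}

clpm_row <- function(fit, id) {
  data.frame(id = id, n = fit$n, rho_base = fit$rho_baseline,
             a_x = fit$a_x, a_y = fit$a_y,
             c_xy = fit$c_xy, c_xy_se = fit$c_xy_se, c_xy_p = fit$c_xy_p,
             c_yx = fit$c_yx, c_yx_se = fit$c_yx_se, c_yx_p = fit$c_yx_p,
             resid_cor = fit$resid_cor, cfi = fit$cfi,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-lagged scan of BMI against significant CpGs
#'
#' For each CpG, BMI at each wave is residualized on age and sex, the CpG
#' beta on age, sex, cell fractions and control-probe PCs (per wave), both
#' are Z-standardized, and the two-wave CLPM is fitted with X = BMI,
#' Y = methylation. Both cross paths are reported with raw and BH-FDR
#' adjusted P-values.
#'
#' @param cpgs character vector of probes to scan.
#' @param waves list with elements `baseline` and `followup`, each a list
#'   with `beta` (probe x sample over the same samples), `pheno`
#'   (sample_id, age, sex, bmi) and `covars_meth` (cells + control PCs).
#' @return data frame, one row per fitted CpG, with p_fdr columns for both
#'   cross paths; skipped CpGs (absent at a wave) are listed in the
#'   `"skipped"` attribute.
#' @export
clpm_scan <- function(cpgs, waves) {
  b <- waves$baseline; f <- waves$followup
  ids <- intersect(b$pheno$sample_id, f$pheno$sample_id)
  bi <- match(ids, b$pheno$sample_id); fi <- match(ids, f$pheno$sample_id)
  sexn_b <- as.numeric(factor(b$pheno$sex[bi], levels = c("female", "male")))
  sexn_f <- as.numeric(factor(f$pheno$sex[fi], levels = c("female", "male")))
  agesex_b <- cbind(age = b$pheno$age[bi], sex = sexn_b)
  agesex_f <- cbind(age = f$pheno$age[fi], sex = sexn_f)
  x_b <- residualize_standardize(b$pheno$bmi[bi], agesex_b)
  x_f <- residualize_standardize(f$pheno$bmi[fi], agesex_f)
  mcov_b <- cbind(agesex_b, as.matrix(b$covars_meth)[bi, , drop = FALSE])
  mcov_f <- cbind(agesex_f, as.matrix(f$covars_meth)[fi, , drop = FALSE])

  skipped <- character(0)
  rows <- list()
  for (cpg in cpgs) {
    if (!cpg %in% rownames(b$beta) || !cpg %in% rownames(f$beta)) {
      skipped <- c(skipped, cpg)
      next
    }
    y_b <- residualize_standardize(b$beta[cpg, ids], mcov_b)
    y_f <- residualize_standardize(f$beta[cpg, ids], mcov_f)
    fit <- fit_clpm(x_b, x_f, y_b, y_f)
    rows[[length(rows) + 1]] <- clpm_row(fit, cpg)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    names(out)[1] <- "cpg"
    out$c_xy_p_fdr <- bh_fdr(out$c_xy_p)
    out$c_yx_p_fdr <- bh_fdr(out$c_yx_p)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Cross-lagged models of the methylation risk score against biomarkers
#'
#' Biomarkers are residualized on age, sex and batch; the MRS on age, sex,
#' cell fractions and control PCs; both Z-standardized. Follow-up-wave
#' residualizations additionally adjust for follow-up time. One CLPM
#' (X = MRS, Y = biomarker) is fitted per biomarker; all-NA biomarkers
#' are skipped.
#'
#' @param mrs list with `baseline` and `followup` per-sample score vectors
#'   (named by sample_id).
#' @param biomarkers data frame with sample_id, visit and biomarker
#'   columns.
#' @param pheno phenotype sheet (sample_id, visit, age, sex,
#'   followup_years).
#' @param covars_mrs list per visit of cell-fraction + control-PC
#'   matrices (rows named by sample_id).
#' @param batch optional per-sample batch covariate list per visit.
#' @param biomarker_cols columns of `biomarkers` to model (default: all
#'   non-id columns).
#' @return data frame, one row per biomarker, with FDR-adjusted cross
#'   paths.
#' @export
mrs_biomarker_clpm <- function(mrs, biomarkers, pheno, covars_mrs,
                               batch = NULL, biomarker_cols = NULL) {
  if (is.null(biomarker_cols)) {
    biomarker_cols <- setdiff(names(biomarkers), c("sample_id", "visit"))
  }
  ids <- intersect(names(mrs$baseline), names(mrs$followup))
  ids <- intersect(ids, biomarkers$sample_id[biomarkers$visit == "baseline"])
  ph_b <- pheno[pheno$visit == "baseline", ][match(ids, pheno$sample_id[pheno$visit == "baseline"]), ]
  ph_f <- pheno[pheno$visit == "followup", ][match(ids, pheno$sample_id[pheno$visit == "followup"]), ]
  bio_b <- biomarkers[biomarkers$visit == "baseline", ][match(ids, biomarkers$sample_id[biomarkers$visit == "baseline"]), ]
  bio_f <- biomarkers[biomarkers$visit == "followup", ][match(ids, biomarkers$sample_id[biomarkers$visit == "followup"]), ]

  sexn <- function(ph) as.numeric(factor(ph$sex, levels = c("female", "male")))
  base_cov <- function(ph, extra = NULL, fu = FALSE) {
    X <- cbind(age = ph$age, sex = sexn(ph))
    if (!is.null(extra)) X <- cbind(X, extra)
    if (fu) X <- cbind(X, followup_years = ph$followup_years)
    X
  }
  batch_b <- if (is.null(batch)) NULL else cbind(batch = batch$baseline[ids])
  batch_f <- if (is.null(batch)) NULL else cbind(batch = batch$followup[ids])
  x_b <- residualize_standardize(mrs$baseline[ids],
                                 base_cov(ph_b, as.matrix(covars_mrs$baseline)[ids, , drop = FALSE]))
  x_f <- residualize_standardize(mrs$followup[ids],
                                 base_cov(ph_f, as.matrix(covars_mrs$followup)[ids, , drop = FALSE], fu = TRUE))
  rows <- list()
  for (nm in biomarker_cols) {
    yb <- bio_b[[nm]]; yf <- bio_f[[nm]]
    if (all(is.na(yb)) || all(is.na(yf))) next
    y_b <- residualize_standardize(yb, base_cov(ph_b, batch_b))
    y_f <- residualize_standardize(yf, base_cov(ph_f, batch_f, fu = TRUE))
    fit <- fit_clpm(x_b, x_f, y_b, y_f)
    rows[[length(rows) + 1]] <- clpm_row(fit, nm)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    names(out)[1] <- "biomarker"
    out$c_xy_p_fdr <- bh_fdr(out$c_xy_p)
    out$c_yx_p_fdr <- bh_fdr(out$c_yx_p)
  }
  out
}
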