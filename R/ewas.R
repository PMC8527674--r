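# Per-stratum epigenome-wide association: ordinary least squares of the
# adiposity trait on methylation beta plus covariates (age, sex, smoking,
# six cell fractions, five control-probe PCs), with the trait as the
# dependent variable and untransformed beta as the predictor of interest.

# Build the covariate design matrix, dropping constant / collinear columns
# (with a warning) and recording what was dropped.
build_design <- function(covars) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covars))
  storage.mode(X) <- "double"
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[-keep]
    warning(sprintf("dropping collinear/constant covariates: %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, sort(keep), drop = FALSE]
    qx <- qr(X)
  }
  list(X = X, qr = qx, dropped = dropped)
}

#' Per-CpG association of a trait with methylation in one stratum
#'
#' For every probe, fits trait ~ beta + covariates by OLS and reports the
#' coefficient on beta (trait units per unit beta), its standard error and
#' the two-sided t-test P-value. Implemented by residualizing trait and
#' beta on the covariates (Frisch-Waugh), which is algebraically identical
#' to the full per-probe regression.
#'
#' @param beta probe x sample matrix (or `beta_matrix`) for the stratum.
#' @param pheno phenotype rows for the same samples (one visit); must
#'   contain the trait column and `sample_id`.
#' @param covars data frame / matrix of covariates, rows aligned with
#'   `pheno$sample_id` (typically age, sex, smoking, cell fractions,
#'   control-probe PCs).
#' @param trait trait column name, "bmi" or "wc".
#' @param stratum label recorded in the output.
#' @return data frame with columns cpg, trait, stratum, n, beta_mean,
#'   beta_sd, effect, se, p, reason (NA unless the estimate is undefined).
#' @export
fit_ewas <- function(beta, pheno, covars, trait = "bmi", stratum = "all") {
  if (inherits(beta, "beta_matrix")) beta <- beta$beta
  ids <- pheno$sample_id
  assert_that(all(ids %in% colnames(beta)),
              "all phenotype samples must be present in the beta matrix")
  beta <- beta[, ids, drop = FALSE]
  covars <- as.matrix(covars)
  assert_that(nrow(covars) == length(ids),
              "covariates must align with phenotype rows")
  assert_that(!anyNA(covars), "covariates must be complete")
  y <- pheno[[trait]]
  n <- length(y)

  des <- build_design(covars)
  p_terms <- ncol(des$X) + 1  # + methylation term
  assert_that(n >= p_terms + 1, "too few samples for the model")

  ry <- qr.resid(des$qr, y)
  E <- qr.resid(des$qr, t(beta))          # samples x probes
  sxx <- colSums(E^2)
  sxy <- colSums(E * ry)
  syy <- sum(ry^2)
  df <- n - p_terms
  slope <- sxy / sxx
  rss <- syy - slope * sxy
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- slope / se
  pval <- 2 * stats::pt(-abs(tval), df)

  const <- sxx < n * 1e-20
  reason <- rep(NA_character_, length(sxx))
  if (any(const)) {
    slope[const] <- NA
    se[const] <- NA
    pval[const] <- NA
    reason[const] <- "constant_beta"
  }
  data.frame(cpg = rownames(beta), trait = trait, stratum = stratum, n = n,
             beta_mean = rowMeans(beta), beta_sd = apply(beta, 1, stats::sd),
             effect = slope, se = se, p = pval, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the EWAS across all strata
#'
#' @param strata_data named list; each element a list with `beta`, `pheno`,
#'   `covars` for one stratum (see [fit_ewas()]).
#' @param trait trait column name.
#' @return row-bound per-stratum estimates.
#' @export
ewas_strata <- function(strata_data, trait = "bmi") {
  do.call(rbind, lapply(names(strata_data), function(s) {
    d <- strata_data[[s]]
    fit_ewas(d$beta, d$pheno, d$covars, trait = trait, stratum = s)
  }))
}

# Group significant CpGs on one chromosome into loci: a gap greater than
# `window_bp` between consecutive (sorted) positions starts a new locus.
clump_loci <- function(hits, window_bp = 5e5) {
  hits$locus <- NA_integer_
  nxt <- 1L
  for (ch in unique(hits$chr)) {
    idx <- which(hits$chr == ch)
    idx <- idx[order(hits$pos[idx])]
    locus <- cumsum(c(TRUE, diff(hits$pos[idx]) > window_bp))
    hits$locus[idx] <- nxt + locus - 1L
    nxt <- nxt + max(locus)
  }
  hits
}

#' Conditional analysis of multi-CpG loci
#'
#' Loci are formed by clumping significant CpGs within `window_bp`. In each
#' locus with two or more CpGs, the non-sentinel CpG (the sentinel has the
#' smallest meta-analysis P) is refit jointly with the sentinel per
#' stratum; the conditional coefficients are pooled by inverse-variance
#' meta-analysis, and a secondary signal is declared when the conditional
#' meta P clears a Bonferroni threshold of 0.05 / n_loci.
#'
#' @param strata_data as in [ewas_strata()].
#' @param hits data frame of significant CpGs with columns cpg, chr, pos
#'   and p (meta-analysis P, used to pick sentinels).
#' @param trait trait column name.
#' @param window_bp clumping window (default 500 kb).
#' @return data frame of conditional estimates, one row per tested
#'   non-sentinel CpG, or an empty frame when no locus has two CpGs.
#' @export
conditional_scan <- function(strata_data, hits, trait = "bmi",
                             window_bp = 5e5) {
  hits <- clump_loci(hits, window_bp)
  multi <- split(hits, hits$locus)
  multi <- multi[vapply(multi, nrow, 1L) >= 2]
  n_loci <- length(multi)
  out <- list()
  for (loc in multi) {
    sentinel <- loc$cpg[which.min(loc$p)]
    for (cpg in setdiff(loc$cpg, sentinel)) {
      allb <- unlist(lapply(strata_data, function(d) d$beta[cpg, d$pheno$sample_id]))
      alls <- unlist(lapply(strata_data, function(d) d$beta[sentinel, d$pheno$sample_id]))
      if (abs(stats::cor(allb, alls)) > 0.99) {
        out[[length(out) + 1]] <- data.frame(
          locus = loc$locus[1], cpg = cpg, sentinel = sentinel,
          effect = NA, se = NA, p = NA, secondary = NA,
          flag = "collinear", stringsAsFactors = FALSE)
        next
      }
      est <- do.call(rbind, lapply(names(strata_data), function(s) {
        d <- strata_data[[s]]
        cov2 <- cbind(as.matrix(d$covars),
                      sentinel_beta = d$beta[sentinel, d$pheno$sample_id])
        fit_ewas(d$beta[cpg, , drop = FALSE], d$pheno, cov2, trait = trait,
                 stratum = s)
      }))
      m <- ivw_meta(est$effect, est$se)
      out[[length(out) + 1]] <- data.frame(
        locus = loc$locus[1], cpg = cpg, sentinel = sentinel,
        effect = m$effect, se = m$se, p = m$p,
        secondary = m$p < 0.05 / n_loci, flag = "ok",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus = integer(0), cpg = character(0),
                      sentinel = character(0), effect = numeric(0),
                      se = numeric(0), p = numeric(0), secondary = logical(0),
                      flag = character(0)))
  }
  do.call(rbind, out)
}

#' Prepare an expression matrix for association testing
#'
#' Drops lowly expressed transcripts (below the control-probe-derived
#' threshold in more than 90% of samples), quantile-normalizes across
#' samples, residualizes each transcript on sex, batch and the top
#' expression principal components (a surrogate for latent-factor
#' correction), and applies a rank-inverse-normal transform (Blom offset
#' 3/8) to the residuals.
#'
#' @param expr_raw transcript x sample matrix.
#' @param ctrl_mean mean expression of array control probes (the
#'   low-expression threshold).
#' @param covars data frame with columns sex and batch, rows aligned with
#'   the samples.
#' @param n_pcs number of expression PCs to remove (default 5).
#' @param low_frac fraction of samples below threshold that triggers
#'   removal (default 0.9).
#' @return transformed transcript x sample matrix.
#' @export
prepare_expression <- function(expr_raw, ctrl_mean, covars, n_pcs = 5,
                               low_frac = 0.9) {
  low <- rowMeans(expr_raw < ctrl_mean) > low_frac
  expr <- expr_raw[!low, , drop = FALSE]
  if (nrow(expr) < 10) stop("fewer than 10 transcripts survive the low-expression filter",
                            call. = FALSE)
  expr <- quantile_normalize(expr, rep("all", ncol(expr)))
  sexn <- as.numeric(factor(covars$sex))
  pcs <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)$x
  n_pcs <- min(n_pcs, ncol(pcs))
  X <- cbind(1, sexn, covars$batch, pcs[, seq_len(n_pcs)])
  qx <- qr(X)
  res <- t(qr.resid(qx, t(expr)))
  out <- t(apply(res, 1, rank_inverse_normal))
  dimnames(out) <- dimnames(expr)
  out
}

#' Cis association of significant CpGs with transcript expression
#'
#' Tests every (CpG, transcript) pair on the same chromosome with
#' |transcript start - CpG position| <= `window_bp` (closed interval):
#' per-stratum OLS of expression on beta plus covariates, pooled by
#' inverse-variance meta-analysis, with BH-FDR across all tested pairs.
#'
#' @param cpg_hits data frame with columns cpg, chr, pos.
#' @param expr_strata named list per stratum with elements `expr`
#'   (prepared transcript x sample matrix), `beta` (probe x sample) and
#'   `covars` (age, cell fractions, control PCs).
#' @param transcript_coords data frame with transcript_id, chr, start.
#' @param window_bp cis window (default 1 Mb).
#' @return data frame with one row per tested pair (cpg, transcript,
#'   effect, se, p, p_fdr) plus an `untested` attribute listing CpGs with
#'   no cis transcript.
#' @export
cis_expression_assoc <- function(cpg_hits, expr_strata, transcript_coords,
                                 window_bp = 1e6) {
  pairs <- do.call(rbind, lapply(seq_len(nrow(cpg_hits)), function(i) {
    h <- cpg_hits[i, ]
    cand <- transcript_coords[transcript_coords$chr == h$chr &
                                abs(transcript_coords$start - h$pos) <= window_bp, ]
    if (nrow(cand) == 0) return(NULL)
    data.frame(cpg = h$cpg, transcript = cand$transcript_id,
               stringsAsFactors = FALSE)
  }))
  untested <- if (is.null(pairs)) cpg_hits$cpg else setdiff(cpg_hits$cpg, pairs$cpg)
  if (is.null(pairs) || nrow(pairs) == 0) {
    out <- data.frame(cpg = character(0), transcript = character(0),
                      effect = numeric(0), se = numeric(0), p = numeric(0),
                      p_fdr = numeric(0))
    attr(out, "untested") <- untested
    return(out)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    cpg <- pairs$cpg[i]; tr <- pairs$transcript[i]
    ests <- do.call(rbind, lapply(expr_strata, function(d) {
      if (!tr %in% rownames(d$expr) || !cpg %in% rownames(d$beta)) return(NULL)
      ids <- colnames(d$expr)
      des <- build_design(d$covars)
      ry <- qr.resid(des$qr, d$expr[tr, ids])
      rx <- qr.resid(des$qr, d$beta[cpg, ids])
      sxx <- sum(rx^2)
      if (sxx < 1e-20) return(NULL)
      slope <- sum(rx * ry) / sxx
      df <- length(ids) - ncol(des$X) - 1
      rss <- sum(ry^2) - slope * sum(rx * ry)
      se <- sqrt(max(rss, 0) / df / sxx)
      data.frame(effect = slope, se = se)
    }))
    if (is.null(ests) || nrow(ests) == 0) return(NULL)
    m <- ivw_meta(ests$effect, ests$se)
    data.frame(cpg = cpg, transcript = tr, effect = m$effect, se = m$se,
               p = m$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  out$p_fdr <- bh_fdr(out$p)
  attr(out, "untested") <- untested
  out
}

#' Impute biomarker values below the detection limit
#'
#' Entries flagged below the limit are replaced by 0.9 times the minimum of
#' the remaining (observed) values of that biomarker; nothing else changes.
#' A biomarker with all values below limit becomes NA with a warning.
#'
#' @param table data frame of biomarker columns.
#' @param limits either a named numeric vector of detection limits (values
#'   strictly below their limit are flagged) or a logical matrix/data
#'   frame of the same shape marking below-limit entries.
#' @return the imputed table.
#' @export
prepare_biomarkers <- function(table, limits) {
  if (is.numeric(limits) && !is.null(names(limits))) {
    mask <- sapply(names(limits), function(nm) table[[nm]] < limits[[nm]])
    colnames(mask) <- names(limits)
    cols <- names(limits)
  } else {
    mask <- as.matrix(limits)
    cols <- colnames(mask)
  }
  for (nm in cols) {
    below <- mask[, nm]
    if (!any(below)) next
    if (all(below)) {
      warning(sprintf("biomarker '%s' is entirely below the detection limit; set to NA", nm))
      table[[nm]] <- NA_real_
      next
    }
    table[[nm]][below] <- 0.9 * min(table[[nm]][!below])
  }
  table
}
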