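# Intensity-level quality control and normalization.
#
# Reproduces the study's filter thresholds: detection P > 1e-16 in > 5% of
# probes drops a sample; detection P > 1e-16 in > 5% of samples or
# beadcount < 3 in > 5% of samples drops a probe; sex-chromosome probes are
# always dropped; cross-reactive and SNP-affected probes are flagged but
# retained. The sex check compares log2 median total intensity of chrY vs
# chrX probes, with a difference > -2 indicating male.

#' Construct an intensity-level data object
#'
#' @param M,U probe x sample matrices of methylated / unmethylated signal.
#' @param beadcount probe x sample integer matrix.
#' @param controls control-probe x sample signal matrix.
#' @param control_type character vector typing each control probe; must
#'   contain at least one "NEGATIVE".
#' @param manifest probe annotation data frame with columns probe_id, chr,
#'   pos, relation_to_island, nearest_gene, cross_reactive, snp_affected.
#' @return an `intensity_data` object.
#' @export
intensity_data <- function(M, U, beadcount, controls, control_type, manifest) {
  assert_that(all(dim(M) == dim(U)) && all(dim(M) == dim(beadcount)),
              "M, U and beadcount must share dimensions")
  assert_that(!is.null(rownames(M)) && !is.null(colnames(M)),
              "M must carry probe and sample names")
  assert_that(all(rownames(M) %in% manifest$probe_id),
              "every probe must appear in the manifest")
  assert_that(length(control_type) == nrow(controls),
              "control_type must type every control probe")
  assert_that(min(M) >= 0 && min(U) >= 0, "signals must be non-negative")
  structure(list(M = M, U = U, beadcount = beadcount, controls = controls,
                 control_type = control_type,
                 manifest = manifest[match(rownames(M), manifest$probe_id), ]),
            class = "intensity_data")
}

#' @export
print.intensity_data <- function(x, ...) {
  cat(sprintf("Intensity data: %d probes x %d samples, %d control probes (%d negative)\n",
              nrow(x$M), ncol(x$M), nrow(x$controls),
              sum(x$control_type == "NEGATIVE")))
  invisible(x)
}

neg_controls <- function(data) {
  idx <- which(data$control_type == "NEGATIVE")
  if (length(idx) == 0) {
    stop("no NEGATIVE control probes present; background statistics cannot be estimated",
         call. = FALSE)
  }
  data$controls[idx, , drop = FALSE]
}

#' Background-correct signal intensities
#'
#' Subtracts, per sample, the 5th percentile of the negative-control signal
#' from both channels and from the control probes themselves, flooring at
#' zero. Correcting the controls too makes the operation idempotent once
#' all signals clear the background estimate (the corrected negatives'
#' 5th percentile is then zero).
#'
#' @param data an [intensity_data()] object.
#' @return the corrected `intensity_data`.
#' @export
background_correct <- function(data) {
  neg <- neg_controls(data)
  b <- apply(neg, 2, stats::quantile, probs = 0.05)
  data$M <- pmax(sweep(data$M, 2, b), 0)
  data$U <- pmax(sweep(data$U, 2, b), 0)
  data$controls <- pmax(sweep(data$controls, 2, b), 0)
  data
}

#' Detection P-values against negative-control background
#'
#' For each probe and sample, the probability that the total signal (M + U)
#' would be seen under the per-sample background distribution, modelled as
#' Normal(mean, sd) of the negative controls; the upper-tail probability is
#' returned, so strong signals give small values.
#'
#' @param data an [intensity_data()] object with >= 2 negative controls.
#' @return probe x sample matrix of detection P-values in [0, 1].
#' @export
detection_pvalues <- function(data) {
  neg <- neg_controls(data)
  assert_that(nrow(neg) >= 2, "need >= 2 negative controls per sample")
  mu <- colMeans(neg)
  sdv <- apply(neg, 2, stats::sd)
  if (any(sdv == 0)) {
    warning("negative-control SD is zero for some samples; detection P degenerates to a step function")
    sdv[sdv == 0] <- .Machine$double.eps
  }
  tot <- data$M + data$U
  z <- sweep(sweep(tot, 2, mu), 2, sdv, `/`)
  detp <- stats::pnorm(z, lower.tail = FALSE)
  dimnames(detp) <- dimnames(data$M)
  detp
}

default_qc_thresholds <- function() {
  list(detp = 1e-16, sample_missing_frac = 0.05, beadcount_min = 3,
       probe_fail_frac = 0.05, sexcheck_cutoff = -2)
}

#' Sample-level QC filter
#'
#' Removes samples with more than `sample_missing_frac` of probes failing
#' the detection-P threshold, then samples whose intensity-inferred sex
#' (log2 median chrY minus log2 median chrX total intensity, male if
#' > `sexcheck_cutoff`) contradicts the self-reported sex. Each exclusion
#' carries exactly one primary reason; missingness takes precedence.
#'
#' @param data an [intensity_data()] object.
#' @param detp matrix from [detection_pvalues()].
#' @param sample_sheet data frame with columns sample_id and sex
#'   ("male"/"female").
#' @param thresholds list as from `default_qc_thresholds()`.
#' @return list with `data` (filtered) and `samples` (per-sample QC table).
#' @export
filter_samples <- function(data, detp, sample_sheet,
                           thresholds = default_qc_thresholds()) {
  th <- utils::modifyList(default_qc_thresholds(), thresholds)
  ids <- colnames(data$M)
  # sex-chromosome probes are excluded from the missingness denominator:
  # chrY probes sit at background level in females by biology, not by
  # sample quality
  auto <- !data$manifest$chr %in% c("X", "Y")
  miss <- colMeans(detp[auto, , drop = FALSE] > th$detp)

  chrx <- data$manifest$chr == "X"
  chry <- data$manifest$chr == "Y"
  tot <- data$M + data$U
  if (!any(chrx) || !any(chry)) {
    warning("manifest has no chrX or chrY probes; sex check skipped")
    sexdiff <- rep(NA_real_, length(ids))
    inferred <- rep(NA_character_, length(ids))
  } else {
    medx <- apply(tot[chrx, , drop = FALSE], 2, stats::median)
    medy <- apply(tot[chry, , drop = FALSE], 2, stats::median)
    sexdiff <- log2(medy) - log2(medx)
    inferred <- ifelse(sexdiff > th$sexcheck_cutoff, "male", "female")
  }
  reported <- sample_sheet$sex[match(ids, sample_sheet$sample_id)]

  reason <- rep("", length(ids))
  reason[!is.na(inferred) & !is.na(reported) & inferred != reported] <- "sex_mismatch"
  reason[miss > th$sample_missing_frac] <- "missingness"

  keep <- reason == ""
  tab <- data.frame(sample_id = ids, missing_frac = miss,
                    sexcheck_diff = sexdiff, inferred_sex = inferred,
                    reported_sex = reported, excluded = !keep,
                    reason = ifelse(keep, NA_character_, reason),
                    stringsAsFactors = FALSE, row.names = NULL)
  data$M <- data$M[, keep, drop = FALSE]
  data$U <- data$U[, keep, drop = FALSE]
  data$beadcount <- data$beadcount[, keep, drop = FALSE]
  data$controls <- data$controls[, keep, drop = FALSE]
  list(data = data, samples = tab)
}

#' Probe-level QC filter
#'
#' Removes probes failing detection P in more than `probe_fail_frac` of the
#' remaining samples, probes with beadcount below `beadcount_min` in more
#' than `probe_fail_frac` of samples, and all sex-chromosome probes.
#' Cross-reactive and SNP-affected probes are flagged but retained. Each
#' exclusion carries one primary reason, in the order detection-P,
#' beadcount, sex-chromosome.
#'
#' @param data an [intensity_data()] object (after sample filtering).
#' @param detp detection-P matrix restricted to the retained samples.
#' @param thresholds list as from `default_qc_thresholds()`.
#' @return list with `data` (filtered) and `probes` (per-probe QC table).
#' @export
filter_probes <- function(data, detp, thresholds = default_qc_thresholds()) {
  th <- utils::modifyList(default_qc_thresholds(), thresholds)
  detp <- detp[, colnames(data$M), drop = FALSE]
  detp_frac <- rowMeans(detp > th$detp)
  bead_frac <- rowMeans(data$beadcount < th$beadcount_min)
  sexchr <- data$manifest$chr %in% c("X", "Y")

  reason <- rep("", nrow(data$M))
  reason[sexchr] <- "sex_chromosome"
  reason[bead_frac > th$probe_fail_frac] <- "beadcount"
  reason[detp_frac > th$probe_fail_frac] <- "detection_p"
  keep <- reason == ""
  if (!any(keep)) stop("no probes survive QC", call. = FALSE)

  tab <- data.frame(probe_id = rownames(data$M), detp_fail_frac = detp_frac,
                    beadcount_fail_frac = bead_frac,
                    excluded = !keep,
                    reason = ifelse(keep, NA_character_, reason),
                    flagged_cross_reactive = data$manifest$cross_reactive,
                    flagged_snp = data$manifest$snp_affected,
                    stringsAsFactors = FALSE, row.names = NULL)
  data$M <- data$M[keep, , drop = FALSE]
  data$U <- data$U[keep, , drop = FALSE]
  data$beadcount <- data$beadcount[keep, , drop = FALSE]
  data$manifest <- data$manifest[keep, , drop = FALSE]
  list(data = data, probes = tab)
}

#' Within-group quantile normalization
#'
#' Within each group of samples, every column is mapped onto the mean of
#' the sorted columns. Two tie policies are offered: `"average"` gives
#' tied values the average of the tied ranks' reference values (so equal
#' inputs stay equal), while `"first"` breaks ties by position
#' (sort-replace-unsort), which makes every sample's sorted vector exactly
#' equal to the group reference even in the presence of ties. Groups of
#' size one are returned unchanged with a warning.
#'
#' @param mat probe x sample numeric matrix.
#' @param groups factor/character vector of length `ncol(mat)`.
#' @param ties tie policy, "average" (default) or "first".
#' @return normalized matrix with identical dimnames.
#' @export
quantile_normalize <- function(mat, groups, ties = c("average", "first")) {
  ties <- match.arg(ties)
  assert_that(length(groups) == ncol(mat),
              "groups must label every sample (column)")
  out <- mat
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) == 1) {
      warning(sprintf("group '%s' has a single sample; left unchanged", g))
      next
    }
    sub <- mat[, cols, drop = FALSE]
    ref <- rowMeans(apply(sub, 2, sort))
    out[, cols] <- apply(sub, 2, function(x) {
      if (ties == "average") {
        r <- rank(x, ties.method = "average")
        (ref[floor(r)] + ref[ceiling(r)]) / 2
      } else {
        ref[rank(x, ties.method = "first")]
      }
    })
  }
  out
}

#' Compute methylation beta values
#'
#' beta = M / (M + U + 100); the +100 offset regularizes low-intensity
#' probes and keeps values strictly below 1.
#'
#' @param data an [intensity_data()] object.
#' @return probe x sample matrix of beta values in [0, 1).
#' @export
compute_beta <- function(data) {
  if (min(data$M) < 0 || min(data$U) < 0) {
    stop("negative signal intensities", call. = FALSE)
  }
  data$M / (data$M + data$U + 100)
}

#' Run the full QC and normalization chain
#'
#' Order: background correction, detection P-values, sample filters, probe
#' filters, beta computation, within-group quantile normalization of beta.
#'
#' @param data an [intensity_data()] object.
#' @param sample_sheet data frame with sample_id and sex columns.
#' @param groups sample grouping for quantile normalization (defaults to a
#'   single group); length must match the original sample count, named or
#'   ordered as `colnames(data$M)`.
#' @param thresholds overrides for `default_qc_thresholds()`.
#' @return list with `beta` (class `beta_matrix`: beta matrix + manifest +
#'   normalization tag) and `report` (class `qc_report`).
#' @export
run_qc <- function(data, sample_sheet, groups = NULL,
                   thresholds = list()) {
  th <- utils::modifyList(default_qc_thresholds(), thresholds)
  if (is.null(groups)) groups <- rep("all", ncol(data$M))
  if (is.null(names(groups))) names(groups) <- colnames(data$M)

  data <- background_correct(data)
  detp <- detection_pvalues(data)
  sf <- filter_samples(data, detp, sample_sheet, th)
  pf <- filter_probes(sf$data, detp, th)
  beta_raw <- compute_beta(pf$data)
  # "first" tie policy: background-floored signals produce exact zeros, and
  # the pipeline guarantees identical within-group sorted columns
  beta <- quantile_normalize(beta_raw, groups[colnames(beta_raw)],
                             ties = "first")

  report <- structure(list(samples = sf$samples, probes = pf$probes,
                           thresholds = th), class = "qc_report")
  bm <- structure(list(beta = beta, manifest = pf$data$manifest,
                       normalization = "within-group quantile (beta scale)"),
                  class = "beta_matrix")
  list(beta = bm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("QC report (detP > %g in > %g%%; beadcount < %d in > %g%%; sex cutoff %g)\n",
              th$detp, 100 * th$sample_missing_frac, th$beadcount_min,
              100 * th$probe_fail_frac, th$sexcheck_cutoff))
  cat(sprintf("  samples: %d kept, %d excluded (%s)\n",
              sum(!x$samples$excluded), sum(x$samples$excluded),
              paste(names(table(x$samples$reason)),
                    table(x$samples$reason), sep = "=", collapse = ", ")))
  cat(sprintf("  probes: %d kept, %d excluded (%s); flagged cross-reactive %d, SNP %d\n",
              sum(!x$probes$excluded), sum(x$probes$excluded),
              paste(names(table(x$probes$reason)),
                    table(x$probes$reason), sep = "=", collapse = ", "),
              sum(x$probes$flagged_cross_reactive), sum(x$probes$flagged_snp)))
  invisible(x)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("Beta matrix: %d probes x %d samples (%s)\n",
              nrow(x$beta), ncol(x$beta), x$normalization))
  invisible(x)
}
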