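# Inverse-variance fixed-effect meta-analysis with Cochran's Q
# heterogeneity, the hierarchical (Chinese-first) pooling scheme, BH-FDR,
# novelty annotation against user-supplied catalogs, and cross-study
# direction-consistency binomial tests.

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-stratum estimates with weights w_i = 1/SE_i^2:
#' effect = sum(w e)/sum(w), SE = 1/sqrt(sum(w)), P from the two-sided
#' normal approximation, and Cochran's Q = sum(w (e - eff)^2) on k - 1
#' degrees of freedom for heterogeneity.
#'
#' @param effects numeric vector of stratum effects (k >= 1).
#' @param ses numeric vector of stratum standard errors (all > 0).
#' @return one-row data frame: effect, se, p, q_stat, df, p_het, k.
#' @export
ivw_meta <- function(effects, ses) {
  ok <- !is.na(effects) & !is.na(ses)
  effects <- effects[ok]; ses <- ses[ok]
  k <- length(effects)
  if (k == 0) stop("no estimates to pool", call. = FALSE)
  if (any(ses <= 0)) stop("all standard errors must be > 0", call. = FALSE)
  w <- 1 / ses^2
  eff <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (effects - eff)^2)
  df <- k - 1L
  p_het <- if (df == 0) 1 else stats::pchisq(q, df, lower.tail = FALSE)
  data.frame(effect = eff, se = se, p = z_pvalue(eff, se),
             q_stat = q, df = df, p_het = p_het, k = k)
}

#' Vectorized inverse-variance meta-analysis over a long table
#'
#' Pools a long table of per-stratum estimates (one row per unit x
#' stratum) within each combination of the `by` columns; same statistics
#' as [ivw_meta()].
#'
#' @param est data frame with columns `effect`, `se` and the `by` columns.
#' @param by grouping columns (default cpg and trait).
#' @return one row per group with effect, se, p, q_stat, df, p_het, k.
#' @export
ivw_meta_table <- function(est, by = c("cpg", "trait")) {
  est <- est[!is.na(est$effect) & !is.na(est$se), , drop = FALSE]
  key <- interaction(est[by], drop = TRUE, lex.order = TRUE)
  w <- 1 / est$se^2
  sw <- tapply(w, key, sum)
  swe <- tapply(w * est$effect, key, sum)
  eff <- swe / sw
  se <- 1 / sqrt(sw)
  q <- tapply(w * est$effect^2, key, sum) - eff^2 * sw
  k <- tapply(w, key, length)
  df <- k - 1
  p_het <- ifelse(df == 0, 1, stats::pchisq(pmax(q, 0), df, lower.tail = FALSE))
  ids <- do.call(rbind, strsplit(names(sw), ".", fixed = TRUE))
  out <- data.frame(ids, effect = as.numeric(eff), se = as.numeric(se),
                    p = z_pvalue(as.numeric(eff), as.numeric(se)),
                    q_stat = as.numeric(pmax(q, 0)), df = as.numeric(df),
                    p_het = as.numeric(p_het), k = as.numeric(k),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[seq_along(by)] <- by
  out
}

#' Hierarchical (Chinese-first) meta-analysis
#'
#' Stage 1 pools the two Chinese strata (longitudinal set and the
#' multi-omic set); stage 2 pools all four base strata. The two-stage
#' pooled effect and SE are algebraically identical to pooling the
#' Chinese-stage result with the Malay and Indian strata; heterogeneity is
#' computed over the four base strata. BH-FDR is applied at each stage,
#' and significance is declared at P_FDR < 0.05.
#'
#' @param stratum_results per-stratum estimates (columns cpg, trait,
#'   stratum, effect, se) with strata labelled by ethnicity: the Chinese
#'   strata are those whose `ethnicity` column (or stratum name containing
#'   "chinese") marks them as Chinese.
#' @return list with `chinese` and `trans` meta tables (each with p_fdr
#'   and significant columns).
#' @export
hierarchical_meta <- function(stratum_results) {
  eth <- if ("ethnicity" %in% names(stratum_results)) {
    stratum_results$ethnicity
  } else {
    ifelse(grepl("chinese", stratum_results$stratum), "chinese", "other")
  }
  chn <- stratum_results[eth == "chinese", , drop = FALSE]
  if (length(unique(stratum_results$stratum)) < 4) {
    warning("fewer than four base strata supplied; pooling over what is available")
  }
  chinese <- ivw_meta_table(chn)
  chinese$p_fdr <- stats::ave(chinese$p, chinese$trait,
                              FUN = function(p) bh_fdr(p))
  chinese$significant <- chinese$p_fdr < 0.05

  trans <- ivw_meta_table(stratum_results)
  trans$p_fdr <- stats::ave(trans$p, trans$trait, FUN = function(p) bh_fdr(p))
  trans$significant <- trans$p_fdr < 0.05
  list(chinese = chinese, trans = trans)
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up FDR adjustment; delegates to [stats::p.adjust()] with
#' method "BH".
#'
#' @param pvals vector of P-values in (0, 1].
#' @return adjusted values (empty input gives empty output).
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Direction-consistency test against an external study
#'
#' Overlaps two effect tables by CpG, counts concordant effect signs
#' (zero effects in either table are excluded from both counts), and
#' tests the concordant proportion against 0.5 with the exact two-sided
#' binomial test.
#'
#' @param hits data frame with columns cpg, effect.
#' @param external_table data frame with columns cpg, effect.
#' @return list: n_overlap, n_concordant, proportion, binom_p (NA when no
#'   overlap).
#' @export
direction_consistency <- function(hits, external_table) {
  m <- merge(hits[, c("cpg", "effect")], external_table[, c("cpg", "effect")],
             by = "cpg", suffixes = c("_a", "_b"))
  m <- m[m$effect_a != 0 & m$effect_b != 0, , drop = FALSE]
  n <- nrow(m)
  if (n == 0) {
    return(list(n_overlap = 0L, n_concordant = 0L, proportion = NA_real_,
                binom_p = NA_real_))
  }
  conc <- sum(sign(m$effect_a) == sign(m$effect_b))
  list(n_overlap = n, n_concordant = conc, proportion = conc / n,
       binom_p = stats::binom.test(conc, n, p = 0.5)$p.value)
}

#' Annotate hits for novelty against association catalogs
#'
#' A hit is novel for its trait when no catalog entry for the same trait
#' lies within 500 kb (strictly greater distance required) on the same
#' chromosome. Optionally flags hits whose nearest gene is on a supplied
#' obesity-gene list. Malformed catalog rows (missing chr/pos) are skipped
#' and counted.
#'
#' @param hits data frame with cpg, chr, pos, trait (and optionally
#'   nearest_gene).
#' @param catalog data frame with cpg, chr, pos, trait.
#' @param window_bp novelty window (default 500 kb).
#' @param obesity_genes optional character vector of gene symbols.
#' @return `hits` with added `novel` (and `obesity_gene`) columns; the
#'   number of skipped catalog rows is attached as attribute
#'   `"skipped_catalog_rows"`.
#' @export
annotate_novelty <- function(hits, catalog, window_bp = 5e5,
                             obesity_genes = NULL) {
  bad <- is.na(catalog$chr) | is.na(catalog$pos) |
    !is.finite(suppressWarnings(as.numeric(catalog$pos)))
  if (any(bad)) catalog <- catalog[!bad, , drop = FALSE]
  catalog$pos <- as.numeric(catalog$pos)
  hits$novel <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    cand <- catalog[catalog$trait == h$trait & catalog$chr == h$chr, ]
    if (nrow(cand) == 0) return(TRUE)
    all(abs(cand$pos - h$pos) > window_bp)
  }, logical(1))
  if (!is.null(obesity_genes) && "nearest_gene" %in% names(hits)) {
    hits$obesity_gene <- hits$nearest_gene %in% obesity_genes
  }
  attr(hits, "skipped_catalog_rows") <- sum(bad)
  hits
}
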