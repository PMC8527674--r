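# File interchange: plain TSV for all tabular layers, VCF (DS field, via
# vcfR) or dosage TSV for genotypes.

#' Read genotype dosages from a dosage TSV or a VCF
#'
#' A dosage TSV has columns snp, chr, pos, ref, alt followed by one column
#' per sample. A VCF must carry the DS (dosage) FORMAT field; an
#' actionable error is raised otherwise.
#'
#' @param path file path (`.vcf`/`.vcf.gz` or TSV).
#' @return list with `dosage` (sample x SNP matrix) and `info` data frame.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
    if (!"DS" %in% fmt) {
      stop(sprintf("VCF %s has no DS (dosage) FORMAT field; re-export dosages or supply a dosage TSV",
                   path), call. = FALSE)
    }
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    info <- data.frame(snp = v@fix[, "ID"], chr = v@fix[, "CHROM"],
                       pos = as.numeric(v@fix[, "POS"]), ref = v@fix[, "REF"],
                       alt = v@fix[, "ALT"], stringsAsFactors = FALSE)
    rownames(ds) <- info$snp
    return(list(dosage = t(ds), info = info))
  }
  tab <- read_tsv(path)
  meta_cols <- c("snp", "chr", "pos", "ref", "alt")
  assert_that(all(meta_cols %in% names(tab)),
              "dosage TSV must have columns snp, chr, pos, ref, alt + samples")
  d <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  rownames(d) <- tab$snp
  list(dosage = t(d), info = tab[, meta_cols])
}

#' Write a study bundle to plain-text files
#'
#' Writes, per visit, long-format intensity tables (probe_id, sample_id,
#' M, U, beadcount) and control-probe tables; plus the manifest, sample
#' sheet, dosage TSV and truth tables. Mainly useful for small bundles and
#' interchange with external tools.
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x, name) {
    p <- file.path(dir, name)
    write_tsv(x, p)
    files <<- c(files, p)
  }
  for (visit in names(bundle$intensities)) {
    d <- bundle$intensities[[visit]]
    long <- data.frame(
      probe_id = rep(rownames(d$M), ncol(d$M)),
      sample_id = rep(colnames(d$M), each = nrow(d$M)),
      M = as.vector(d$M), U = as.vector(d$U),
      beadcount = as.vector(d$beadcount), stringsAsFactors = FALSE)
    put(long, sprintf("intensities_%s.tsv", visit))
    ctrl <- data.frame(control_id = rownames(d$controls),
                       control_type = d$control_type, d$controls,
                       check.names = FALSE, stringsAsFactors = FALSE)
    put(ctrl, sprintf("controls_%s.tsv", visit))
  }
  put(bundle$intensities[[1]]$manifest, "manifest.tsv")
  put(bundle$phenotypes, "sample_sheet.tsv")
  if (!is.null(bundle$genotypes)) {
    g <- cbind(bundle$genotypes$info, t(bundle$genotypes$dosage))
    put(g, "genotypes_dosage.tsv")
  }
  put(bundle$truth$probes, "truth_probes.tsv")
  put(bundle$truth$samples, "truth_samples.tsv")
  put(bundle$truth$snps, "truth_snps.tsv")
  invisible(files)
}

#' Published per-stratum association estimates for the novel adiposity CpGs
#'
#' Returns the per-stratum (effect, SE, P) estimates, and the printed
#' pooled reference values, for the eight novel CpG-trait association rows
#' (six novel BMI CpGs, two of them also associated with waist
#' circumference), as printed in the source study's summary table. These
#' serve as fixed inputs for validating the meta-analysis stage.
#'
#' @return list with `strata` (long table: cpg, trait, stratum, ethnicity,
#'   effect, se, p) and `reference` (printed pooled effect/SE/P_het/P_FDR
#'   per row for the Chinese-stage and trans-ethnic meta-analyses).
#' @export
published_novel_cpg_estimates <- function() {
  path <- system.file("extdata", "novel_cpg_strata.tsv",
                      package = "adipomethyl")
  strata <- read_tsv(path)
  ref <- read_tsv(system.file("extdata", "novel_cpg_reference.tsv",
                              package = "adipomethyl"))
  list(strata = strata, reference = ref)
}
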