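#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

#' Two-sided normal P-value from an effect and its standard error
#' @noRd
z_pvalue <- function(effect, se) {
  2 * stats::pnorm(-abs(effect / se))
}

#' Stop unless a condition holds
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Write a data frame as TSV (no quoting, no row names)
#'
#' All tabular interchange in the package uses plain TSV with a header row.
#'
#' @param x data frame
#' @param path output file path
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# rank-inverse-normal transform with the Blom offset
rank_inverse_normal <- function(x, offset = 3 / 8) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (length(x) + 1 - 2 * offset))
}
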