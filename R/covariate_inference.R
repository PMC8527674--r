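# Technical and biological covariates: principal components of the array
# control probes (batch surrogates) and reference-based blood cell-type
# deconvolution by constrained projection.

#' Principal components of control-probe signals
#'
#' PCA of the column-centered, unit-variance-scaled control-probe matrix;
#' the leading components act as batch/technical covariates. Component
#' signs are fixed by making the largest-magnitude loading of each
#' component positive, so results are fully deterministic.
#'
#' @param controls control-probe x sample signal matrix.
#' @param k number of components (default 5).
#' @return list with `scores` (sample x k, zero column means),
#'   `explained_var` (fractions), `loadings`.
#' @export
control_probe_pcs <- function(controls, k = 5) {
  x <- t(controls)  # samples x controls
  assert_that(ncol(x) >= k, "need at least k control probes")
  assert_that(nrow(x) >= k + 1, "need at least k + 1 samples")
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (k > ncol(pc$rotation)) stop("k exceeds the rank of the control matrix",
                                  call. = FALSE)
  flip <- apply(pc$rotation[, seq_len(k), drop = FALSE], 2,
                function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- paste0("ctrl_pc", seq_len(k))
  list(scores = scores,
       explained_var = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       loadings = loadings)
}

#' Reference-based cell-type deconvolution
#'
#' For each sample, solves the constrained least-squares projection
#' min || beta_s - R p ||^2 subject to p >= 0 over the probes shared
#' between the sample matrix and the reference profiles (no sum-to-one
#' equality constraint; optional renormalization divides by the row sum).
#'
#' @param beta beta matrix (probe x sample) or `beta_matrix` object.
#' @param ref probe x cell-type reference beta profiles.
#' @param renormalize divide each row of proportions by its sum.
#' @return sample x cell-type matrix of non-negative proportions, with a
#'   `"row_sums"` attribute holding the pre-normalization sums.
#' @export
houseman_deconvolve <- function(beta, ref, renormalize = FALSE) {
  if (inherits(beta, "beta_matrix")) beta <- beta$beta
  shared <- intersect(rownames(beta), rownames(ref))
  if (length(shared) < 2) stop("need >= 2 probes shared with the reference",
                               call. = FALSE)
  R <- as.matrix(ref[shared, , drop = FALSE])
  if (qr(R)$rank < ncol(R)) stop("reference profile matrix is singular",
                                 call. = FALSE)
  B <- beta[shared, , drop = FALSE]
  props <- t(apply(B, 2, function(b) pracma::lsqnonneg(R, b)$x))
  colnames(props) <- colnames(ref)
  rownames(props) <- colnames(beta)
  sums <- rowSums(props)
  if (renormalize) {
    ok <- sums > 0
    props[ok, ] <- props[ok, ] / sums[ok]
  }
  attr(props, "row_sums") <- sums
  props
}
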