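#' Per-pathway principal component scores for one omics type
#'
#' Intersects the pathway's gene set with the genes available in the omics
#' matrix (missing genes are simply dropped, no imputation), mean-centers
#' each gene across samples and computes covariance-PCA scores. Components
#' are made deterministic by a sign rule: each component is flipped so that
#' its loading of largest absolute value is positive, ties resolved in favor
#' of the first gene in sorted gene-id order. If fewer informative
#' directions than `q` exist (few genes, or rank-deficient data), trailing
#' score columns are zero with explained-variance ratio 0, so the image
#' geometry stays fixed.
#'
#' @param omics an [omics_matrix()].
#' @param genes character vector of member gene ids for the pathway.
#' @param q number of components to return (>= 1).
#' @param pathway_name optional name recorded in the result.
#' @param scale. if `TRUE`, genes are scaled to unit variance before PCA
#'   (default `FALSE`: within one omics block units are homogeneous).
#' @param fit_sample_ids optional subset of sample ids to fit center/loadings
#'   on; scores are still produced for all samples (used for
#'   within-fold refitting to avoid train/test leakage).
#' @return a `pc_scores` object: list with `scores` (n x q, rownames =
#'   sample ids), `explained_variance_ratio`, `rotation`, `center`,
#'   `genes_used`, `n_genes_used`, `n_genes_missing`, `pathway_name`,
#'   `omics_tag`.
#' @export
pathway_pca <- function(omics, genes, q, pathway_name = NULL, scale. = FALSE,
                        fit_sample_ids = NULL) {
  assert_that(inherits(omics, "omics_matrix"), "omics must be an omics_matrix")
  assert_that(is_count(q), "q must be a positive count")
  tag <- omics_tag(omics)
  present <- intersect(genes, colnames(omics))
  if (length(present) == 0)
    abort(sprintf("no genes of pathway '%s' present in omics '%s'",
                  if (is.null(pathway_name)) "<unnamed>" else pathway_name, tag))
  B <- unclass(omics)[, present, drop = FALSE]
  fit_rows <- if (is.null(fit_sample_ids)) seq_len(nrow(B)) else {
    assert_that(all(fit_sample_ids %in% rownames(B)), "fit_sample_ids not all present")
    match(fit_sample_ids, rownames(B))
  }
  ctr <- colMeans(B[fit_rows, , drop = FALSE])
  scl <- if (scale.) {
    s <- apply(B[fit_rows, , drop = FALSE], 2, sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(B))
  Bc <- sweep(sweep(B, 2, ctr), 2, scl, "/")
  pr <- prcomp(Bc[fit_rows, , drop = FALSE], center = FALSE, scale. = FALSE)
  k <- min(q, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  ev <- pr$sdev^2
  total <- sum(ev)

  # sign rule: largest-|loading| gene positive; ties -> first in sorted order
  ord <- order(present)
  for (j in seq_len(k)) {
    lv <- rot[ord, j]
    i_star <- which.max(abs(lv))
    if (lv[i_star] < 0) rot[, j] <- -rot[, j]
  }
  scores <- matrix(0, nrow(B), q, dimnames = list(rownames(B), paste0("PC", seq_len(q))))
  scores[, seq_len(k)] <- Bc %*% rot
  evr <- rep(0, q)
  if (total > 0) evr[seq_len(k)] <- ev[seq_len(k)] / total
  structure(list(
    pathway_name = pathway_name, omics_tag = tag,
    scores = scores, explained_variance_ratio = evr,
    rotation = rot, center = ctr, scale = scl, genes_used = present,
    n_genes_used = length(present),
    n_genes_missing = length(unique(genes)) - length(present), q = q
  ), class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat(sprintf("<pc_scores %s/%s: %d samples, q=%d, %d genes used (%d missing), evr1=%.3f>\n",
              x$pathway_name %||% "?", x$omics_tag, nrow(x$scores), x$q,
              x$n_genes_used, x$n_genes_missing, x$explained_variance_ratio[1]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
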