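#' Assemble per-sample pathway images from PC scores
#'
#' Stacks the per-(pathway, omics) PC scores into an `n x P x (O*q)` image
#' array: one row per pathway, columns ordered omics-major (all `q`
#' components of the first omics type, then the second, ...).
#'
#' @param pcs list of [pathway_pca()] results covering every
#'   (pathway, omics) pair on a shared sample set.
#' @param order character vector: pathway display order (a permutation of
#'   the pathway names found in `pcs`). Defaults to first-appearance order.
#' @param omics_types omics column order; defaults to first-appearance order.
#' @return a `pathway_image_set`: list with `images` (n x P x O*q array),
#'   `row_labels`, `col_labels` (tibble with `omics`, `pc`), `sample_ids`,
#'   `q`, `omics_types`.
#' @export
assemble_images <- function(pcs, order = NULL, omics_types = NULL) {
  assert_that(is.list(pcs) && length(pcs) > 0 &&
                all(vapply(pcs, inherits, logical(1), "pc_scores")),
              "pcs must be a list of pc_scores")
  pnames <- unique(vapply(pcs, function(p) p$pathway_name %||% NA_character_, character(1)))
  assert_that(!anyNA(pnames), "every pc_scores needs a pathway_name")
  tags <- unique(vapply(pcs, function(p) p$omics_tag, character(1)))
  if (is.null(omics_types)) omics_types <- tags
  omics_types <- unname(omics_types)
  assert_that(setequal(omics_types, tags), "omics_types must match the tags present in pcs")
  qs <- unique(vapply(pcs, function(p) p$q, numeric(1)))
  assert_that(length(qs) == 1, "all pc_scores must share the same q")
  q <- qs
  if (is.null(order)) order <- pnames
  assert_that(length(order) == length(pnames) && setequal(order, pnames),
              "order must be a permutation of the pathway names")

  key <- function(p, o) paste(p, o, sep = "\r")
  idx <- stats::setNames(seq_along(pcs),
                         vapply(pcs, function(p) key(p$pathway_name, p$omics_tag), character(1)))
  sample_ids <- rownames(pcs[[1]]$scores)
  for (p in pcs) {
    if (!identical(rownames(p$scores), sample_ids)) {
      extra <- setdiff(rownames(p$scores), sample_ids)
      miss <- setdiff(sample_ids, rownames(p$scores))
      abort(sprintf("sample sets differ across omics blocks (%s/%s): %d missing, %d extra (e.g. %s)",
                    p$pathway_name, p$omics_tag, length(miss), length(extra),
                    paste(head(c(miss, extra), 3), collapse = ", ")))
    }
  }
  n <- length(sample_ids); P <- length(order); O <- length(omics_types)
  col_labels <- tibble::tibble(
    omics = rep(omics_types, each = q),
    pc = rep(seq_len(q), times = O)
  )
  col_names <- paste0(col_labels$omics, "_PC", col_labels$pc)
  images <- array(0, dim = c(n, P, O * q),
                  dimnames = list(sample_ids, order, col_names))
  for (i in seq_len(P)) {
    for (o in seq_len(O)) {
      k <- key(order[i], omics_types[o])
      if (is.na(idx[k]))
        abort(sprintf("missing PC block for pathway '%s', omics '%s'", order[i], omics_types[o]))
      images[, i, (o - 1) * q + seq_len(q)] <- pcs[[idx[k]]]$scores
    }
  }
  structure(list(images = images, row_labels = order, col_labels = col_labels,
                 sample_ids = sample_ids, q = q, omics_types = omics_types),
            class = "pathway_image_set")
}

#' @export
print.pathway_image_set <- function(x, ...) {
  cat(sprintf("<pathway_image_set: %d samples, %d pathways x %d columns (%s, q=%d)>\n",
              length(x$sample_ids), length(x$row_labels), nrow(x$col_labels),
              paste(x$omics_types, collapse = "/"), x$q))
  invisible(x)
}

#' Build pathway images straight from omics matrices and gene sets
#'
#' Convenience wrapper: runs [pathway_pca()] for every (pathway, omics) pair
#' and assembles the image stack. Samples are restricted to ids shared by
#' all omics matrices (and by `sample_ids` when given).
#'
#' @param omics_list named list of [omics_matrix()] objects, in display
#'   (column-block) order.
#' @param gene_sets a [gene_set_collection()].
#' @param q components per omics type.
#' @param sample_ids optional sample subset/order to use.
#' @param scale. passed to [pathway_pca()].
#' @param fit_sample_ids optional ids PCA is fitted on (see [pathway_pca()]).
#' @return a `pathway_image_set`.
#' @export
build_pathway_images <- function(omics_list, gene_sets, q = 2, sample_ids = NULL,
                                 scale. = FALSE, fit_sample_ids = NULL) {
  assert_that(is.list(omics_list) && length(omics_list) > 0, "omics_list must be non-empty")
  shared <- Reduce(intersect, lapply(omics_list, rownames))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, shared)
    assert_that(length(missing) == 0,
                sprintf("samples not present in all omics: %s",
                        paste(head(missing, 3), collapse = ", ")))
    shared <- sample_ids
  }
  assert_that(length(shared) >= 2, "need at least 2 shared samples")
  omics_list <- lapply(omics_list, function(m) {
    omics_matrix(unclass(m)[shared, , drop = FALSE], omics_tag(m))
  })
  pcs <- list()
  for (m in omics_list) {
    for (nm in names(gene_sets)) {
      pcs[[length(pcs) + 1]] <- pathway_pca(m, gene_sets[[nm]], q, pathway_name = nm,
                                            scale. = scale., fit_sample_ids = fit_sample_ids)
    }
  }
  assemble_images(pcs, order = names(gene_sets),
                  omics_types = vapply(omics_list, omics_tag, character(1)))
}

#' Min-max normalize pathway images per pixel position
#'
#' For each pixel (pathway row, column), the minimum and maximum are computed
#' on the reference samples only; all samples are mapped through
#' `(x - min) / (max - min)` and clipped to `[0, 1]`. A constant reference
#' pixel maps every sample to 0. The returned parameters can be re-applied to
#' held-out data with [apply_normalization()].
#'
#' @param images a `pathway_image_set`.
#' @param reference_sample_ids ids the min/max are computed on (default: all).
#' @return list with `images` (normalized `pathway_image_set`) and `params`
#'   (list of `min`/`max` matrices).
#' @export
normalize_images <- function(images, reference_sample_ids = NULL) {
  assert_that(inherits(images, "pathway_image_set"), "images must be a pathway_image_set")
  if (is.null(reference_sample_ids)) reference_sample_ids <- images$sample_ids
  assert_that(length(reference_sample_ids) > 0, "reference sample set is empty")
  assert_that(all(reference_sample_ids %in% images$sample_ids),
              "reference ids must be a subset of the image sample ids")
  ref <- images$images[match(reference_sample_ids, images$sample_ids), , , drop = FALSE]
  mn <- apply(ref, c(2, 3), min)
  mx <- apply(ref, c(2, 3), max)
  params <- list(min = mn, max = mx)
  list(images = apply_normalization(images, params), params = params)
}

#' Apply stored min-max normalization parameters to an image set
#' @param images a `pathway_image_set`.
#' @param params normalization parameters from [normalize_images()].
#' @return a normalized `pathway_image_set` (values in `[0, 1]`).
#' @export
apply_normalization <- function(images, params) {
  rng <- params$max - params$min
  out <- images$images
  n <- dim(out)[1]
  for (s in seq_len(n)) {
    x <- (out[s, , ] - params$min) / ifelse(rng > 0, rng, 1)
    x[rng <= 0] <- 0
    out[s, , ] <- pmin(pmax(x, 0), 1)
  }
  images$images <- out
  images
}

#' Extract one sample's image as a labelled matrix
#' @param images a `pathway_image_set`.
#' @param sample_id sample to extract.
#' @return numeric matrix (pathways x columns).
#' @export
sample_image <- function(images, sample_id) {
  i <- match(sample_id, images$sample_ids)
  assert_that(!is.na(i), sprintf("sample '%s' not in image set", sample_id))
  m <- images$images[i, , ]
  dimnames(m) <- list(images$row_labels, dimnames(images$images)[[3]])
  m
}
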