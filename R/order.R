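#' Pathway-by-pathway Pearson correlation from assembled images
#'
#' Each pathway's feature vector is its image row concatenated across
#' samples (length `n * O * q`); correlations are computed between these
#' vectors. A zero-variance vector correlates 0 with everything
#' (1 on the diagonal).
#'
#' @param images a `pathway_image_set` (any row order; typically raw,
#'   pre-normalization values).
#' @return a `pathway_correlation`: list with `pathway_names` and `matrix`.
#' @export
pathway_correlation_matrix <- function(images) {
  assert_that(inherits(images, "pathway_image_set"), "images must be a pathway_image_set")
  P <- length(images$row_labels)
  if (P < 2) abort("need at least 2 pathways to compute a correlation matrix")
  # feature matrix: one column per pathway, rows = (sample, image column) pairs
  feat <- vapply(seq_len(P), function(i) as.vector(images$images[, i, ]),
                 numeric(dim(images$images)[1] * dim(images$images)[3]))
  sds <- apply(feat, 2, sd)
  M <- suppressWarnings(cor(feat))
  M[is.na(M)] <- 0
  diag(M) <- 1
  M <- (M + t(M)) / 2
  dimnames(M) <- list(images$row_labels, images$row_labels)
  structure(list(pathway_names = images$row_labels, matrix = M),
            class = "pathway_correlation")
}

#' @export
print.pathway_correlation <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("<pathway_correlation: %d pathways, off-diagonal range [%.3f, %.3f]>\n",
              length(x$pathway_names), min(off), max(off)))
  invisible(x)
}

#' Greedy correlation-based pathway ordering
#'
#' Places the two most correlated pathways first (the lower-index pathway of
#' the pair on row 1), then repeatedly appends the not-yet-selected pathway
#' most correlated with the pathway on the previous row. Signed correlation
#' is maximized; ties are broken by input order.
#'
#' @param corr a [pathway_correlation_matrix()] result.
#' @return character vector: pathway names in display order.
#' @export
greedy_order <- function(corr) {
  assert_that(inherits(corr, "pathway_correlation"), "corr must be a pathway_correlation")
  M <- corr$matrix
  P <- nrow(M)
  assert_that(P >= 2, "need at least 2 pathways")
  # best pair: strict > keeps the lexicographically first maximizer
  best <- c(1L, 2L); best_val <- -Inf
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      if (M[i, j] > best_val) { best_val <- M[i, j]; best <- c(i, j) }
    }
  }
  sel <- best
  remaining <- setdiff(seq_len(P), sel)
  while (length(remaining) > 0) {
    last <- sel[length(sel)]
    nxt <- remaining[which.max(M[last, remaining])]
    sel <- c(sel, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  corr$pathway_names[sel]
}

#' Reorder the pathway rows of an image set
#' @param images a `pathway_image_set`.
#' @param order permutation of `images$row_labels`.
#' @return the image set with rows and row labels permuted consistently.
#' @export
apply_order <- function(images, order) {
  assert_that(inherits(images, "pathway_image_set"), "images must be a pathway_image_set")
  assert_that(length(order) == length(images$row_labels) &&
                setequal(order, images$row_labels) && !anyDuplicated(order),
              "order must be a permutation of the pathway row labels")
  perm <- match(order, images$row_labels)
  images$images <- images$images[, perm, , drop = FALSE]
  dimnames(images$images)[[2]] <- order
  images$row_labels <- order
  images
}

#' Write / read a pathway order as a one-column text file
#' @param order character vector of pathway names.
#' @param path file path.
#' @export
write_order <- function(order, path) {
  writeLines(order, path)
  invisible(path)
}

#' @rdname write_order
#' @export
read_order <- function(path) readLines(path, warn = FALSE)
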