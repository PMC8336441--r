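make_small_cohort_images <- function(q = 2) {
  co <- generate_fixture()
  ls <- assign_labels(co$clinical)
  build_pathway_images(co$omics, co$gene_sets, q = q, sample_ids = ls$sample_id)
}

test_that("assembled images have omics-major column order and fixed geometry", {
  im <- make_small_cohort_images(q = 2)
  expect_equal(dim(im$images)[2:3], c(5L, 6L))
  expect_equal(im$col_labels$omics, rep(c("EXP", "CNV", "MET"), each = 2))
  expect_equal(im$col_labels$pc, rep(1:2, 3))
  # block values match a direct per-pathway PCA
  co <- generate_fixture()
  ls <- assign_labels(co$clinical)
  m <- omics_matrix(unclass(co$omics$CNV)[ls$sample_id, ], "CNV")
  pcs <- pathway_pca(m, co$gene_sets[[3]], q = 2, pathway_name = names(co$gene_sets)[3])
  expect_equal(im$images[, 3, 3:4], unname(pcs$scores), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate geometry: one omics and q = 1 give single-column images", {
  co <- generate_fixture()
  im <- build_pathway_images(co$omics["EXP"], co$gene_sets, q = 1)
  expect_equal(dim(im$images)[2:3], c(5L, 1L))
})

test_that("row reordering permutes rows and labels consistently", {
  im <- make_small_cohort_images()
  ord <- rev(im$row_labels)
  im2 <- apply_order(im, ord)
  expect_equal(im2$row_labels, ord)
  expect_equal(im2$images[, 1, ], im$images[, 5, ])
  # applying the inverse restores the original
  im3 <- apply_order(im2, im$row_labels)
  expect_equal(im3$images, im$images)
  # identity order is a no-op
  expect_equal(apply_order(im, im$row_labels)$images, im$images)
  expect_error(apply_order(im, c(im$row_labels[-1], im$row_labels[2])),
               "permutation")
})

test_that("assembly rejects inconsistent inputs", {
  set.seed(4)
  m1 <- make_omics(matrix(rnorm(12), 4, 3), tag = "EXP")
  m2 <- make_omics(matrix(rnorm(12), 4, 3), tag = "CNV",
                   samples = sprintf("T%02d", 1:4))
  g <- sprintf("G%02d", 1:3)
  p1 <- pathway_pca(m1, g, 1, pathway_name = "A")
  p2 <- pathway_pca(m2, g, 1, pathway_name = "A")
  expect_error(assemble_images(list(p1, p2)), "sample sets differ")
  # pathway A only measured in EXP, pathway B only in CNV
  m3 <- make_omics(matrix(rnorm(12), 4, 3), tag = "CNV")
  p3 <- pathway_pca(m3, g, 1, pathway_name = "B")
  expect_error(assemble_images(list(p1, p3)), "missing PC block")
})

test_that("min-max normalization maps, clips and handles constant pixels", {
  x <- array(0, c(3, 2, 1), dimnames = list(c("a", "b", "c"), NULL, NULL))
  x[, 1, 1] <- c(-2, 0, 2)   # reference range [-2, 2]
  x[, 2, 1] <- 1             # constant pixel
  im <- structure(list(images = x, row_labels = c("P1", "P2"),
                       col_labels = tibble::tibble(omics = "EXP", pc = 1),
                       sample_ids = c("a", "b", "c"), q = 1, omics_types = "EXP"),
                  class = "pathway_image_set")
  nr <- normalize_images(im, reference_sample_ids = c("a", "c"))
  expect_equal(nr$images$images[, 1, 1], c(a = 0, b = 0.5, c = 1))
  expect_equal(unname(nr$images$images[, 2, 1]), c(0, 0, 0))  # constant -> 0
  # held-out value beyond the reference range clips to [0, 1]
  x2 <- x; x2[1, 1, 1] <- 3; x2[2, 1, 1] <- -7
  im2 <- im; im2$images <- x2
  out <- apply_normalization(im2, nr$params)
  expect_equal(unname(out$images[1:2, 1, 1]), c(1, 0))
  expect_error(normalize_images(im, reference_sample_ids = character(0)), "empty")
})

test_that("permuting gene columns of an omics matrix leaves images unchanged", {
  co <- generate_fixture()
  ls <- assign_labels(co$clinical)
  im1 <- build_pathway_images(co$omics, co$gene_sets, q = 2, sample_ids = ls$sample_id)
  perm <- sample(ncol(co$omics$EXP))
  co$omics$EXP <- omics_matrix(unclass(co$omics$EXP)[, perm], "EXP")
  im2 <- build_pathway_images(co$omics, co$gene_sets, q = 2, sample_ids = ls$sample_id)
  expect_equal(im1$images, im2$images, tolerance = 1e-10)
})
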