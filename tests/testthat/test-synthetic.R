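test_that("identical config and seed give bit-identical cohorts", {
  cf <- synthetic_config(n_samples = 40, n_pathways = 6, genes_per_pathway = 5,
                         signal_pathways = tibble::tibble(pathway = 1L, omics = "EXP"),
                         effect_size = 1, seed = 11)
  a <- generate_cohort(cf)
  b <- generate_cohort(cf)
  expect_identical(a$omics, b$omics)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$gene_sets, b$gene_sets)
  # different seed: same cohort size, different values
  cf2 <- cf; cf2$seed <- 12L
  c2 <- generate_cohort(cf2)
  expect_identical(nrow(c2$omics$EXP), nrow(a$omics$EXP))
  expect_false(identical(c2$clinical$survival_years, a$clinical$survival_years))
})

test_that("null construction: zero effect size leaves no mean group difference", {
  # independent genes and balanced groups so the Monte-Carlo error of the
  # mean standardized difference is ~ 1/sqrt(n_genes * n_samples)
  cf <- synthetic_config(n_samples = 200, n_pathways = 10, genes_per_pathway = 10,
                         effect_size = 0, within_pathway_rho = 0,
                         lts_fraction = 0.5, missing_gene_rate = 0, seed = 21)
  co <- generate_cohort(cf)
  grp <- co$truth$is_lts
  d <- vapply(colnames(co$omics$EXP), function(g) {
    v <- unclass(co$omics$EXP)[, g]
    (mean(v[grp]) - mean(v[!grp])) / sd(v)
  }, numeric(1))
  expect_lt(abs(mean(d)), 3 / sqrt(length(d) * cf$n_samples))
})

test_that("planted effect: standardized group difference matches effect_size", {
  cf <- synthetic_config(n_samples = 300, n_pathways = 10, genes_per_pathway = 20,
                         signal_pathways = tibble::tibble(pathway = c(2L, 5L),
                                                          omics = c("EXP", "EXP")),
                         effect_size = 2, within_pathway_rho = 0,
                         missing_gene_rate = 0, seed = 31)
  co <- generate_cohort(cf)
  grp <- co$truth$is_lts
  sig_genes <- unlist(co$gene_sets[c(2, 5)])
  d <- vapply(sig_genes, function(g) {
    v <- unclass(co$omics$EXP)[, g]
    # pooled within-group SD so the planted shift does not inflate the scale
    sp <- sqrt((sum((v[grp] - mean(v[grp]))^2) + sum((v[!grp] - mean(v[!grp]))^2)) /
                 (length(v) - 2))
    (mean(v[grp]) - mean(v[!grp])) / sp
  }, numeric(1))
  expect_lt(abs(mean(d) - 2), 0.15)
  # non-signal omics carries no shift
  d0 <- vapply(sig_genes, function(g) {
    v <- unclass(co$omics$CNV)[, g]
    (mean(v[grp]) - mean(v[!grp])) / sd(v)
  }, numeric(1))
  expect_lt(abs(mean(d0)), 0.15)
})

test_that("within-pathway correlation follows the latent-factor model", {
  cf <- synthetic_config(n_samples = 400, n_pathways = 4, genes_per_pathway = 10,
                         within_pathway_rho = 0.5, factor_overlap = 0,
                         missing_gene_rate = 0, seed = 41)
  co <- generate_cohort(cf)
  m <- unclass(co$omics$EXP)
  g1 <- co$gene_sets[[1]]
  cors <- cor(m[, g1])
  expect_lt(abs(mean(cors[upper.tri(cors)]) - 0.5), 0.08)
  # across pathways (no overlap): near zero
  g2 <- co$gene_sets[[3]]
  cross <- cor(m[, g1], m[, g2])
  expect_lt(abs(mean(cross)), 0.08)
})

test_that("survival times respect the label threshold and censoring plan", {
  cf <- synthetic_config(n_samples = 200, seed = 51)
  co <- generate_cohort(cf)
  grp <- co$truth$is_lts
  expect_true(all(co$clinical$survival_years[grp] > 2))
  expect_true(all(co$clinical$survival_years[!grp] <= 2))
  expect_equal(sum(co$clinical$event == 0), round(0.1 * 200))
  # ages overlap but differ by roughly age_shift
  dt <- mean(co$clinical$age[!grp]) - mean(co$clinical$age[grp])
  expect_gt(dt, 13 - 4 * 8 / sqrt(40))
  expect_lt(dt, 13 + 4 * 8 / sqrt(40))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(genes_per_pathway = 1), "genes_per_pathway")
  expect_error(synthetic_config(within_pathway_rho = 1), "within_pathway_rho")
  expect_error(synthetic_config(lts_fraction = 0), "lts_fraction")
  expect_error(synthetic_config(
    n_pathways = 4,
    signal_pathways = tibble::tibble(pathway = 5L, omics = "EXP")),
    "signal pathway indices")
  expect_error(synthetic_config(
    signal_pathways = tibble::tibble(pathway = 1L, omics = "XXX")),
    "omics tags")
})

test_that("frozen fixture is stable, complete and internally consistent", {
  f1 <- generate_fixture()
  f2 <- generate_fixture()
  expect_identical(f1, f2)
  expect_equal(nrow(f1$clinical), 12)
  for (m in f1$omics) expect_equal(nrow(m), 12)
  expect_length(f1$gene_sets, 5)
  # every pathway keeps at least one measured gene in every omics type
  for (m in f1$omics) {
    for (nm in names(f1$gene_sets)) {
      expect_gte(length(intersect(f1$gene_sets[[nm]], colnames(m))), 1)
    }
  }
})
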