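test_that("exact rank-sum p-value matches full enumeration", {
  # fully separated 3 vs 3: 2 of C(6,3)=20 assignments are as extreme
  maps <- array(0, c(6, 1, 1))
  maps[, 1, 1] <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3)
  diffs <- make_diff_set(maps, rep(c("LTS", "non-LTS"), each = 3))
  res <- pixelwise_test(diffs)
  expect_equal(res$raw_p[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(res$raw_p[1, 1],
               enumerate_ranksum_p(maps[1:3, 1, 1], maps[4:6, 1, 1]),
               tolerance = 1e-12)
})

test_that("exact branch agrees with enumeration on random small samples", {
  for (s in 1:10) {
    v <- withr::with_seed(500 + s, round(runif(9), 3))
    if (any(duplicated(v))) next
    maps <- array(v, c(9, 1, 1))
    diffs <- make_diff_set(maps, rep(c("LTS", "non-LTS"), c(4, 5)))
    res <- pixelwise_test(diffs)
    expect_equal(res$raw_p[1, 1], enumerate_ranksum_p(v[1:4], v[5:9]),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni adjustment is the capped product with the test count", {
  d <- small_images_with_model()
  res <- pixelwise_test(d$diffs)
  expect_equal(res$n_tests, 8 * 6)
  expect_equal(res$adjusted_p, pmin(res$raw_p * res$n_tests, 1))
  expect_true(all(res$adjusted_p >= res$raw_p))
  expect_true(all(res$adjusted_p <= 1))
  # matches the standard multiple-testing routine
  expect_equal(as.vector(res$adjusted_p),
               p.adjust(as.vector(res$raw_p), method = "bonferroni"))
})

test_that("identical values in both groups give p = 1 by convention", {
  maps <- array(0.5, c(8, 2, 1))
  maps[, 2, 1] <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)  # control pixel
  diffs <- make_diff_set(maps, rep(c("LTS", "non-LTS"), each = 4))
  res <- pixelwise_test(diffs)
  expect_equal(res$raw_p[1, 1], 1)
  expect_lt(res$raw_p[2, 1], 1)
})

test_that("null difference maps give approximately uniform raw p-values", {
  maps <- withr::with_seed(77, array(runif(50 * 40 * 6), c(50, 40, 6)))
  diffs <- make_diff_set(maps, rep(c("LTS", "non-LTS"), c(20, 30)))
  res <- pixelwise_test(diffs)
  frac <- mean(res$raw_p < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 240))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 240))
  expect_equal(sum(res$significant_mask), 0)
})

fake_ptest <- function(sig_pixels, d = c(60, 6)) {
  adj <- matrix(0.9, d[1], d[2],
                dimnames = list(sprintf("PW%03d", seq_len(d[1])),
                                paste0("C", seq_len(d[2]))))
  for (px in sig_pixels) adj[px[1], px[2]] <- 1e-5
  structure(list(raw_p = adj / d[1] / d[2], adjusted_p = adj,
                 n_tests = prod(d), alpha = 0.001,
                 significant_mask = adj < 0.001),
            class = "pixel_test_result")
}

test_that("hot spots are 4-connected components of the significance mask", {
  res <- fake_ptest(list(c(4, 1), c(5, 1), c(6, 1), c(4, 2), c(5, 2), c(51, 3)))
  hs <- find_hotspots(res)
  expect_equal(max(hs$hotspot), 2)
  expect_equal(as.vector(table(hs$hotspot)), c(5L, 1L))
  expect_equal(attr(hs, "n_unique_pathways"), 4)  # rows 4,5,6,51
  # empty mask
  expect_equal(nrow(find_hotspots(fake_ptest(list()))), 0)
  # full mask is one component covering every pixel
  res_full <- fake_ptest(list())
  res_full$adjusted_p[] <- 1e-6
  hs_full <- find_hotspots(res_full)
  expect_equal(max(hs_full$hotspot), 1)
  expect_equal(nrow(hs_full), 60 * 6)
  # diagonal neighbours are separate components
  res_diag <- fake_ptest(list(c(10, 1), c(11, 2)))
  expect_equal(max(find_hotspots(res_diag)$hotspot), 2)
})

test_that("median split halves the cohort and log-rank behaves at the nulls", {
  # identical survival experience in both value groups -> statistic 0, p 1
  cl <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:8),
    survival_years = rep(c(1, 2, 3, 4), 2),
    event = rep(c(1L, 0L, 1L, 1L), 2),
    age = 60)
  v <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)[c(1, 3, 5, 7, 2, 4, 6, 8)],
                cl$sample_id)
  # arrange so low/high groups get identical survival rows
  v <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.9, 0.8, 0.7, 0.6), cl$sample_id)
  km <- km_logrank_median_split(v, cl)
  expect_equal(km$statistic, 0, tolerance = 1e-12)
  expect_equal(km$p_value, 1, tolerance = 1e-12)
  # split rule: median of 4 distinct values gives 2 vs 2
  v4 <- setNames(c(0.1, 0.2, 0.3, 0.4), cl$sample_id[1:4])
  km4 <- km_logrank_median_split(v4, cl[1:4, ])
  expect_equal(as.vector(table(km4$groups$group)), c(2L, 2L))
  expect_setequal(km4$groups$sample_id[km4$groups$group == "low"],
                  c("S01", "S02"))
  # degenerate split rejected
  expect_error(km_logrank_median_split(setNames(rep(1, 4), cl$sample_id[1:4]),
                                       cl[1:4, ]), "degenerate")
})

test_that("a pixel tracking true group membership is prognostic at n = 200", {
  co <- generate_cohort(synthetic_config(n_samples = 200, n_pathways = 4,
                                         genes_per_pathway = 4, seed = 60))
  v <- setNames(as.numeric(co$truth$is_lts) +
                  withr::with_seed(61, rnorm(200, sd = 1e-3)),
                co$clinical$sample_id)
  km <- km_logrank_median_split(v, co$clinical)
  expect_lt(km$p_value, 0.01)
  # survival cross-check: survdiff on the same split agrees
  gl <- glance(km)
  expect_equal(gl$statistic, km$statistic)
})
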