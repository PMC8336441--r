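#' Pixel-wise rank-sum tests on class-difference maps
#'
#' For every pixel, the difference-map values of the two survival groups are
#' compared with a two-sided Wilcoxon rank-sum test: exact enumeration when
#' the smaller group has at most 10 samples and there are no ties, otherwise
#' the normal approximation with tie and continuity correction. P-values are
#' Bonferroni-corrected over all `rows x cols` pixels. A pixel whose values
#' are identical in both groups gets p = 1 by convention.
#'
#' @param diffs a [difference_maps()] result.
#' @param alpha significance level applied to the adjusted p-values
#'   (default 0.001).
#' @return a `pixel_test_result`: matrices `raw_p` and `adjusted_p`
#'   (`adjusted_p = min(1, raw_p * n_tests)`), `n_tests`, `alpha`, and the
#'   logical `significant_mask`.
#' @export
pixelwise_test <- function(diffs, alpha = 0.001) {
  assert_that(inherits(diffs, "difference_map_set"), "diffs must be a difference_map_set")
  g1 <- diffs$group == "LTS"
  g2 <- diffs$group == "non-LTS"
  assert_that(sum(g1) >= 2 && sum(g2) >= 2, "both groups need at least 2 samples")
  d <- dim(diffs$maps)
  raw <- matrix(NA_real_, d[2], d[3], dimnames = dimnames(diffs$maps)[2:3])
  for (j in seq_len(d[2])) {
    for (k in seq_len(d[3])) {
      x <- diffs$maps[g1, j, k]
      y <- diffs$maps[g2, j, k]
      if (length(unique(c(x, y))) == 1) {
        raw[j, k] <- 1
        next
      }
      exact <- min(length(x), length(y)) <= 10 && !any(duplicated(c(x, y)))
      p <- suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
      raw[j, k] <- if (is.na(p)) 1 else min(p, 1)
    }
  }
  n_tests <- d[2] * d[3]
  adj <- pmin(raw * n_tests, 1)
  structure(list(raw_p = raw, adjusted_p = adj, n_tests = n_tests,
                 alpha = alpha, significant_mask = adj < alpha),
            class = "pixel_test_result")
}

#' @export
print.pixel_test_result <- function(x, ...) {
  cat(sprintf("<pixel_test_result: %d pixels, %d significant at adjusted p < %g>\n",
              x$n_tests, sum(x$significant_mask), x$alpha))
  invisible(x)
}

#' @method tidy pixel_test_result
#' @export
tidy.pixel_test_result <- function(x, ...) {
  dn <- dimnames(x$raw_p)
  d <- dim(x$raw_p)
  tb <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    pathway = if (!is.null(dn[[1]])) rep(dn[[1]], d[2]) else NA_character_,
    pixel = if (!is.null(dn[[2]])) rep(dn[[2]], each = d[1]) else NA_character_,
    p_value = as.vector(x$raw_p),
    adjusted_p = as.vector(x$adjusted_p),
    significant = as.vector(x$significant_mask)
  )
  dplyr::arrange(tb, .data$adjusted_p)
}

#' Hot spots: connected components of significant pixels
#'
#' Labels the 4-connected components of the significance mask (neighbors
#' share an edge, not a corner). Single-pixel components are reported.
#'
#' @param result a [pixelwise_test()] result.
#' @param alpha significance level; defaults to the one stored in `result`.
#' @return a tibble with one row per significant pixel: `hotspot` (component
#'   id in discovery order), `row`, `col`, `pathway`, `pixel` (column
#'   label), `adjusted_p`. The number of distinct pathways is attached as
#'   attribute `n_unique_pathways`.
#' @export
find_hotspots <- function(result, alpha = NULL) {
  assert_that(inherits(result, "pixel_test_result"), "result must be a pixel_test_result")
  if (is.null(alpha)) alpha <- result$alpha
  mask <- result$adjusted_p < alpha
  d <- dim(mask)
  comp <- matrix(0L, d[1], d[2])
  n_comp <- 0L
  for (j in seq_len(d[1])) {
    for (k in seq_len(d[2])) {
      if (!mask[j, k] || comp[j, k] > 0) next
      n_comp <- n_comp + 1L
      queue <- list(c(j, k)); comp[j, k] <- n_comp
      while (length(queue) > 0) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (nb in list(cur + c(-1, 0), cur + c(1, 0), cur + c(0, -1), cur + c(0, 1))) {
          if (nb[1] >= 1 && nb[1] <= d[1] && nb[2] >= 1 && nb[2] <= d[2] &&
              mask[nb[1], nb[2]] && comp[nb[1], nb[2]] == 0) {
            comp[nb[1], nb[2]] <- n_comp
            queue[[length(queue) + 1]] <- nb
          }
        }
      }
    }
  }
  idx <- which(comp > 0, arr.ind = TRUE)
  dn <- dimnames(result$raw_p)
  tb <- tibble::tibble(
    hotspot = comp[idx],
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    pathway = if (!is.null(dn[[1]])) dn[[1]][idx[, 1]] else NA_character_,
    pixel = if (!is.null(dn[[2]])) dn[[2]][idx[, 2]] else NA_character_,
    adjusted_p = result$adjusted_p[idx]
  )
  tb <- dplyr::arrange(tb, .data$hotspot, .data$row, .data$col)
  attr(tb, "n_unique_pathways") <- length(unique(tb$pathway))
  tb
}

#' Kaplan-Meier median-split log-rank test for one pixel
#'
#' Dichotomizes samples by the median of the supplied per-sample values
#' (low: value <= median; high: value > median) and compares survival
#' between the two groups with a standard log-rank test, censoring handled
#' through Kaplan-Meier estimation.
#'
#' @param pixel_values named numeric vector (names = sample ids), typically
#'   the raw PC values of one pathway-image pixel.
#' @param clinical clinical table with `sample_id`, `survival_years`,
#'   `event`.
#' @return a `km_split` object: `statistic` (log-rank chi-square), `p_value`
#'   (1 df), `fit` (a [survival::survfit] object), and a `groups` tibble.
#' @export
km_logrank_median_split <- function(pixel_values, clinical) {
  validate_clinical(clinical)
  assert_that(!is.null(names(pixel_values)), "pixel_values must be named by sample id")
  common <- intersect(names(pixel_values), clinical$sample_id)
  assert_that(length(common) >= 4, "need at least 4 samples shared with the clinical table")
  v <- pixel_values[common]
  if (length(unique(v)) == 1)
    abort("degenerate split: all pixel values are equal")
  med <- median(v)
  grp <- factor(ifelse(v <= med, "low", "high"), levels = c("low", "high"))
  if (min(table(grp)) < 2)
    abort("degenerate split: fewer than 2 samples on one side of the median")
  cl <- clinical[match(common, clinical$sample_id), ]
  df <- data.frame(time = cl$survival_years, event = cl$event, group = grp)
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- sdf$chisq
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  structure(list(statistic = stat, p_value = p, fit = fit,
                 groups = tibble::tibble(sample_id = common, value = as.numeric(v),
                                         group = as.character(grp)),
                 median = med),
            class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("<km_split: log-rank chisq %.3f, p = %.4g (%d low / %d high)>\n",
              x$statistic, x$p_value, sum(x$groups$group == "low"),
              sum(x$groups$group == "high")))
  invisible(x)
}

#' @method glance km_split
#' @export
glance.km_split <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_low = sum(x$groups$group == "low"),
                 n_high = sum(x$groups$group == "high"))
}
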