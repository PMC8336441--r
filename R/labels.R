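#' Assign long-term-survival labels from a clinical table
#'
#' Samples surviving beyond `threshold_years` are long-term survivors
#' (`LTS`), regardless of censoring status. Samples with observed death at or
#' below the threshold are `non-LTS`. Samples censored at or below the
#' threshold carry no usable label (their true survival is unknown) and are
#' excluded from all further analysis.
#'
#' @param clinical data frame with columns `sample_id`, `survival_years`,
#'   `event` (1 = death observed, 0 = censored).
#' @param threshold_years positive survival threshold; default 2.
#' @return a `label_set`: list with `sample_id`, `label` (factor with levels
#'   `LTS`, `non-LTS`, aligned with `sample_id`) and `excluded_ids`.
#' @export
assign_labels <- function(clinical, threshold_years = 2.0) {
  assert_that(is.numeric(threshold_years) && threshold_years > 0,
              "threshold_years must be positive")
  validate_clinical(clinical)
  t <- clinical$survival_years
  ev <- clinical$event
  lts <- t > threshold_years
  excluded <- !lts & ev == 0
  keep <- !excluded
  structure(list(
    sample_id = clinical$sample_id[keep],
    label = factor(ifelse(lts[keep], "LTS", "non-LTS"), levels = c("LTS", "non-LTS")),
    excluded_ids = clinical$sample_id[excluded],
    threshold_years = threshold_years
  ), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set: %d LTS, %d non-LTS, %d excluded (follow-up <= %g y)>\n",
              sum(x$label == "LTS"), sum(x$label == "non-LTS"),
              length(x$excluded_ids), x$threshold_years))
  invisible(x)
}

#' @method tidy label_set
#' @export
tidy.label_set <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(sample_id = x$sample_id, label = as.character(x$label)),
    tibble::tibble(sample_id = x$excluded_ids, label = NA_character_)
  )
}

#' Per-class weights inversely proportional to class frequency
#'
#' `w_c = N / (2 n_c)`, so the minority class receives the larger weight and
#' the weight ratio equals the inverse of the class-size ratio.
#'
#' @param labels factor of class labels (or a `label_set`).
#' @return named numeric vector of weights, one per class level.
#' @export
compute_class_weights <- function(labels) {
  if (inherits(labels, "label_set")) labels <- labels$label
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts == 0))
    abort(sprintf("class '%s' has zero members", names(counts)[counts == 0][1]))
  w <- as.numeric(sum(counts) / (length(counts) * counts))
  stats::setNames(w, names(counts))
}
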