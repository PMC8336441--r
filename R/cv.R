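# Stratified fold ids: within each class, shuffled samples are dealt
# round-robin across folds, so every fold carries both classes.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      fold[idx[sample(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Stratified split of `idx` into (train, val) with val_frac per class.
stratified_split <- function(idx, y, val_frac, seed) {
  val <- integer(0)
  with_seed(seed, {
    for (cls in levels(y)) {
      cidx <- idx[y[idx] == cls]
      n_val <- max(1L, round(val_frac * length(cidx)))
      val <- c(val, cidx[sample(length(cidx), n_val)])
    }
  })
  list(train = setdiff(idx, val), val = sort(val))
}

#' Repeated stratified cross-validation of the pathway-image CNN
#'
#' Runs `n_repeats` independent stratified `n_folds`-fold cross-validations.
#' In each split the fold is the test set (20% for 5 folds) and the
#' remaining samples are split 80/20 (stratified) into training and
#' validation sets; a model is trained fresh per split and its test AUC
#' recorded. All randomness derives deterministically from `seed`.
#'
#' @param images `pathway_image_set` or `n x rows x cols` array, already
#'   normalized (unless `image_builder` is given).
#' @param labels factor with levels `LTS`, `non-LTS` (or a `label_set`),
#'   aligned with the image rows.
#' @param age optional age vector (required when `config$use_age`).
#' @param n_repeats,n_folds protocol size (defaults 30 and 5).
#' @param config a [cnn_config()].
#' @param seed master seed; per-repeat and per-fold seeds are derived from it.
#' @param image_builder optional function `function(train_ids)` returning an
#'   `n x rows x cols` array for *all* samples, rebuilt using only the
#'   training samples (e.g. within-fold PCA refitting and normalization to
#'   avoid train/test leakage). When `NULL`, `images` is used as-is.
#' @param verbose print per-split progress.
#' @return a `pathcnn_cv` object: AUC matrix (`n_repeats x n_folds`),
#'   `mean_auc`, `sd_auc`, per-repeat fold assignments, config echo.
#' @export
repeated_cv <- function(images, labels, age = NULL, n_repeats = 30, n_folds = 5,
                        config = cnn_config(), seed = 1, image_builder = NULL,
                        verbose = FALSE) {
  if (inherits(labels, "label_set")) {
    ids <- if (inherits(images, "pathway_image_set")) images$sample_ids else dimnames(as_image_array(images))[[1]]
    assert_that(!is.null(ids) && setequal(ids, labels$sample_id),
                "image samples and label samples differ")
    labels <- labels$label[match(ids, labels$sample_id)]
  }
  sample_ids <- if (inherits(images, "pathway_image_set")) images$sample_ids else dimnames(as_image_array(images))[[1]]
  x <- as_image_array(images)
  y <- factor(labels, levels = c("LTS", "non-LTS"))
  assert_that(!anyNA(y) && length(y) == dim(x)[1], "labels must align with image rows")
  counts <- table(y)
  if (any(counts < n_folds))
    abort(sprintf("class '%s' has %d samples, fewer than n_folds = %d",
                  names(counts)[which.min(counts)], min(counts), n_folds))
  if (config$use_age)
    assert_that(!is.null(age) && length(age) == length(y), "config uses age: supply one value per sample")

  aucs <- matrix(NA_real_, n_repeats, n_folds)
  assignments <- vector("list", n_repeats)
  splits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds, derive_seed(seed, "repeat", r))
    assignments[[r]] <- fold
    splits[[r]] <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      test_idx <- which(fold == f)
      rest <- which(fold != f)
      sp <- stratified_split(rest, y, 0.2, derive_seed(seed, "repeat", r, "fold", f, "val"))
      splits[[r]][[f]] <- list(train = sp$train, val = sp$val, test = test_idx)
      xs <- x
      if (!is.null(image_builder)) {
        xs <- image_builder(sample_ids[sp$train])
        xs <- as_image_array(xs)
      }
      cf <- config
      cf$seed <- derive_seed(seed, "repeat", r, "fold", f, "model")
      model <- build_cnn(dim(xs)[2:3], cf)
      model <- train_model(model,
                           xs[sp$train, , , drop = FALSE], y[sp$train],
                           xs[sp$val, , , drop = FALSE], y[sp$val],
                           age_train = age[sp$train], age_val = age[sp$val],
                           eval_train = FALSE)
      aucs[r, f] <- evaluate_auc(model, xs[test_idx, , , drop = FALSE], y[test_idx],
                                 age = age[test_idx])
      if (verbose)
        message(sprintf("repeat %d fold %d: test AUC %.3f", r, f, aucs[r, f]))
    }
  }
  structure(list(aucs = aucs,
                 mean_auc = if (length(aucs)) mean(aucs) else NA_real_,
                 sd_auc = if (length(aucs) > 1) sd(as.vector(aucs)) else NA_real_,
                 fold_assignments = assignments, splits = splits, n_repeats = n_repeats,
                 n_folds = n_folds, config = config, seed = seed,
                 sample_ids = sample_ids),
            class = "pathcnn_cv")
}

#' @export
print.pathcnn_cv <- function(x, ...) {
  cat(sprintf("<pathcnn_cv: %d repeats x %d folds, AUC %.3f +/- %.3f>\n",
              x$n_repeats, x$n_folds, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' @method tidy pathcnn_cv
#' @export
tidy.pathcnn_cv <- function(x, ...) {
  tibble::tibble(
    repeat_id = rep(seq_len(x$n_repeats), x$n_folds),
    fold = rep(seq_len(x$n_folds), each = x$n_repeats),
    auc = as.vector(x$aucs)
  ) |> dplyr::arrange(.data$repeat_id, .data$fold)
}

#' @method glance pathcnn_cv
#' @export
glance.pathcnn_cv <- function(x, ...) {
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc,
                 n_repeats = x$n_repeats, n_folds = x$n_folds)
}
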