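#' Model hyperparameters for the pathway-image CNN
#'
#' The architecture is fixed: two 3x3 convolutions (32 then 64 filters, each
#' followed by ReLU), a 4x2 max-pooling layer, dropout, flattening, an
#' optional standardized-age input concatenated to the flattened features, a
#' 64-unit ReLU dense layer, dropout, and a 2-unit softmax. Training uses
#' Adam with weighted cross-entropy.
#'
#' @param conv_filters filters of the two convolutional layers.
#' @param kernel convolution kernel size (only 3x3 supported).
#' @param pool max-pooling window (rows, cols).
#' @param dropout_conv,dropout_dense dropout rates in `[0, 1)`.
#' @param dense_units width of the fully connected layer.
#' @param epochs,batch_size,learning_rate training schedule (defaults: 30
#'   epochs, batches of 64, Adam at 1e-4).
#' @param use_age whether the age covariate enters the dense layer.
#' @param padding `"same"` (default) or `"valid"` for both convolutions.
#'   With `"same"` the class-activation maps keep the full image geometry,
#'   so activation differences can resolve individual PC columns.
#' @param seed integer seed for weight initialization, shuffling and dropout.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(conv_filters = c(32L, 64L), kernel = c(3L, 3L),
                       pool = c(4L, 2L), dropout_conv = 0.25,
                       dense_units = 64L, dropout_dense = 0.5,
                       epochs = 30L, batch_size = 64L, learning_rate = 1e-4,
                       use_age = TRUE, padding = c("same", "valid"), seed = 1L) {
  padding <- match.arg(padding)
  assert_that(identical(as.integer(kernel), c(3L, 3L)), "only 3x3 kernels are supported")
  assert_that(length(conv_filters) == 2 && all(conv_filters >= 1),
              "conv_filters must be two positive counts")
  assert_that(all(pool >= 1) && length(pool) == 2, "pool must be two positive counts")
  assert_that(is_fraction(dropout_conv) && is_fraction(dropout_dense),
              "dropout rates must be in [0, 1)")
  assert_that(is_count(dense_units) && is_count(epochs) && is_count(batch_size),
              "dense_units, epochs, batch_size must be positive counts")
  assert_that(learning_rate > 0, "learning_rate must be positive")
  structure(list(conv_filters = as.integer(conv_filters), kernel = c(3L, 3L),
                 pool = as.integer(pool), dropout_conv = dropout_conv,
                 dense_units = as.integer(dense_units), dropout_dense = dropout_dense,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, use_age = isTRUE(use_age),
                 padding = padding, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Build an untrained pathway-image CNN
#'
#' Computes the layer geometry for the given image shape, initializes
#' weights (Glorot uniform, seeded) and returns a model object that exposes
#' the last convolutional layer for Grad-CAM.
#'
#' @param image_shape `c(rows, cols)` of the input pathway image.
#' @param config a [cnn_config()].
#' @return a `pathcnn_model`.
#' @export
build_cnn <- function(image_shape, config = cnn_config()) {
  assert_that(inherits(config, "cnn_config"), "config must be a cnn_config")
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  ph <- config$pool[1]; pw <- config$pool[2]
  if (config$padding == "same") {
    Hc <- H; Wc <- W
    min_h <- ph; min_w <- pw
  } else {
    Hc <- H - 4L; Wc <- W - 4L
    min_h <- 4L + ph; min_w <- 4L + pw
  }
  if (H < min_h || W < min_w || Hc < 1L || Wc < 1L || Hc < ph || Wc < pw)
    abort(sprintf("image shape %dx%d too small for two 3x3 convolutions (+%s padding) and %dx%d pooling; minimal shape is %dx%d",
                  H, W, config$padding, ph, pw, min_h, min_w))
  Hp <- Hc %/% ph; Wp <- Wc %/% pw
  f1 <- config$conv_filters[1]; f2 <- config$conv_filters[2]
  flat <- Hp * Wp * f2
  dense_in <- flat + as.integer(config$use_age)
  params <- with_seed(derive_seed(config$seed, "init"), list(
    W1 = glorot_uniform(9L, f1, 9L, 9L * f1), b1 = numeric(f1),
    W2 = glorot_uniform(9L * f1, f2, 9L * f1, 9L * f2), b2 = numeric(f2),
    Wd = glorot_uniform(dense_in, config$dense_units, dense_in, config$dense_units),
    bd = numeric(config$dense_units),
    Wo = glorot_uniform(config$dense_units, 2L, config$dense_units, 2L),
    bo = numeric(2L)
  ))
  structure(list(
    config = config, input_shape = c(H, W),
    shapes = list(conv = c(Hc, Wc), pool = c(Hp, Wp), flat = flat, dense_in = dense_in),
    params = params, classes = c("LTS", "non-LTS"),
    age_stats = NULL, trained = FALSE, history = NULL
  ), class = "pathcnn_model")
}

#' @export
print.pathcnn_model <- function(x, ...) {
  cat(sprintf(paste0("<pathcnn_model %s: input %dx%d -> conv %dx%dx%d -> pool %dx%dx%d",
                     " -> dense %d%s -> softmax(2)%s>\n"),
              if (x$trained) "(trained)" else "(untrained)",
              x$input_shape[1], x$input_shape[2],
              x$shapes$conv[1], x$shapes$conv[2], x$config$conv_filters[2],
              x$shapes$pool[1], x$shapes$pool[2], x$config$conv_filters[2],
              x$config$dense_units, if (x$config$use_age) " (+age)" else "",
              ""))
  invisible(x)
}

# Coerce image input (pathway_image_set or n x h x w array) to an array.
as_image_array <- function(x) {
  if (inherits(x, "pathway_image_set")) return(x$images)
  assert_that(is.array(x) && length(dim(x)) == 3, "images must be an n x rows x cols array")
  x
}

# Full forward pass. In training mode dropout masks are sampled from the
# current RNG stream; in eval mode dropout is the identity.
nn_forward <- function(model, x, age = NULL, training = FALSE) {
  cf <- model$config
  d <- dim(x)
  N <- d[1]
  dim(x) <- c(d, 1L)
  c1 <- conv_forward(x, model$params$W1, model$params$b1, cf$padding)
  r1 <- pmax(c1$out, 0)
  c2 <- conv_forward(r1, model$params$W2, model$params$b2, cf$padding)
  a2 <- pmax(c2$out, 0)                    # last-conv feature maps A^k
  pl <- maxpool_forward(a2, cf$pool)
  h <- pl$out
  mask1 <- NULL
  if (training && cf$dropout_conv > 0) {
    mask1 <- array((runif(length(h)) >= cf$dropout_conv) / (1 - cf$dropout_conv), dim(h))
    h <- h * mask1
  }
  flat <- h
  dim(flat) <- c(N, model$shapes$flat)
  if (cf$use_age) {
    assert_that(!is.null(age) && length(age) == N, "model uses age: supply one value per sample")
    z_age <- (age - model$age_stats$mean) / model$age_stats$sd
    flat <- cbind(flat, z_age)
  }
  zd <- flat %*% model$params$Wd + rep(model$params$bd, each = N)
  hd <- pmax(zd, 0)
  mask2 <- NULL
  if (training && cf$dropout_dense > 0) {
    mask2 <- matrix((runif(length(hd)) >= cf$dropout_dense) / (1 - cf$dropout_dense), nrow(hd))
    hd <- hd * mask2
  }
  logits <- hd %*% model$params$Wo + rep(model$params$bo, each = N)
  probs <- softmax_rows(logits)
  list(c1 = c1, r1 = r1, c2 = c2, a2 = a2, pl = pl, mask1 = mask1, flat = flat,
       zd = zd, hd = hd, mask2 = mask2, logits = logits, probs = probs, n = N)
}

# Backward pass from weighted cross-entropy; y_idx in {1, 2}, sw per-sample
# weights. Returns gradients named like the params.
nn_backward <- function(model, fw, y_idx, sw) {
  cf <- model$config
  N <- fw$n
  Y <- matrix(0, N, 2); Y[cbind(seq_len(N), y_idx)] <- 1
  dlogits <- (fw$probs - Y) * (sw / N)
  dWo <- crossprod(fw$hd, dlogits); dbo <- colSums(dlogits)
  dhd <- dlogits %*% t(model$params$Wo)
  if (!is.null(fw$mask2)) dhd <- dhd * fw$mask2
  dzd <- dhd * (fw$zd > 0)
  dWd <- crossprod(fw$flat, dzd); dbd <- colSums(dzd)
  dflat <- dzd %*% t(model$params$Wd)
  if (cf$use_age) dflat <- dflat[, seq_len(model$shapes$flat), drop = FALSE]
  dh <- array(dflat, dim(fw$pl$out))
  if (!is.null(fw$mask1)) dh <- dh * fw$mask1
  da2 <- maxpool_backward(dh, fw$pl)
  dc2 <- da2 * (fw$c2$out > 0)
  g2 <- conv_backward(dc2, fw$c2, model$params$W2)
  dr1 <- g2$dx * (fw$c1$out > 0)
  g1 <- conv_backward(dr1, fw$c1, model$params$W1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wd = dWd, bd = dbd, Wo = dWo, bo = dbo)
}

weighted_ce <- function(probs, y_idx, sw) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)
  mean(sw * -log(p))
}

#' Area under the ROC curve by pairwise concordance
#'
#' The probability that a randomly chosen positive sample scores above a
#' randomly chosen negative one, ties counted one half (the rank-sum form).
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels class labels.
#' @param positive label value treated as positive (default `"LTS"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = "LTS") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  assert_that(n1 > 0 && n0 > 0, "AUC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a pathway-image CNN
#'
#' Minimizes class-weighted cross-entropy with Adam for `config$epochs`
#' epochs and returns the parameter snapshot with the best validation AUC
#' (epoch snapshotting is the only hyperparameter tuning; everything else is
#' fixed by the configuration). Fully seeded: the same seed reproduces the
#' same history bit for bit.
#'
#' @param model an untrained (or trained) `pathcnn_model`.
#' @param x_train,x_val image arrays (`n x rows x cols`) or
#'   `pathway_image_set`s; train and validation must be disjoint. `x_val`
#'   may be `NULL` with `snapshot = "final"` (full-cohort training).
#' @param y_train,y_val factors with levels `LTS`, `non-LTS`.
#' @param age_train,age_val age in years (required when the model uses age).
#' @param class_weights named per-class weights; default
#'   [compute_class_weights()] on `y_train`.
#' @param seed integer; defaults to the model config seed.
#' @param snapshot `"best_val"` (default) keeps the epoch with the best
#'   validation AUC; `"final"` keeps the last epoch (used when training the
#'   interpretation model on the full cohort, where no held-out validation
#'   set exists).
#' @param eval_train if `FALSE`, the per-epoch training-set loss/AUC columns
#'   of the history are skipped (`NA`); validation metrics are always
#'   computed. Saves a full forward pass per epoch in large protocols.
#' @param verbose print per-epoch progress.
#' @return the trained model, with a `history` tibble (per-epoch train and
#'   validation loss and AUC).
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        age_train = NULL, age_val = NULL,
                        class_weights = NULL, seed = NULL,
                        snapshot = c("best_val", "final"), eval_train = TRUE,
                        verbose = FALSE) {
  snapshot <- match.arg(snapshot)
  assert_that(inherits(model, "pathcnn_model"), "model must be a pathcnn_model")
  cf <- model$config
  x_train <- as_image_array(x_train)
  y_train <- factor(y_train, levels = model$classes)
  assert_that(!anyNA(y_train), "labels must be LTS / non-LTS")
  have_val <- !is.null(x_val)
  if (!have_val && snapshot == "best_val")
    abort("snapshot = 'best_val' needs a validation set; use snapshot = 'final'")
  if (have_val) {
    x_val <- as_image_array(x_val)
    y_val <- factor(y_val, levels = model$classes)
    assert_that(!anyNA(y_val), "labels must be LTS / non-LTS")
  }
  if (is.null(class_weights)) class_weights <- compute_class_weights(y_train)
  if (cf$use_age) {
    assert_that(!is.null(age_train) && !is.null(age_val), "model uses age: supply age vectors")
    s <- sd(age_train)
    model$age_stats <- list(mean = mean(age_train), sd = if (s > 0) s else 1)
  }
  y_idx <- as.integer(y_train)
  sw <- as.numeric(class_weights[as.character(y_train)])
  val_ok <- have_val && length(unique(y_val)) == 2
  if (!val_ok && snapshot == "best_val")
    warn("validation set contains a single class; falling back to the final-epoch snapshot")
  use_best <- val_ok && snapshot == "best_val"

  if (is.null(seed)) seed <- cf$seed
  n <- dim(x_train)[1]
  state <- adam_init(model$params)
  best <- list(auc = -Inf, params = model$params)
  hist <- vector("list", cf$epochs)
  with_seed(derive_seed(seed, "train"), {
    for (epoch in seq_len(cf$epochs)) {
      idx <- sample(n)
      for (start in seq(1, n, by = cf$batch_size)) {
        b <- idx[start:min(start + cf$batch_size - 1, n)]
        fw <- nn_forward(model, x_train[b, , , drop = FALSE],
                         age = age_train[b], training = TRUE)
        grads <- nn_backward(model, fw, y_idx[b], sw[b])
        upd <- adam_step(model$params, grads, state, cf$learning_rate)
        model$params <- upd$params; state <- upd$state
      }
      tr <- if (eval_train) nn_forward(model, x_train, age = age_train, training = FALSE)
      vl <- if (have_val) nn_forward(model, x_val, age = age_val, training = FALSE)
      row <- tibble::tibble(
        epoch = epoch,
        train_loss = if (eval_train) weighted_ce(tr$probs, y_idx, sw) else NA_real_,
        train_auc = if (eval_train) auc_score(tr$probs[, 1], y_train) else NA_real_,
        val_loss = if (have_val)
          weighted_ce(vl$probs, as.integer(y_val), rep(1, length(y_val))) else NA_real_,
        val_auc = if (val_ok) auc_score(vl$probs[, 1], y_val) else NA_real_
      )
      hist[[epoch]] <- row
      if (use_best && row$val_auc > best$auc) {
        best$auc <- row$val_auc; best$params <- model$params
      }
      if (verbose)
        message(sprintf("epoch %2d  val loss %.4f  val AUC %.3f",
                        epoch, row$val_loss, row$val_auc))
    }
  })
  if (use_best) model$params <- best$params
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model
}

#' Predict class probabilities from a pathway-image CNN
#' @param object a `pathcnn_model`.
#' @param x images (`n x rows x cols` array or `pathway_image_set`).
#' @param age age vector if the model uses age.
#' @param ... unused.
#' @return matrix of class probabilities (columns `LTS`, `non-LTS`).
#' @export
predict.pathcnn_model <- function(object, x, age = NULL, ...) {
  x <- as_image_array(x)
  fw <- nn_forward(object, x, age = age, training = FALSE)
  colnames(fw$probs) <- object$classes
  rownames(fw$probs) <- dimnames(x)[[1]]
  fw$probs
}

#' Test-set AUC of a trained model
#' @param model a trained `pathcnn_model`.
#' @param x test images.
#' @param y test labels (both classes must be present).
#' @param age test ages if the model uses age.
#' @return AUC (LTS as the positive class).
#' @export
evaluate_auc <- function(model, x, y, age = NULL) {
  y <- factor(y, levels = model$classes)
  assert_that(length(unique(y)) == 2, "test set must contain both classes")
  probs <- predict(model, x, age = age)
  auc_score(probs[, "LTS"], y)
}
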