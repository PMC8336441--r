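# Bilinear interpolation matrix (out x src) with corner alignment; the
# degenerate src = 1 / out = 1 cases replicate / average sensibly.
interp_matrix <- function(src, out, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  R <- matrix(0, out, src)
  pos <- if (out == 1) (1 + src) / 2
         else if (src == 1) rep(1, out)
         else 1 + (seq_len(out) - 1) * (src - 1) / (out - 1)
  for (i in seq_len(out)) {
    p <- pos[i]
    lo <- floor(p); hi <- min(lo + 1, src); lo <- max(lo, 1)
    w <- p - lo
    if (method == "nearest") {
      R[i, if (w < 0.5) lo else hi] <- 1
    } else {
      R[i, lo] <- R[i, lo] + (1 - w)
      if (w > 0) R[i, hi] <- R[i, hi] + w
    }
  }
  R
}

# Batched gradient of the class score w.r.t. the last-conv feature maps.
# Returns A (N,h,w,K) and dA of the same shape. The class score y^c is the
# pre-softmax logit by default; softmax-probability gradients saturate but
# are available via score = "prob".
gradcam_backward <- function(model, x, age = NULL, class_tag,
                             score = c("logit", "prob")) {
  score <- match.arg(score)
  ci <- match(class_tag, model$classes)
  if (is.na(ci))
    abort(sprintf("class '%s' is not a model output (expected %s)",
                  class_tag, paste(model$classes, collapse = ", ")))
  fw <- nn_forward(model, x, age = age, training = FALSE)
  N <- fw$n
  dlogits <- matrix(0, N, 2)
  if (score == "logit") {
    dlogits[, ci] <- 1
  } else {
    # d p_c / d z_j = p_c (1[j=c] - p_j)
    pc <- fw$probs[, ci]
    dlogits <- -fw$probs * pc
    dlogits[, ci] <- dlogits[, ci] + pc
  }
  dhd <- dlogits %*% t(model$params$Wo)
  dzd <- dhd * (fw$zd > 0)
  dflat <- dzd %*% t(model$params$Wd)
  if (model$config$use_age) dflat <- dflat[, seq_len(model$shapes$flat), drop = FALSE]
  dh <- array(dflat, dim(fw$pl$out))
  dA <- maxpool_backward(dh, fw$pl)
  list(A = fw$a2, dA = dA, probs = fw$probs, logits = fw$logits)
}

# Spatial-mean neuron weights for a batch: (N x K) from dA (N,h,w,K).
spatial_mean_weights <- function(dA) {
  d <- dim(dA); N <- d[1]; Z <- d[2] * d[3]; K <- d[4]
  dim(dA) <- c(N, Z, K)
  w <- matrix(0, N, K)
  for (k in seq_len(K)) w[, k] <- rowMeans(dA[, , k, drop = FALSE])
  w
}

#' Grad-CAM neuron importance weights for one sample
#'
#' The weight of feature map `k` for class `c` is the spatial mean of the
#' gradient of the class score with respect to that map,
#' `w_k = (1/Z) * sum_ij d y_c / d A_ij^k`, where `Z` is the number of
#' pixels of a feature map and `y_c` is the pre-softmax logit.
#'
#' @param model a trained `pathcnn_model`.
#' @param image one pathway image (`rows x cols` matrix).
#' @param class_tag `"LTS"` or `"non-LTS"`.
#' @param age age value if the model uses age.
#' @param score `"logit"` (default) or `"prob"` for the class score.
#' @return list with `weights` (length K), `feature_maps` (`h x w x K`) and
#'   `grads` (`h x w x K`).
#' @export
gradcam_weights <- function(model, image, class_tag, age = NULL,
                            score = c("logit", "prob")) {
  x <- array(image, c(1L, dim(image)))
  gb <- gradcam_backward(model, x, age = age, class_tag = class_tag, score = score)
  d <- dim(gb$A)[-1]
  list(weights = as.numeric(spatial_mean_weights(gb$dA)),
       feature_maps = array(gb$A, d), grads = array(gb$dA, d))
}

# Shared map construction: weighted sum of feature maps + ReLU, per-sample
# min-max normalization to [0,1], then up-sampling to out_shape.
build_maps <- function(A, w, out_shape, method = "bilinear") {
  d <- dim(A); N <- d[1]; h <- d[2]; wd <- d[3]; K <- d[4]
  Z <- h * wd
  Ar <- A; dim(Ar) <- c(N, Z, K)
  L <- matrix(0, N, Z)
  for (k in seq_len(K)) L <- L + Ar[, , k] * w[, k]
  L[L < 0] <- 0                               # ReLU
  rng <- apply(L, 1, max) - apply(L, 1, min)
  L <- (L - apply(L, 1, min)) / ifelse(rng > 0, rng, 1)
  L[rng <= 0, ] <- 0                          # constant map -> all zeros
  Rh <- interp_matrix(h, out_shape[1], method)
  Rw <- interp_matrix(wd, out_shape[2], method)
  out <- array(0, c(N, out_shape[1], out_shape[2]))
  for (s in seq_len(N)) {
    m <- matrix(L[s, ], h, wd)
    out[s, , ] <- pmin(pmax(Rh %*% m %*% t(Rw), 0), 1)
  }
  out
}

#' Grad-CAM class activation map for one sample
#'
#' Weighted sum of the last-conv feature maps with the neuron importance
#' weights, clamped by ReLU, min-max normalized to `[0, 1]`, and up-sampled
#' (bilinear with corner alignment by default) to the input image shape.
#'
#' @inheritParams gradcam_weights
#' @param out_shape target shape, normally the input image shape.
#' @param method `"bilinear"` (default) or `"nearest"` up-sampling.
#' @param sample_id optional id recorded in the result.
#' @return a `gradcam_result`: list with `sample_id`, `class_tag`,
#'   `feature_maps`, `neuron_weights`, `raw_map` (h x w, nonnegative) and
#'   `upsampled_map` (values in `[0, 1]`).
#' @export
gradcam_map <- function(model, image, class_tag, out_shape = dim(image),
                        age = NULL, score = c("logit", "prob"),
                        method = c("bilinear", "nearest"), sample_id = NULL) {
  method <- match.arg(method)
  gw <- gradcam_weights(model, image, class_tag, age = age, score = score)
  d <- dim(gw$feature_maps)
  A <- array(gw$feature_maps, c(1L, d))
  w <- matrix(gw$weights, 1L)
  raw <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) raw <- raw + gw$weights[k] * gw$feature_maps[, , k]
  raw[raw < 0] <- 0
  up <- build_maps(A, w, out_shape, method)[1, , ]
  structure(list(sample_id = sample_id, class_tag = class_tag,
                 feature_maps = gw$feature_maps, neuron_weights = gw$weights,
                 raw_map = raw, upsampled_map = up),
            class = "gradcam_result")
}

#' Per-sample class-difference maps
#'
#' Feeds every sample through the (age-free) interpretation model, builds
#' the Grad-CAM activation maps for both classes, and returns
#' `D_i = |L_i^LTS - L_i^non-LTS|` elementwise on the normalized, up-sampled
#' maps, with each sample's true group attached.
#'
#' @param model a trained `pathcnn_model` built without the age input.
#' @param images `pathway_image_set` or `n x rows x cols` array (same data
#'   the model was trained on).
#' @param labels a `label_set` or factor aligned with the images.
#' @param score,method passed to the Grad-CAM computation.
#' @return a `difference_map_set`: list with `maps` (`n x rows x cols`, all
#'   values in `[0, 1]`), `sample_ids`, `group`.
#' @export
difference_maps <- function(model, images, labels,
                            score = c("logit", "prob"),
                            method = c("bilinear", "nearest")) {
  score <- match.arg(score); method <- match.arg(method)
  if (model$config$use_age)
    abort("interpretation model must be trained without the age input")
  sample_ids <- if (inherits(images, "pathway_image_set")) images$sample_ids
                else dimnames(as_image_array(images))[[1]]
  x <- as_image_array(images)
  if (inherits(labels, "label_set")) {
    if (!setequal(sample_ids, labels$sample_id))
      abort(sprintf("sample ids of images and labels differ (e.g. %s)",
                    paste(head(c(setdiff(sample_ids, labels$sample_id),
                                 setdiff(labels$sample_id, sample_ids)), 3), collapse = ", ")))
    group <- labels$label[match(sample_ids, labels$sample_id)]
  } else {
    group <- factor(labels, levels = c("LTS", "non-LTS"))
    assert_that(length(group) == dim(x)[1], "labels must align with image rows")
  }
  out_shape <- dim(x)[2:3]
  maps_by_class <- lapply(model$classes, function(cl) {
    gb <- gradcam_backward(model, x, class_tag = cl, score = score)
    w <- spatial_mean_weights(gb$dA)
    build_maps(gb$A, w, out_shape, method)
  })
  D <- abs(maps_by_class[[1]] - maps_by_class[[2]])
  dimnames(D) <- dimnames(x)
  structure(list(maps = D, sample_ids = sample_ids, group = group),
            class = "difference_map_set")
}

#' @export
print.difference_map_set <- function(x, ...) {
  cat(sprintf("<difference_map_set: %d samples (%d LTS / %d non-LTS), %d x %d maps>\n",
              length(x$sample_ids), sum(x$group == "LTS"), sum(x$group == "non-LTS"),
              dim(x$maps)[2], dim(x$maps)[3]))
  invisible(x)
}
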