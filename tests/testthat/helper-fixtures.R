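# Shared fixtures and independent oracles, all built in code.

# Deterministic image array with sample ids.
make_images_array <- function(n, rows, cols, seed = 1) {
  withr::with_seed(seed, {
    x <- array(rnorm(n * rows * cols), c(n, rows, cols))
  })
  dimnames(x)[[1]] <- sprintf("S%03d", seq_len(n))
  x
}

# Tiny omics matrix from explicit values.
make_omics <- function(values, tag = "EXP",
                       samples = sprintf("S%02d", seq_len(nrow(values))),
                       genes = sprintf("G%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, genes)
  omics_matrix(values, tag)
}

# Toy CNN with a 1x1 feature-map geometry (image 1x1, pool 1x1) whose head
# weights are set by hand, so class scores are analytic linear functions of
# the feature maps: logit_1 = sum_k wo1[k] * (A_k + 10).
make_linear_head_model <- function(wo1, wo2 = rep(0, length(wo1))) {
  K <- 8L
  stopifnot(length(wo1) <= K)
  cfg <- cnn_config(conv_filters = c(4L, K), pool = c(1L, 1L),
                    use_age = FALSE, seed = 42)
  m <- build_cnn(c(1, 1), cfg)
  m$params$Wd <- diag(1, K, cfg$dense_units)
  m$params$bd <- rep(10, cfg$dense_units)   # keeps the dense ReLU active
  m$params$Wo <- matrix(0, cfg$dense_units, 2)
  m$params$Wo[seq_along(wo1), 1] <- wo1
  m$params$Wo[seq_along(wo2), 2] <- wo2
  m$trained <- TRUE
  m
}

# Small fixed-weight model on a larger map, for gradient and map-range
# property checks. Positive conv biases keep the feature maps strictly
# positive, so the max-pooling has no tied (non-differentiable) windows and
# finite differences are well-defined.
make_toy_model <- function(rows = 8, cols = 6, seed = 7) {
  cfg <- cnn_config(conv_filters = c(4L, 6L), use_age = FALSE, seed = seed)
  m <- build_cnn(c(rows, cols), cfg)
  m$params$b1[] <- 0.5
  m$params$b2[] <- 1
  m
}

# Independent central-finite-difference oracle for the Grad-CAM neuron
# weights: perturbs the last-conv feature maps directly and re-runs the
# network head (pool -> flatten -> dense -> logits) written out from the
# model parameters, independent of the package's backward pass.
head_logit_from_A <- function(model, A, class_index) {
  pl <- pathcnn:::maxpool_forward(array(A, c(1L, dim(A))), model$config$pool)
  flat <- pl$out
  dim(flat) <- c(1L, model$shapes$flat)
  zd <- flat %*% model$params$Wd + model$params$bd
  hd <- pmax(zd, 0)
  logits <- hd %*% model$params$Wo + model$params$bo
  logits[1, class_index]
}

fd_gradcam_weights <- function(model, image, class_tag, eps = 1e-5) {
  ci <- match(class_tag, model$classes)
  fw <- pathcnn:::nn_forward(model, array(image, c(1L, dim(image))), training = FALSE)
  A <- array(fw$a2, dim(fw$a2)[-1])
  d <- dim(A); Z <- d[1] * d[2]
  w <- numeric(d[3])
  for (k in seq_len(d[3])) {
    g <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      Ap <- A; Am <- A
      Ap[i, j, k] <- Ap[i, j, k] + eps
      Am[i, j, k] <- Am[i, j, k] - eps
      g <- g + (head_logit_from_A(model, Ap, ci) -
                  head_logit_from_A(model, Am, ci)) / (2 * eps)
    }
    w[k] <- g / Z
  }
  w
}

# Brute-force re-implementation of the greedy correlation ordering rule,
# written independently for oracle comparison.
brute_force_order <- function(M) {
  P <- nrow(M)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[pairs]
  best <- pairs[order(-vals, pairs[, 1], pairs[, 2])[1], ]
  sel <- c(best[1], best[2])
  while (length(sel) < P) {
    rem <- setdiff(seq_len(P), sel)
    last <- sel[length(sel)]
    sel <- c(sel, rem[which.max(M[last, rem])])
  }
  sel
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
enumerate_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  stats_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# Random symmetric correlation-like matrix with unit diagonal.
random_corr <- function(P, seed) {
  withr::with_seed(seed, {
    M <- matrix(runif(P * P, -1, 1), P)
  })
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}

as_pathway_corr <- function(M, names = sprintf("PW%02d", seq_len(nrow(M)))) {
  dimnames(M) <- list(names, names)
  structure(list(pathway_names = names, matrix = M), class = "pathway_correlation")
}

# Manually assembled difference-map set.
make_diff_set <- function(maps, group) {
  n <- dim(maps)[1]
  structure(list(maps = maps, sample_ids = sprintf("S%03d", seq_len(n)),
                 group = factor(group, levels = c("LTS", "non-LTS"))),
            class = "difference_map_set")
}

signal_4 <- tibble::tibble(pathway = c(5L, 12L, 23L, 34L),
                           omics = c("EXP", "EXP", "CNV", "CNV"))

# A small trained model + normalized images + labels, cached per session.
small_images_with_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- generate_cohort(synthetic_config(
      n_samples = 60, n_pathways = 8, genes_per_pathway = 6,
      signal_pathways = tibble::tibble(pathway = c(1L, 2L), omics = c("EXP", "CNV")),
      effect_size = 2, seed = 33))
    ls <- assign_labels(co$clinical)
    im <- build_pathway_images(co$omics, co$gene_sets, q = 2,
                               sample_ids = ls$sample_id)
    imn <- normalize_images(im)$images
    cfg <- cnn_config(use_age = FALSE, epochs = 6, batch_size = 16, seed = 2)
    m <- train_model(build_cnn(dim(imn$images)[2:3], cfg), imn$images, ls$label,
                     snapshot = "final", eval_train = FALSE)
    diffs <- difference_maps(m, imn, ls)
    cache <<- list(cohort = co, labels = ls, images = imn, model = m, diffs = diffs)
    cache
  }
})
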