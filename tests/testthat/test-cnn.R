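# Naive direct convolution, written independently of the im2col path.
naive_conv <- function(x, Wm, b, padding) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (padding == "same") {
    xp <- array(0, c(N, H + 2, W + 2, C)); xp[, 2:(H + 1), 2:(W + 1), ] <- x
    Ho <- H; Wo <- W
  } else { xp <- x; Ho <- H - 2; Wo <- W - 2 }
  Cout <- ncol(Wm)
  out <- array(0, c(N, Ho, Wo, Cout))
  for (n in 1:N) for (i in 1:Ho) for (j in 1:Wo) for (co in 1:Cout) {
    acc <- b[co]
    for (di in 0:2) for (dj in 0:2) for (cc in 1:C)
      acc <- acc + xp[n, i + di, j + dj, cc] * Wm[(di * 3 + dj) * C + cc, co]
    out[n, i, j, co] <- acc
  }
  out
}

test_that("im2col convolution agrees with direct convolution", {
  set.seed(8)
  x <- array(rnorm(2 * 5 * 4 * 2), c(2, 5, 4, 2))
  Wm <- matrix(rnorm(9 * 2 * 3), 9 * 2, 3)
  b <- rnorm(3)
  for (pad in c("same", "valid")) {
    got <- pathcnn:::conv_forward(x, Wm, b, pad)$out
    expect_equal(got, naive_conv(x, Wm, b, pad), tolerance = 1e-12)
  }
})

test_that("max pooling tracks maxima and routes gradients to the argmax", {
  set.seed(2)
  x <- array(rnorm(3 * 9 * 5 * 2), c(3, 9, 5, 2))   # 9x5 not divisible by 4x2
  fw <- pathcnn:::maxpool_forward(x, c(4L, 2L))
  expect_equal(dim(fw$out), c(3L, 2L, 2L, 2L))
  # each pooled value is the max of its window
  for (n in 1:3) for (i in 1:2) for (j in 1:2) for (c in 1:2)
    expect_equal(fw$out[n, i, j, c],
                 max(x[n, (4 * i - 3):(4 * i), (2 * j - 1):(2 * j), c]))
  dout <- array(1, dim(fw$out))
  dx <- pathcnn:::maxpool_backward(dout, fw)
  expect_equal(sum(dx), prod(dim(dout)))          # one unit per window
  expect_true(all(dx[, 9, , ] == 0))              # dropped remainder row
})

test_that("layer geometry matches the stated architecture arithmetic", {
  m <- build_cnn(c(146, 6), cnn_config(padding = "same"))
  expect_equal(m$shapes$conv, c(146L, 6L))
  expect_equal(m$shapes$pool, c(36L, 3L))
  expect_equal(m$shapes$flat, 36L * 3L * 64L)
  mv <- build_cnn(c(146, 6), cnn_config(padding = "valid"))
  expect_equal(mv$shapes$conv, c(142L, 2L))
  expect_equal(mv$shapes$pool, c(35L, 1L))
  # without age the dense input is exactly the flattened pooled size
  m2 <- build_cnn(c(40, 6), cnn_config(use_age = FALSE))
  expect_equal(m2$shapes$dense_in, m2$shapes$flat)
  m3 <- build_cnn(c(40, 6), cnn_config(use_age = TRUE))
  expect_equal(m3$shapes$dense_in, m3$shapes$flat + 1L)
  expect_error(build_cnn(c(3, 2), cnn_config()), "minimal shape")
})

test_that("AUC equals the concordance probability with tie handling", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), positive = 1), 0.75)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), positive = 1), 1)
  expect_equal(auc_score(rep(0.5, 6), rep(c(1, 0), 3), positive = 1), 0.5)
  # invariant under strictly increasing transforms
  set.seed(1)
  s <- rnorm(40); y <- rbinom(40, 1, 0.4)
  expect_equal(auc_score(s, y, positive = 1), auc_score(exp(3 * s), y, positive = 1))
  # independent cross-check
  skip_if_not_installed("pROC")
  expect_equal(auc_score(s, y, positive = 1),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

make_shifted_images <- function(n, rows = 20, cols = 6, shift = 1.5, seed = 1) {
  withr::with_seed(seed, {
    x <- array(rnorm(n * rows * cols), c(n, rows, cols))
    y <- factor(rep(c("LTS", "non-LTS"), length.out = n), levels = c("LTS", "non-LTS"))
    x[y == "LTS", 3:8, 1:3] <- x[y == "LTS", 3:8, 1:3] + shift
    list(x = x, y = y)
  })
}

test_that("training separates a strongly shifted cohort", {
  d <- make_shifted_images(200, shift = 1.5, seed = 3)
  cfg <- cnn_config(use_age = FALSE, epochs = 30, seed = 4)
  m <- train_model(build_cnn(dim(d$x)[2:3], cfg), d$x, d$y, snapshot = "final")
  expect_gt(tail(m$history$train_auc, 1), 0.95)
})

test_that("randomly permuted labels stay near chance on held-out data", {
  d <- make_shifted_images(120, shift = 1.5, seed = 5)
  y_perm <- withr::with_seed(6, sample(d$y))
  cfg <- cnn_config(use_age = FALSE, epochs = 10, seed = 7)
  m <- train_model(build_cnn(dim(d$x)[2:3], cfg),
                   d$x[1:80, , ], y_perm[1:80], d$x[81:120, , ], y_perm[81:120])
  auc <- evaluate_auc(m, d$x[81:120, , ], y_perm[81:120])
  expect_gte(auc, 0.3); expect_lte(auc, 0.7)
})

test_that("training is exactly reproducible under a fixed seed", {
  d <- make_shifted_images(60, shift = 1, seed = 8)
  cfg <- cnn_config(use_age = FALSE, epochs = 2, batch_size = 16, seed = 9)
  run <- function() train_model(build_cnn(dim(d$x)[2:3], cfg),
                                d$x[1:40, , ], d$y[1:40],
                                d$x[41:60, , ], d$y[41:60])
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("single-class validation sets fall back with a warning", {
  d <- make_shifted_images(40, seed = 10)
  cfg <- cnn_config(use_age = FALSE, epochs = 1, seed = 11)
  keep <- d$y == "LTS"
  expect_warning(
    train_model(build_cnn(dim(d$x)[2:3], cfg), d$x[1:30, , ], d$y[1:30],
                d$x[keep, , ][1:4, , ], d$y[keep][1:4]),
    "single class")
})

test_that("the age covariate enters the dense layer and affects predictions", {
  d <- make_shifted_images(50, shift = 0, seed = 12)
  age <- withr::with_seed(13, rnorm(50, 60, 8))
  cfg <- cnn_config(use_age = TRUE, epochs = 2, seed = 14)
  m <- train_model(build_cnn(dim(d$x)[2:3], cfg), d$x[1:40, , ], d$y[1:40],
                   d$x[41:50, , ], d$y[41:50],
                   age_train = age[1:40], age_val = age[41:50])
  p1 <- predict(m, d$x[41:50, , ], age = age[41:50])
  p2 <- predict(m, d$x[41:50, , ], age = age[41:50] + 20)
  expect_false(isTRUE(all.equal(p1, p2)))
  expect_error(predict(m, d$x[41:50, , ]), "age")
})

test_that("class weighting does not hurt minority-class recall under imbalance", {
  rec <- function(weighted, seed) {
    n <- 120
    withr::with_seed(seed, {
      x <- array(rnorm(n * 12 * 6), c(n, 12, 6))
      y <- factor(rep(c("LTS", "non-LTS"), c(24, 96)), levels = c("LTS", "non-LTS"))
      x[y == "LTS", 3:6, 1:2] <- x[y == "LTS", 3:6, 1:2] + 0.8
      idx <- sample(n)
    })
    x <- x[idx, , ]; y <- y[idx]
    tr <- 1:80; te <- 81:120
    cfg <- cnn_config(use_age = FALSE, epochs = 10, batch_size = 32, seed = seed)
    cw <- if (weighted) NULL else c(LTS = 1, `non-LTS` = 1)
    m <- train_model(build_cnn(c(12, 6), cfg), x[tr, , ], y[tr],
                     class_weights = cw, snapshot = "final")
    pr <- predict(m, x[te, , ])
    pred <- ifelse(pr[, "LTS"] > 0.5, "LTS", "non-LTS")
    sum(pred == "LTS" & y[te] == "LTS") / sum(y[te] == "LTS")
  }
  seeds <- c(101, 202, 303)
  r_w <- mean(vapply(seeds, function(s) rec(TRUE, s), numeric(1)))
  r_u <- mean(vapply(seeds, function(s) rec(FALSE, s), numeric(1)))
  expect_gte(r_w, r_u)
})
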