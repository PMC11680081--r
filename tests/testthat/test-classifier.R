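fake_clips <- function(n_bark, n_howl) {
  mk <- function(lbl) labeled_clip(audio_signal(0.1, 8000), lbl)
  c(replicate(n_bark, mk("bark"), simplify = FALSE),
    replicate(n_howl, mk("howl"), simplify = FALSE))
}

# Two-class images that are trivially separable: class A is bright in the
# top-left quadrant, class B in the bottom-right.
quadrant_image <- function(class, seed) {
  set.seed(seed)
  img <- base::matrix(runif(256 * 256, 0, 0.1), 256, 256)
  if (class == "bark") img[1:128, 1:128] <- img[1:128, 1:128] + 0.8
  else img[129:256, 129:256] <- img[129:256, 129:256] + 0.8
  structure(pmin(img, 1), source_kind = "mel_db",
            class = c("feature_image", "matrix"))
}

test_that("dataset splitting is deterministic, exhaustive and sized right", {
  clips <- fake_clips(46, 57)
  cfg <- train_config(seed = 4L)
  sp <- split_dataset(clips, cfg)
  expect_identical(length(sp$train), 82L)
  expect_identical(length(sp$test), 21L)
  expect_identical(sort(c(sp$train, sp$test)), 1:103)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_dataset(clips, cfg), sp)
  expect_false(identical(split_dataset(clips, train_config(seed = 5L)), sp))

  # stratified mode keeps per-class proportions
  sps <- split_dataset(clips, train_config(seed = 4L, stratify = TRUE))
  labels <- vapply(clips, `[[`, character(1), "label")
  expect_equal(sum(labels[sps$train] == "bark"), floor(46 * 0.8))
  expect_error(split_dataset(fake_clips(1, 5), cfg), "at least 2")
})

test_that("the compact CNN is seeded, shape-strict and produces a simplex", {
  m1 <- build_compact_cnn(seed = 3L)
  m2 <- build_compact_cnn(seed = 3L)
  img <- quadrant_image("bark", 1)
  p1 <- predict(m1, img)
  p2 <- predict(m2, img)
  expect_identical(p1$probabilities, p2$probabilities)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-9)
  expect_identical(p1$confidence, max(p1$probabilities))
  expect_false(identical(
    predict(build_compact_cnn(seed = 9L), img)$probabilities,
    p1$probabilities))

  bad <- structure(base::matrix(0, 64, 64), source_kind = "mel_db",
                   class = c("feature_image", "matrix"))
  expect_error(predict(m1, bad), "256")
})

test_that("conv/pool layers pass a finite-difference gradient check", {
  ns <- asNamespace("canivox")
  set.seed(1)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  W <- base::matrix(rnorm(3 * 18, sd = 0.5), 3, 18)
  b <- rnorm(3)
  loss <- function(W, b, x) {
    y <- ns$cnn_conv2d_forward(x, W, b, 3L)
    r <- y * (y > 0)
    sum(ns$cnn_maxpool2_forward(r)$y^2)
  }
  y <- ns$cnn_conv2d_forward(x, W, b, 3L)
  r <- y * (y > 0)
  p <- ns$cnn_maxpool2_forward(r)
  dr <- ns$cnn_maxpool2_backward(p$idx, 2 * p$y, 8L, 8L)
  bw <- ns$cnn_conv2d_backward(x, W, dr * (y > 0), 3L)

  eps <- 1e-6
  num <- function(get, set, n) {
    vapply(seq_len(n), function(i) {
      up <- set(i, eps); dn <- set(i, -eps)
      (loss(up$W, up$b, up$x) - loss(dn$W, dn$b, dn$x)) / (2 * eps)
    }, numeric(1))
  }
  dW_num <- num(NULL, function(i, e) { W2 <- W; W2[i] <- W2[i] + e
                                       list(W = W2, b = b, x = x) },
                length(W))
  expect_lt(max(abs(dW_num - as.numeric(bw$dw))) / max(abs(dW_num)), 1e-6)
  dx_num <- num(NULL, function(i, e) { x2 <- x; x2[i] <- x2[i] + e
                                       list(W = W, b = b, x = x2) },
                length(x))
  expect_lt(max(abs(dx_num - as.numeric(bw$dx))) / max(abs(dx_num)), 1e-6)
  db_num <- num(NULL, function(i, e) { b2 <- b; b2[i] <- b2[i] + e
                                       list(W = W, b = b2, x = x) },
                length(b))
  expect_lt(max(abs(db_num - as.numeric(bw$db))) / max(abs(db_num)), 1e-6)
})

test_that("training separates disjoint bright-quadrant classes quickly", {
  labels <- rep(c("bark", "howl"), each = 8)
  images <- lapply(seq_along(labels), function(i)
    quadrant_image(labels[i], 100 + i))
  clips <- lapply(labels, function(l) labeled_clip(audio_signal(0.1, 8000), l))
  cfg <- train_config("mel_db", epochs = 50L, batch_size = 8L, seed = 1L,
                      early_stop_train_acc = 1.0)
  model <- train_model(build_compact_cnn(seed = 1L), clips, cfg,
                       images = images)
  expect_true(all(is.finite(model$history$train_loss)))
  expect_equal(max(model$history$train_accuracy), 1.0)
  expect_lte(nrow(model$history), 50L)

  # inference is deterministic
  pr1 <- predict(model, images[[1]])
  pr2 <- predict(model, images[[1]])
  expect_identical(pr1$probabilities, pr2$probabilities)
})

test_that("a single-class training set yields single-class predictions", {
  labels <- rep("howl", 6)
  images <- lapply(1:6, function(i) quadrant_image("howl", 200 + i))
  clips <- lapply(labels, function(l) labeled_clip(audio_signal(0.1, 8000), l))
  cfg <- train_config("mel_db", epochs = 12L, batch_size = 6L, seed = 2L)
  model <- train_model(build_compact_cnn(seed = 2L), clips, cfg,
                       images = images)
  probe <- list(quadrant_image("bark", 300), quadrant_image("howl", 301))
  for (img in probe)
    expect_identical(predict(model, img)$predicted_label, "howl")
})

test_that("model artifacts round-trip and guard against misuse", {
  model <- build_compact_cnn(feature_kind = "mfcc", seed = 6L)
  img <- quadrant_image("bark", 7)
  attr(img, "source_kind") <- "mfcc"
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(model, p)
  loaded <- load_model(p)
  expect_identical(predict(loaded, img)$probabilities,
                   predict(model, img)$probabilities)

  wrong <- quadrant_image("bark", 7)  # source_kind mel_db
  expect_error(predict(loaded, wrong), "mismatch")

  writeLines("garbage", p)
  expect_error(load_model(p), "cannot read|not a canivox")
  p2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), p2)
  expect_error(load_model(p2), "not a canivox")
  m2 <- model; m2$format_version <- 99L
  saveRDS(m2, p2)
  expect_error(load_model(p2), "version")
})

test_that("classical baselines honor the prediction contract", {
  corpus <- synth_corpus(8, 8, seed = 21)
  cfg <- train_config("mfcc", seed = 21L)

  # 1-NN memorizes its training set
  knn1 <- fit_baseline(corpus, "mfcc", "nearest_neighbor", cfg, k = 1L)
  train_preds <- vapply(corpus, function(cl)
    predict(knn1, featurize_clip(cl$clip, "mfcc"))$predicted_label,
    character(1))
  expect_identical(train_preds, vapply(corpus, `[[`, character(1), "label"))

  for (fam in c("margin", "nearest_neighbor", "tree_ensemble",
                "probabilistic")) {
    m <- fit_baseline(corpus, "mfcc", fam, cfg)
    pr <- predict(m, featurize_clip(corpus[[1]]$clip, "mfcc"))
    expect_true(all(pr$probabilities >= 0))
    expect_equal(sum(pr$probabilities), 1, tolerance = 1e-6)
    expect_identical(names(pr$probabilities), c("bark", "howl"))
    expect_identical(pr$predicted_label,
                     names(which.max(pr$probabilities)))
  }
  expect_error(fit_baseline(corpus, "mfcc", "boosted"), "arg")
})
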