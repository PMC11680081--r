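CLASS_ORDER <- c("bark", "howl")
MODEL_FORMAT_VERSION <- 1L

#' Construct a labeled clip
#'
#' @param clip An [audio_signal].
#' @param label Class label, one of `"bark"`, `"howl"`.
#' @return A `labeled_clip` list.
#' @export
labeled_clip <- function(clip, label) {
  stopifnot(inherits(clip, "audio_signal"))
  label <- as.character(label)
  if (!label %in% CLASS_ORDER)
    stop("label must be one of: ", paste(CLASS_ORDER, collapse = ", "))
  structure(list(clip = clip, label = label), class = "labeled_clip")
}

#' Training configuration
#'
#' Defaults mirror the experiment design the package reproduces: 80/20
#' train/test split with a fixed random state, batch size 32. The epoch
#' default of 700 matches that design; desk-scale runs typically pass a
#' much smaller `epochs` together with early stopping.
#'
#' @param feature_kind Feature fed to the classifier: `"mel_db"`,
#'   `"mfcc"` or `"lfcc"`.
#' @param train_fraction Fraction of clips used for training, in (0, 1).
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Number of training epochs.
#' @param seed Integer seed controlling the split, parameter
#'   initialization, shuffling and dropout.
#' @param learning_rate Adam step size.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping, or `NULL` to disable early stopping.
#' @param val_fraction Fraction of the training set held out as validation
#'   when early stopping is enabled.
#' @param early_stop_train_acc Stop once training accuracy reaches this
#'   value (e.g. `1.0`), or `NULL` to disable.
#' @param stratify Use a per-class (stratified) split instead of a uniform
#'   unstratified shuffle.
#' @return A `train_config` list.
#' @export
train_config <- function(feature_kind = c("mel_db", "mfcc", "lfcc"),
                         train_fraction = 0.8, batch_size = 32L,
                         epochs = 700L, seed = 0L, learning_rate = 1e-3,
                         early_stop_patience = NULL, val_fraction = 0.15,
                         early_stop_train_acc = NULL, stratify = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  structure(list(feature_kind = feature_kind,
                 train_fraction = train_fraction,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 learning_rate = learning_rate,
                 early_stop_patience = early_stop_patience,
                 val_fraction = val_fraction,
                 early_stop_train_acc = early_stop_train_acc,
                 stratify = isTRUE(stratify)),
            class = "train_config")
}

#' Split labeled clips into train and test sets
#'
#' Deterministic given `config$seed`; the test set holds
#' `n - floor(n * train_fraction)` clips. The default split is an
#' unstratified uniform shuffle; set `stratify = TRUE` in the config for a
#' per-class split.
#'
#' @param clips List of [labeled_clip] objects, at least 2 per class.
#' @param config A [train_config].
#' @return List with integer index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @export
split_dataset <- function(clips, config = train_config()) {
  labels <- vapply(clips, function(cl) cl$label, character(1))
  tab <- table(factor(labels, levels = CLASS_ORDER))
  if (any(tab < 2L))
    stop("need at least 2 clips per class; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  n <- length(clips)
  with_seed(config$seed, {
    if (config$stratify) {
      train <- integer(0)
      for (cl in CLASS_ORDER) {
        idx <- sample(which(labels == cl))
        train <- c(train, idx[seq_len(floor(length(idx) *
                                              config$train_fraction))])
      }
      train <- sort(train)
    } else {
      perm <- sample(n)
      train <- sort(perm[seq_len(floor(n * config$train_fraction))])
    }
  })
  list(train = train, test = sort(setdiff(seq_len(n), train)))
}

#' Extract a feature matrix from one clip
#'
#' Resamples the clip to the configured rate if needed, then computes the
#' requested feature.
#'
#' @param clip An [audio_signal].
#' @param feature_kind `"mel_db"`, `"mfcc"` or `"lfcc"`.
#' @param config An [stft_config].
#' @return A `feature_matrix`.
#' @export
featurize_clip <- function(clip, feature_kind = c("mel_db", "mfcc", "lfcc"),
                           config = stft_config()) {
  feature_kind <- match.arg(feature_kind)
  if (clip$sample_rate != config$sample_rate)
    clip <- resample_signal(clip, config$sample_rate)
  switch(feature_kind,
         mel_db = mel_spectrogram(clip, config),
         mfcc = mfcc(clip, config),
         lfcc = lfcc(clip, config))
}

# Pool a 2-D feature matrix to a fixed-length vector (per-row mean and
# standard deviation) for the classical baselines.
pooled_features <- function(fm) {
  m <- unclass(fm)
  c(rowMeans(m), apply(m, 1L, sd))
}

featurize_images <- function(clips, feature_kind, config = stft_config()) {
  lapply(clips, function(cl)
    to_image(featurize_clip(cl$clip, feature_kind, config)))
}

new_model <- function(architecture, feature_kind, fit, class_order,
                      history = NULL, extra = list()) {
  structure(c(list(architecture = architecture, feature_kind = feature_kind,
                   fit = fit, class_order = class_order, history = history,
                   format_version = MODEL_FORMAT_VERSION),
              extra),
            class = "canivox_model")
}

#' @export
print.canivox_model <- function(x, ...) {
  cat(sprintf("<canivox_model %s on %s> classes: %s%s\n", x$architecture,
              x$feature_kind, paste(x$class_order, collapse = ", "),
              if (is.null(x$history)) " (untrained)" else
                sprintf(" (%d epochs trained)", nrow(x$history))))
  invisible(x)
}

#' Build the compact CNN (untrained)
#'
#' Architecture: a fixed 4x4 average-pooling stem on the 256x256 input,
#' four convolution blocks (3x3 kernels, 'same' padding, ReLU, 2x2 max
#' pooling; 16/32/64/128 channels), global average pooling, a 128-unit
#' dense layer with dropout 0.5, and a softmax output. Parameter
#' initialization is deterministic given `seed`.
#'
#' @param n_classes Number of output classes (default 2).
#' @param feature_kind Feature the model will consume.
#' @param seed Integer seed for parameter initialization.
#' @return An untrained `canivox_model`.
#' @export
build_compact_cnn <- function(n_classes = 2L,
                              feature_kind = c("mel_db", "mfcc", "lfcc"),
                              seed = 0L) {
  feature_kind <- match.arg(feature_kind)
  params <- init_cnn_params(n_classes, seed)
  new_model("compact_cnn", feature_kind, list(params = params),
            CLASS_ORDER[seq_len(n_classes)])
}

#' Train the compact CNN on labeled clips
#'
#' Minimizes categorical cross-entropy with the Adam optimizer on
#' minibatches; records per-epoch loss and accuracy (and validation
#' metrics when early stopping is enabled). Deterministic given the
#' config seed.
#'
#' @param model An untrained `canivox_model` from [build_compact_cnn()].
#' @param clips List of [labeled_clip] objects (the training material;
#'   split off a test set with [split_dataset()] first).
#' @param config A [train_config]; `feature_kind` must match the model.
#' @param images Optional precomputed list of `feature_image`s matching
#'   `clips` (skips feature extraction).
#' @return The trained `canivox_model` with a `history` data.frame.
#' @export
train_model <- function(model, clips, config, images = NULL) {
  stopifnot(inherits(model, "canivox_model"),
            model$architecture == "compact_cnn")
  if (length(clips) == 0L) stop("empty training set")
  if (config$feature_kind != model$feature_kind)
    stop("config feature_kind (", config$feature_kind,
         ") does not match the model (", model$feature_kind, ")")
  labels <- vapply(clips, function(cl) cl$label, character(1))
  y <- match(labels, model$class_order)
  if (anyNA(y)) stop("clip label outside the model's class set")
  if (is.null(images)) images <- featurize_images(clips, config$feature_kind)

  n <- length(images)
  val_idx <- integer(0)
  if (!is.null(config$early_stop_patience)) {
    val_idx <- with_seed(config$seed + 1L,
                         sort(sample(n, max(1L, round(n * config$val_fraction)))))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  params <- model$fit$params
  state <- adam_init(params)
  n_classes <- length(model$class_order)
  onehot <- diag(n_classes)
  hist <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L

  with_seed(config$seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- tr_idx[sample(length(tr_idx))]
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, length(order_idx), by = config$batch_size)) {
        batch <- order_idx[start:min(start + config$batch_size - 1L,
                                     length(order_idx))]
        acc_grad <- NULL
        for (i in batch) {
          mask <- (runif(CNN_HIDDEN) >= CNN_DROPOUT) / (1 - CNN_DROPOUT)
          fwd <- cnn_forward(params, images[[i]], dropout_mask = mask)
          p_true <- max(fwd$probs[y[i]], 1e-12)
          ep_loss <- ep_loss - log(p_true)
          if (which.max(fwd$probs) == y[i]) ep_correct <- ep_correct + 1L
          acc_grad <- grad_add(acc_grad, cnn_backward(params, fwd,
                                                      onehot[, y[i]]))
        }
        upd <- adam_step(params, grad_scale(acc_grad, 1 / length(batch)),
                         state, config$learning_rate)
        params <- upd$params; state <- upd$state
      }
      train_loss <- ep_loss / length(order_idx)
      train_acc <- ep_correct / length(order_idx)

      val_loss <- NA_real_; val_acc <- NA_real_
      if (length(val_idx)) {
        vl <- 0; vc <- 0L
        for (i in val_idx) {
          fwd <- cnn_forward(params, images[[i]])
          vl <- vl - log(max(fwd$probs[y[i]], 1e-12))
          if (which.max(fwd$probs) == y[i]) vc <- vc + 1L
        }
        val_loss <- vl / length(val_idx); val_acc <- vc / length(val_idx)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  train_accuracy = train_acc,
                                  val_loss = val_loss, val_accuracy = val_acc)

      if (length(val_idx)) {
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= config$early_stop_patience) break
        }
      }
      if (!is.null(config$early_stop_train_acc) &&
          train_acc >= config$early_stop_train_acc) break
    }
  })

  if (length(val_idx) && is.finite(best$loss)) params <- best$params
  model$fit$params <- params
  model$history <- do.call(rbind, hist)
  model$train_config <- config
  model
}

#' Classify a feature image (or pooled features) with a trained model
#'
#' Inference is deterministic (dropout disabled). The predicted label is
#' the argmax class; ties break toward the earlier class in the model's
#' class order.
#'
#' @param object A trained `canivox_model`.
#' @param image A `feature_image` whose `source_kind` matches the model's
#'   `feature_kind` (for the CNN), or a `feature_matrix` (baselines accept
#'   either and pool internally).
#' @param ... Unused.
#' @return A `canivox_prediction`: list with `probabilities` (named,
#'   summing to 1), `predicted_label`, `confidence`.
#' @export
predict.canivox_model <- function(object, image, ...) {
  kind <- attr(image, "source_kind") %||% attr(image, "kind")
  if (!is.null(kind) && kind != "unknown" && kind != object$feature_kind)
    stop("feature kind mismatch: model expects ", object$feature_kind,
         ", image is ", kind)
  probs <- switch(object$architecture,
    compact_cnn = {
      if (!inherits(image, "feature_image"))
        stop("the compact CNN expects a feature_image")
      drop(cnn_forward(object$fit$params, image)$probs)
    },
    baseline_predict(object, image))
  names(probs) <- object$class_order
  pred <- object$class_order[which.max(probs)]
  structure(list(probabilities = probs, predicted_label = pred,
                 confidence = max(probs)),
            class = "canivox_prediction")
}

#' @export
print.canivox_prediction <- function(x, ...) {
  cat(sprintf("<prediction> %s (confidence %.3f)\n", x$predicted_label,
              x$confidence))
  invisible(x)
}

baseline_vector <- function(object, image) {
  if (inherits(image, "feature_image"))
    stop("baseline models consume feature matrices (pooled internally), ",
         "not resized feature images")
  v <- if (inherits(image, "feature_matrix")) pooled_features(image)
       else as.numeric(image)
  v <- v[object$fit$keep]
  (v - object$fit$center) / object$fit$scale
}

baseline_predict <- function(object, image) {
  v <- baseline_vector(object, image)
  x <- matrix(v, nrow = 1)
  fit <- object$fit
  switch(object$architecture,
    baseline_margin = {
      colnames(x) <- fit$feature_names
      pr <- attr(predict(fit$model, x, probability = TRUE), "probabilities")
      as.numeric(pr[1, object$class_order])
    },
    baseline_nearest_neighbor = {
      pred <- class::knn(fit$train_x, x, fit$train_y, k = fit$k, prob = TRUE)
      p_win <- attr(pred, "prob")
      probs <- rep((1 - p_win) / (length(object$class_order) - 1),
                   length(object$class_order))
      probs[match(as.character(pred), object$class_order)] <- p_win
      probs
    },
    baseline_tree_ensemble = {
      colnames(x) <- fit$feature_names
      pr <- predict(fit$model, data = as.data.frame(x))$predictions
      as.numeric(pr[1, object$class_order])
    },
    baseline_probabilistic = {
      colnames(x) <- fit$feature_names
      pr <- predict(fit$model, as.data.frame(x), type = "raw")
      as.numeric(pr[1, object$class_order])
    },
    stop("unknown architecture: ", object$architecture))
}

#' Fit a classical baseline classifier on pooled features
#'
#' Feature matrices are pooled to fixed-length vectors (per-row mean and
#' standard deviation), standardized by training statistics, and fitted
#' with the chosen family: `margin` (RBF support vector machine),
#' `nearest_neighbor` (k-NN), `tree_ensemble` (random forest) or
#' `probabilistic` (Gaussian naive Bayes). The fitted model honors the
#' same prediction and metrics contract as the CNN.
#'
#' @param clips List of [labeled_clip] objects (the training set).
#' @param feature_kind `"mel_db"`, `"mfcc"` or `"lfcc"`.
#' @param family One of `"margin"`, `"nearest_neighbor"`,
#'   `"tree_ensemble"`, `"probabilistic"`.
#' @param config A [train_config] (supplies the seed).
#' @param k Neighbor count for the `nearest_neighbor` family (default 5).
#' @param stft STFT configuration used for feature extraction.
#' @return A trained `canivox_model`.
#' @export
fit_baseline <- function(clips, feature_kind = c("mel_db", "mfcc", "lfcc"),
                         family = c("margin", "nearest_neighbor",
                                    "tree_ensemble", "probabilistic"),
                         config = train_config(), k = 5L,
                         stft = stft_config()) {
  feature_kind <- match.arg(feature_kind)
  family <- match.arg(family)
  if (length(clips) == 0L) stop("empty training set")
  labels <- factor(vapply(clips, function(cl) cl$label, character(1)),
                   levels = CLASS_ORDER)
  feats <- do.call(rbind, lapply(clips, function(cl)
    pooled_features(featurize_clip(cl$clip, feature_kind, stft))))

  keep <- which(apply(feats, 2L, sd) > 1e-10)
  feats <- feats[, keep, drop = FALSE]
  center <- colMeans(feats)
  scale <- apply(feats, 2L, sd)
  xs <- sweep(sweep(feats, 2L, center), 2L, scale, "/")
  feature_names <- paste0("f", seq_along(keep))
  colnames(xs) <- feature_names

  fit <- with_seed(config$seed, switch(family,
    margin = list(model = e1071::svm(xs, labels, probability = TRUE,
                                     kernel = "radial")),
    nearest_neighbor = list(train_x = xs, train_y = labels, k = as.integer(k)),
    tree_ensemble = {
      df <- as.data.frame(xs); df$label <- labels
      list(model = ranger::ranger(label ~ ., data = df, probability = TRUE,
                                  num.trees = 500L, seed = config$seed),
           feature_names = feature_names)
    },
    probabilistic = {
      df <- as.data.frame(xs)
      list(model = e1071::naiveBayes(df, labels),
           feature_names = feature_names)
    }))
  fit$keep <- keep; fit$center <- center; fit$scale <- scale
  fit$feature_names <- fit$feature_names %||% feature_names
  new_model(paste0("baseline_", family), feature_kind, fit, CLASS_ORDER)
}

#' Save a trained model to disk
#'
#' Writes a single-file artifact containing the architecture identifier,
#' parameters, feature kind, class order and a format version.
#'
#' @param model A `canivox_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "canivox_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path Path to the artifact.
#' @return The `canivox_model`; predictions reproduce the saved model's
#'   bit-identically.
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) stop("cannot read model artifact ",
                                             path, ": ", conditionMessage(e)))
  if (!inherits(model, "canivox_model"))
    stop("file is not a canivox model artifact: ", path)
  if (!identical(model$format_version, MODEL_FORMAT_VERSION))
    stop("incompatible model format version ", model$format_version,
         " (this package reads version ", MODEL_FORMAT_VERSION, ")")
  model
}

#' Load labeled clips from a folder of WAV files
#'
#' Accepts either class subdirectories (`bark/`, `howl/`) or a flat folder
#' with a `labels.csv` file (columns `file,label`).
#'
#' @param dir Folder path.
#' @return List of [labeled_clip] objects.
#' @export
load_clip_folder <- function(dir) {
  if (!dir.exists(dir)) stop("folder not found: ", dir)
  labels_csv <- file.path(dir, "labels.csv")
  if (file.exists(labels_csv)) {
    tab <- read.csv(labels_csv, stringsAsFactors = FALSE)
    return(lapply(seq_len(nrow(tab)), function(i)
      labeled_clip(read_wav(file.path(dir, tab$file[i])), tab$label[i])))
  }
  out <- list()
  for (cl in CLASS_ORDER) {
    sub <- file.path(dir, cl)
    if (!dir.exists(sub)) next
    for (f in sort(list.files(sub, pattern = "\\.wav$", full.names = TRUE)))
      out[[length(out) + 1L]] <- labeled_clip(read_wav(f), cl)
  }
  if (!length(out)) stop("no labeled clips found under ", dir)
  out
}
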