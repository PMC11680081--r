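#' Confusion matrix from true and predicted labels
#'
#' Rows are true classes, columns predicted classes, in the order given by
#' `class_order`; `counts[i, j]` is the number of instances of true class i
#' predicted as class j.
#'
#' @param y_true,y_pred Equal-length label vectors; every label must
#'   appear in `class_order`.
#' @param class_order Character vector fixing the class order.
#' @return An integer matrix of class `confusion_matrix` with dimnames
#'   `true` x `predicted`.
#' @export
confusion <- function(y_true, y_pred, class_order = c("bark", "howl")) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = class_order),
              factor(y_pred, levels = class_order))
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Construct a confusion matrix directly from counts
#'
#' @param counts Square matrix of non-negative integers (rows = true
#'   class, columns = predicted class).
#' @param class_order Class labels in matrix order.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, class_order = c("bark", "howl")) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) != length(class_order))
    stop("`counts` must be square with one row per class")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(true = class_order, predicted = class_order)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Per-class and aggregate classification metrics
#'
#' For each class: precision `TP / (TP + FP)`, recall `TP / (TP + FN)`,
#' F1 `2PR / (P + R)`, and support (row sum). Overall accuracy is
#' `trace / total`. The macro average is the unweighted mean over classes;
#' the weighted average weights each class metric by its support. A metric
#' whose denominator is zero is reported as 0 and flagged via the
#' `zero_division` attribute.
#'
#' @param cm A `confusion_matrix` with at least one count.
#' @return A `metrics_report`: list with `per_class` (data.frame),
#'   `accuracy`, `macro_avg`, `weighted_avg`, `n`.
#' @export
classification_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- unclass(cm)
  total <- sum(counts)
  if (total == 0L) stop("all-zero confusion matrix")
  classes <- rownames(counts)
  tp <- diag(counts)
  support <- rowSums(counts)
  pred_n <- colSums(counts)

  zero_division <- FALSE
  safe_div <- function(num, den) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0)) zero_division <<- TRUE
    out
  }
  precision <- safe_div(tp, pred_n)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)

  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL)
  avg <- function(v) c(macro = mean(v),
                       weighted = sum(v * support) / total)
  agg <- vapply(list(precision = precision, recall = recall, f1 = f1), avg,
                numeric(2))
  structure(list(per_class = per_class,
                 accuracy = sum(tp) / total,
                 macro_avg = as.list(agg["macro", ]),
                 weighted_avg = as.list(agg["weighted", ]),
                 n = total,
                 zero_division = zero_division),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification report (n =", x$n, ")\n")
  print(transform(x$per_class, precision = round(precision, 4),
                  recall = round(recall, 4), f1 = round(f1, 4)))
  cat(sprintf("accuracy: %.4f\nmacro avg P/R/F1: %.4f / %.4f / %.4f\n",
              x$accuracy, x$macro_avg$precision, x$macro_avg$recall,
              x$macro_avg$f1))
  cat(sprintf("weighted avg P/R/F1: %.4f / %.4f / %.4f\n",
              x$weighted_avg$precision, x$weighted_avg$recall,
              x$weighted_avg$f1))
  invisible(x)
}

#' Round half-up to a number of decimals
#'
#' Comparison-harness convention for matching published two-decimal
#' tables; never applied inside the metrics themselves.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded values (0.005 rounds to 0.01).
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition: `F = MSB / MSW` with
#' `MSB = SSB / (g - 1)` and `MSW = SSW / (n - g)`; the p-value is the
#' upper tail of the F distribution (computed through the regularized
#' incomplete beta function).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups).
#' @return An `anova_result`: list with `F`, `df_between`, `df_within`,
#'   `p_value`, `ss_between`, `ss_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  groups <- lapply(groups, as.numeric)
  if (any(!vapply(groups, length, integer(1)))) stop("empty group")
  n_i <- vapply(groups, length, integer(1))
  g <- length(groups)
  n <- sum(n_i)
  if (n - g < 1L) stop("need more observations than groups")
  grand <- sum(unlist(groups)) / n
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(seq_len(g), function(i) sum((groups[[i]] - means[i])^2),
                    numeric(1)))
  if (ssw == 0)
    stop("zero within-group variance everywhere; F is undefined")
  df_b <- g - 1L; df_w <- n - g
  f <- (ssb / df_b) / (ssw / df_w)
  structure(list(F = f, df_between = df_b, df_within = df_w,
                 p_value = pf(f, df_b, df_w, lower.tail = FALSE),
                 ss_between = ssb, ss_within = ssw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

#' Bundled benchmark of nine audio classifiers
#'
#' Weighted-average F1 scores of nine classifiers (five CNN backbones and
#' four classical models), each evaluated with three feature extraction
#' methods (Mel spectrogram, MFCC, LFCC) on a bark/howl test set of 21
#' clips. Shipped as an example input for [one_way_anova()].
#'
#' @return A data.frame with columns `model`, `feature`, `weighted_f1`
#'   (27 rows).
#' @export
model_benchmark <- function() {
  read.csv(system.file("extdata", "model_benchmark_f1.csv",
                       package = "canivox"),
           stringsAsFactors = FALSE)
}

#' Export a metrics report as CSV or JSON
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- report$per_class
    df <- rbind(df,
                data.frame(class = "macro avg",
                           precision = report$macro_avg$precision,
                           recall = report$macro_avg$recall,
                           f1 = report$macro_avg$f1, support = report$n),
                data.frame(class = "weighted avg",
                           precision = report$weighted_avg$precision,
                           recall = report$weighted_avg$recall,
                           f1 = report$weighted_avg$f1, support = report$n))
    df$accuracy <- report$accuracy
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(path)
}
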