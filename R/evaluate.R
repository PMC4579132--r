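#' Confusion matrix of class predictions
#'
#' @param truth True classes (factor/character/integer).
#' @param estimate Predicted classes, same length and levels.
#' @param classes Optional explicit class order; defaults to the union of
#'   levels in first-appearance order.
#' @return An r x r integer matrix, rows = true class, columns = predicted
#'   class, with class names as dimnames.
#' @examples
#' confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusion_matrix <- function(truth, estimate, classes = NULL) {
  if (length(truth) != length(estimate)) abort("`truth` and `estimate` lengths differ.")
  if (length(truth) == 0) abort("empty input.")
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (is.null(classes)) classes <- unique(c(truth, estimate))
  if (!all(c(truth, estimate) %in% classes)) abort("class outside the declared `classes`.")
  tt <- factor(truth, levels = classes)
  ee <- factor(estimate, levels = classes)
  cm <- table(tt, ee)
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Per-class sensitivity and specificity from a confusion matrix
#'
#' Treats each class one-vs-rest: for class j, TP is the diagonal entry,
#' FN the rest of its row, FP the rest of its column and TN the remainder;
#' sensitivity = TP / (TP + FN) and specificity = TN / (TN + FP). Ratios with
#' a zero denominator are reported as `NA` (not 0) so macro averages stay
#' honest. Total accuracy is the diagonal mass as a percentage.
#'
#' @param cm A square integer confusion matrix (rows = truth), as returned
#'   by [confusion_matrix()].
#' @return An object of class `class_metrics`: a list with `per_class`
#'   (tibble: `class`, `tp`, `fn`, `fp`, `tn`, `sensitivity`, `specificity`),
#'   `accuracy` (percent, 0-100), `macro_sensitivity` and
#'   `macro_specificity` (means over classes, `NA`s dropped). `tidy()`
#'   returns the per-class tibble, `glance()` the one-row summary.
#' @export
class_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || length(cm) == 0) {
    abort("`cm` must be a non-empty square matrix.")
  }
  total <- sum(cm)
  if (total == 0) abort("`cm` has no counts.")
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  per_class <- tibble(
    class = classes,
    tp = as.integer(tp), fn = as.integer(fn),
    fp = as.integer(fp), tn = as.integer(tn),
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, tn + fp)
  )
  structure(list(
    per_class = per_class,
    accuracy = 100 * sum(tp) / total,
    macro_sensitivity = mean(per_class$sensitivity, na.rm = TRUE),
    macro_specificity = mean(per_class$specificity, na.rm = TRUE),
    confusion = cm
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("Total accuracy: %.2f%% (n = %d)\n", x$accuracy, sum(x$confusion)))
  cat(sprintf("Macro sensitivity %.3f, macro specificity %.3f\n",
              x$macro_sensitivity, x$macro_specificity))
  print(x$per_class)
  invisible(x)
}

#' @method tidy class_metrics
#' @export
tidy.class_metrics <- function(x, ...) x$per_class

#' @method glance class_metrics
#' @export
glance.class_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_sensitivity = x$macro_sensitivity,
         macro_specificity = x$macro_specificity,
         n = sum(x$confusion))
}

#' Leave-one-unlabeled cross-validation
#'
#' For each sample in turn, its label is hidden, the model is fitted on all
#' samples with that one unlabeled, and its class is predicted; predictions
#' accumulate into a confusion matrix. Each fold uses seed
#' `seed + fold index`, so the whole procedure is deterministic.
#'
#' @param data Expression data (matrix or data frame with `sample_id`).
#' @param labels Full labels, one per sample (no `NA`).
#' @param classes Optional class order; defaults to first appearance.
#' @param control A [semipnmf_control()] list.
#' @param seed Base integer seed.
#' @param ... Control overrides passed to [semipnmf()].
#' @return An object of class `semipnmf_cv`: list with `predictions`
#'   (tibble: `sample_id`, `truth`, `.pred_class`), `confusion`, and
#'   `metrics` (a [class_metrics()] object).
#' @export
leave_one_unlabeled <- function(data, labels, classes = NULL,
                                control = semipnmf_control(), seed = 1L, ...) {
  V <- as_expression_matrix(data)
  lab <- resolve_labels(V, labels, classes)
  if (anyNA(lab$assignment)) abort("every sample must be labeled for leave-one-unlabeled evaluation.")
  classes <- lab$classes
  sizes <- table(factor(classes[lab$assignment], levels = classes))
  if (any(sizes == 1)) {
    warn(paste0("class(es) with a single sample: ",
                paste(names(sizes)[sizes == 1], collapse = ", "),
                " (their fold has no labeled example of that class)."))
  }
  n <- nrow(V)
  preds <- character(n)
  for (i in seq_len(n)) {
    fold_lab <- classes[lab$assignment]
    fold_lab[i] <- NA_character_
    fit <- semipnmf(V, labels = fold_lab, classes = classes,
                    control = control, seed = seed + i, ...)
    preds[i] <- as.character(predict(fit)$.pred_class[1])
  }
  truth <- classes[lab$assignment]
  cm <- confusion_matrix(truth, preds, classes = classes)
  structure(list(
    predictions = tibble(sample_id = rownames(V),
                         truth = factor(truth, levels = classes),
                         .pred_class = factor(preds, levels = classes)),
    confusion = cm,
    metrics = class_metrics(cm)
  ), class = "semipnmf_cv")
}

#' @export
print.semipnmf_cv <- function(x, ...) {
  cat("Leave-one-unlabeled cross-validation\n")
  print(x$metrics)
  invisible(x)
}

#' @method tidy semipnmf_cv
#' @export
tidy.semipnmf_cv <- function(x, ...) x$predictions

#' @method glance semipnmf_cv
#' @export
glance.semipnmf_cv <- function(x, ...) glance(x$metrics)

#' Accuracy versus number of labeled samples per class
#'
#' For each count in `counts`, repeats `trials` times: draw that many labeled
#' samples per class uniformly without replacement (seeded), fit the model
#' with the rest unlabeled, and record the accuracy on the unlabeled samples.
#' The rising accuracy-vs-labels curve is the standard picture of how much a
#' semi-supervised classifier gains from each additional label.
#'
#' @inheritParams leave_one_unlabeled
#' @param counts Integer vector of labeled-per-class counts (each must leave
#'   at least one unlabeled sample in every class).
#' @param trials Number of random draws per count (default 100).
#' @return A tibble of class `labeled_count_curve` with one row per count:
#'   `n_labeled_per_class`, `mean_accuracy`, `sd_accuracy`, `trials`
#'   (accuracies in percent).
#' @export
labeled_count_curve <- function(data, labels, counts = 1:6, trials = 100,
                                classes = NULL, control = semipnmf_control(),
                                seed = 1L, ...) {
  V <- as_expression_matrix(data)
  lab <- resolve_labels(V, labels, classes)
  if (anyNA(lab$assignment)) abort("every sample must be labeled (labels are hidden by the harness).")
  classes <- lab$classes
  truth <- classes[lab$assignment]
  sizes <- table(factor(truth, levels = classes))
  if (any(max(counts) > sizes - 1)) {
    abort("`counts` too large: each class must keep at least one unlabeled sample.")
  }
  res <- purrr::map_dfr(counts, function(cnt) {
    accs <- vapply(seq_len(trials), function(t) {
      trial_seed <- seed + 1000L * match(cnt, counts) + t
      set.seed(trial_seed)
      labeled_idx <- unlist(lapply(classes, function(cl) {
        idx <- which(truth == cl)
        sample(idx, cnt)
      }))
      part <- truth
      part[-labeled_idx] <- NA_character_
      fit <- semipnmf(V, labels = part, classes = classes,
                      control = control, seed = trial_seed, ...)
      pred <- predict(fit)
      100 * mean(as.character(pred$.pred_class) ==
                   truth[match(pred$sample_id, rownames(V))])
    }, numeric(1))
    tibble(n_labeled_per_class = cnt,
           mean_accuracy = mean(accs),
           sd_accuracy = if (trials > 1) sd(accs) else NA_real_,
           trials = trials)
  })
  class(res) <- c("labeled_count_curve", class(res))
  res
}

#' Plot a labeled-count accuracy curve
#'
#' @param object A [labeled_count_curve()] result.
#' @param ... Unused.
#' @return A ggplot object: mean accuracy (with +/- 1 sd ribbon) against the
#'   number of labeled samples per class.
#' @method autoplot labeled_count_curve
#' @export
autoplot.labeled_count_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_labeled_per_class,
                                       y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                                      ymax = .data$mean_accuracy + .data$sd_accuracy),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Labeled samples per class", y = "Mean accuracy (%)") +
    ggplot2::theme_minimal()
}
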