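#' Tidy the coefficients of a Semi-PNMF fit
#'
#' One row per (unlabeled sample, class) pair with the learned coefficient,
#' in long format.
#'
#' @param x A fitted [semipnmf()] object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `class`, `coefficient`.
#' @method tidy semipnmf
#' @export
tidy.semipnmf <- function(x, ...) {
  as_tibble(x$H_U, .name_repair = "minimal") |>
    setNames(x$classes) |>
    dplyr::mutate(sample_id = x$unlabeled_ids, .before = 1) |>
    tidyr::pivot_longer(-"sample_id", names_to = "class", values_to = "coefficient")
}

#' One-row summary of a Semi-PNMF fit
#'
#' @inheritParams tidy.semipnmf
#' @return A tibble with the dimensions of the problem, the penalty weights,
#'   iteration count, convergence flag and final objective value.
#' @method glance semipnmf
#' @export
glance.semipnmf <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_labeled = length(x$labeled_ids),
    n_unlabeled = length(x$unlabeled_ids),
    n_genes = ncol(x$W),
    alpha = x$control$alpha,
    beta = x$control$beta,
    n_iter = x$n_iter,
    converged = x$converged,
    objective = x$objective_trace[x$n_iter]
  )
}

#' Augment sample records with Semi-PNMF predictions
#'
#' @inheritParams tidy.semipnmf
#' @param data Optional data frame with a `sample_id` column to join onto;
#'   defaults to the fitted samples.
#' @return A tibble with one row per sample: `sample_id`, the supplied label
#'   (`.label`, `NA` for unlabeled), and `.pred_class` — the given label for
#'   labeled samples, the argmax prediction for unlabeled ones.
#' @method augment semipnmf
#' @export
augment.semipnmf <- function(x, data = NULL, ...) {
  pred <- predict(x)
  out <- tibble(sample_id = x$sample_ids, .label = unname(x$labels[x$sample_ids])) |>
    dplyr::left_join(pred[, c("sample_id", ".pred_class")], by = "sample_id") |>
    dplyr::mutate(.pred_class = factor(
      ifelse(is.na(.data$.label), as.character(.data$.pred_class), .data$.label),
      levels = x$classes))
  if (!is.null(data)) {
    out <- dplyr::left_join(as_tibble(data), out, by = "sample_id")
  }
  out
}

#' Plot the objective trace of a Semi-PNMF fit
#'
#' The per-iteration objective value on a log10 y scale; monotone descent is
#' a property of the multiplicative updates, so a non-increasing curve is the
#' expected picture.
#'
#' @param object A fitted [semipnmf()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot semipnmf
#' @export
autoplot.semipnmf <- function(object, ...) {
  df <- tibble(iteration = seq_len(object$n_iter), objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "Objective J (log scale)",
                  title = "Semi-PNMF objective trace") +
    ggplot2::theme_minimal()
}

#' Heatmap of unlabeled-sample coefficients
#'
#' Rows are unlabeled samples, columns classes; the darkest entry in a row is
#' the predicted class. Mirrors the coefficient panels used to illustrate
#' label propagation.
#'
#' @param fit A fitted [semipnmf()] object.
#' @return A ggplot object.
#' @export
plot_coefficients <- function(fit) {
  stopifnot(inherits(fit, "semipnmf"))
  tidy(fit) |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = rev(fit$unlabeled_ids)),
                  class = factor(.data$class, levels = fit$classes)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$class, y = .data$sample_id,
                                 fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::labs(x = "Class", y = "Unlabeled sample", fill = "H[U]") +
    ggplot2::theme_minimal()
}
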