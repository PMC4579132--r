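#' Control parameters for Semi-PNMF fitting
#'
#' @param alpha Non-negative weight of the centroid-consistency (projective)
#'   penalty tying centroids to the span of the unlabeled samples. Default 0.2.
#' @param beta Non-negative weight of the local coordinate coding penalty that
#'   sparsifies coefficients toward nearby centroids. Default 0.01.
#' @param max_iter Maximum number of update sweeps (one W update followed by
#'   one H_U update). Default 1500.
#' @param tol Relative-objective stopping threshold: iteration stops once
#'   `|J_new - J_old| / |J_old| < tol`. Default 1e-7.
#' @param denom_guard Additive guard for the multiplicative-update
#'   denominators. Default 1e-12.
#' @param rescale If `TRUE`, divide the expression matrix by its global
#'   maximum before fitting (off by default; the model applies no internal
#'   normalization).
#' @return A list of class `semipnmf_control`.
#' @export
semipnmf_control <- function(alpha = 0.2, beta = 0.01, max_iter = 1500,
                             tol = 1e-7, denom_guard = 1e-12, rescale = FALSE) {
  stopifnot(alpha >= 0, beta >= 0, max_iter >= 1, tol > 0, denom_guard > 0)
  structure(list(alpha = alpha, beta = beta, max_iter = as.integer(max_iter),
                 tol = tol, denom_guard = denom_guard, rescale = rescale),
            class = "semipnmf_control")
}

#' Fit a semi-supervised projective NMF classifier
#'
#' Factorizes a partially labeled non-negative expression matrix
#' \eqn{V = [V_L; V_U]} (samples x genes) as \eqn{V \approx [Q; H_U] W}:
#' the coefficient rows of labeled samples are pinned to their one-hot class
#' indicators \eqn{Q} throughout, so the shared centroid matrix \eqn{W}
#' (classes x genes) absorbs the label structure, and the free non-negative
#' coefficients \eqn{H_U} of the unlabeled samples inherit it. Unlabeled
#' samples are classified by the argmax of their coefficient row. The
#' objective (see [semipnmf_objective()]) is minimized by alternating
#' multiplicative updates — [update_w()] then [update_h()] each sweep — which
#' keep both factors non-negative and never increase the objective.
#'
#' W and H_U are initialized i.i.d. uniform on (0, 1) from `seed`; a strictly
#' positive start avoids the zero-locking of multiplicative rules. Iteration
#' stops at the relative-objective criterion `tol` or at `max_iter`
#' (`converged = FALSE` then, which is not an error). An exact zero objective
#' stops immediately.
#'
#' @param data Expression data: a numeric samples-by-genes matrix or a data
#'   frame with a `sample_id` column and numeric gene columns (see
#'   [as_expression_matrix()]). Values must be non-negative with no missing
#'   entries.
#' @param labels Partial labels: a vector with one entry per sample
#'   (`NA` or `"UNLABELED"` = unlabeled) or a data frame with `sample_id`
#'   and `class` columns listing the labeled samples only.
#' @param classes Optional explicit class order; defaults to first appearance
#'   in `labels`. The factorization rank r equals the number of classes.
#' @param control A [semipnmf_control()] list.
#' @param seed Integer seed for the random initialization.
#' @param ... Shorthand overrides for `control` fields, e.g. `alpha = 2`.
#' @return An object of class `semipnmf` with elements `W` (r x genes
#'   centroids), `H_U` (unlabeled x r coefficients), `objective_trace`,
#'   `n_iter`, `converged`, `classes`, sample bookkeeping, and the control
#'   used. Methods: [predict.semipnmf()], [tidy.semipnmf()],
#'   [glance.semipnmf()], [augment.semipnmf()], [autoplot.semipnmf()].
#' @examples
#' toy <- generate_toy(seed = 1)
#' fit <- semipnmf(toy, labels = toy$class, seed = 1, max_iter = 300)
#' glance(fit)
#' @export
semipnmf <- function(data, labels, classes = NULL,
                     control = semipnmf_control(), seed = 1L, ...) {
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(control))
    if (length(bad)) abort(paste0("unknown control argument(s): ", paste(bad, collapse = ", ")))
    control[names(dots)] <- dots
    control <- do.call(semipnmf_control, unclass(control))
  }
  V <- as_expression_matrix(data)
  lab <- resolve_labels(V, labels, classes)
  r <- length(lab$classes)
  if (r < 1) abort("no classes declared; supply at least one labeled sample or `classes`.")
  is_lab <- !is.na(lab$assignment)
  n_U <- sum(!is_lab)
  if (n_U < 1) abort("no unlabeled samples; nothing to classify.")
  empty <- lab$classes[!seq_len(r) %in% lab$assignment[is_lab]]
  if (length(empty) && any(is_lab)) {
    warn(paste0("class(es) without a labeled sample: ", paste(empty, collapse = ", "),
                " (their centroids are data-driven only)."))
  }
  if (isTRUE(control$rescale) && max(V) > 0) V <- V / max(V)

  V_L <- V[is_lab, , drop = FALSE]
  V_U <- V[!is_lab, , drop = FALSE]
  Q <- indicator_matrix(lab$assignment, r)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  W <- matrix(runif(r * ncol(V)), r, ncol(V))
  H_U <- matrix(runif(n_U * r), n_U, r)

  trace <- numeric(control$max_iter)
  J_prev <- NA_real_
  converged <- FALSE
  l <- 0L
  while (l < control$max_iter) {
    l <- l + 1L
    W <- update_w(V_L, V_U, Q, W, H_U, control$alpha, control$beta, control$denom_guard)
    H_U <- update_h(V_U, W, H_U, control$alpha, control$beta, control$denom_guard)
    J <- semipnmf_objective(V_L, V_U, Q, W, H_U, control$alpha, control$beta)
    trace[l] <- J
    if (J == 0 || (!is.na(J_prev) && abs(J - J_prev) / abs(J_prev) < control$tol)) {
      converged <- TRUE
      break
    }
    J_prev <- J
  }

  dimnames(W) <- list(lab$classes, colnames(V))
  dimnames(H_U) <- list(rownames(V_U), lab$classes)
  structure(list(
    W = W, H_U = H_U,
    objective_trace = trace[seq_len(l)],
    n_iter = l, converged = converged,
    classes = lab$classes,
    sample_ids = rownames(V),
    labeled_ids = rownames(V)[is_lab],
    unlabeled_ids = rownames(V)[!is_lab],
    labels = setNames(lab$classes[lab$assignment], rownames(V)),
    control = control, seed = as.integer(seed)
  ), class = "semipnmf")
}

#' @export
print.semipnmf <- function(x, ...) {
  cat(sprintf(
    "Semi-PNMF fit: %d classes, %d labeled + %d unlabeled samples, %d genes\n",
    length(x$classes), length(x$labeled_ids), length(x$unlabeled_ids), ncol(x$W)))
  cat(sprintf("  alpha = %g, beta = %g; %d iteration(s); %s; final J = %.6g\n",
              x$control$alpha, x$control$beta, x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              x$objective_trace[x$n_iter]))
  invisible(x)
}

#' Argmax class assignment from a coefficient matrix
#'
#' Each sample is assigned the class whose coefficient is largest in its row;
#' ties break to the lowest class index, so the rule is deterministic and
#' invariant to positive rescaling of the coefficients.
#'
#' @param H_U Non-negative coefficient matrix (samples x classes).
#' @param classes Optional class names; defaults to `colnames(H_U)`.
#' @return Factor of predicted classes (or integer indices when no names are
#'   available), one per row.
#' @export
predict_classes <- function(H_U, classes = colnames(H_U)) {
  if (!is.matrix(H_U) || nrow(H_U) == 0 || ncol(H_U) == 0) {
    abort("`H_U` must be a non-empty matrix.")
  }
  if (anyNA(H_U) || any(is.infinite(H_U)) || min(H_U) < 0) {
    abort("`H_U` must be finite and non-negative.")
  }
  idx <- max.col(H_U, ties.method = "first")
  if (is.null(classes)) idx else factor(classes[idx], levels = classes)
}

#' Predict classes of the unlabeled samples
#'
#' @param object A fitted [semipnmf()] object.
#' @param ... Unused.
#' @return A tibble with one row per unlabeled sample: `sample_id`,
#'   `.pred_class`, and the coefficient for each class.
#' @export
predict.semipnmf <- function(object, ...) {
  coef_tbl <- as_tibble(object$H_U, .name_repair = "minimal")
  names(coef_tbl) <- paste0(".coef_", object$classes)
  dplyr::bind_cols(
    tibble(sample_id = object$unlabeled_ids,
           .pred_class = predict_classes(object$H_U, object$classes)),
    coef_tbl
  )
}
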