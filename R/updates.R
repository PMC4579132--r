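#' Multiplicative update for the centroid matrix W
#'
#' One multiplicative-update step for the centroids with the coefficients
#' held fixed:
#' \deqn{W \leftarrow W \otimes \frac{Q^\top V_L + (1+\alpha+\beta) H_U^\top V_U}
#'   {Q^\top Q W + H_U^\top H_U W + \alpha W + \beta F_U W + \epsilon}}
#' with \eqn{F_U = \mathrm{diag}(\mathrm{colSums}(H_U))} (an r x r diagonal:
#' total coefficient mass per class). The update preserves non-negativity and
#' never increases the objective; a small additive guard `denom_guard` keeps
#' the elementwise division defined where a denominator entry is exactly zero.
#'
#' @inheritParams semipnmf_objective
#' @param denom_guard Small positive constant added to the denominator.
#' @return The updated W, same shape, non-negative.
#' @seealso [update_h()], [semipnmf()]
#' @export
update_w <- function(V_L, V_U, Q, W, H_U, alpha, beta, denom_guard = 1e-12) {
  check_core_shapes(V_L, V_U, Q, W, H_U, alpha, beta)
  num <- crossprod(Q, V_L) + (1 + alpha + beta) * crossprod(H_U, V_U)
  den <- crossprod(Q) %*% W + crossprod(H_U) %*% W + alpha * W +
    beta * colSums(H_U) * W + denom_guard
  out <- W * num / den
  if (anyNA(out)) abort("NaN produced in update_w (zero denominator not covered by guard).")
  out
}

#' Multiplicative update for the unlabeled coefficients H_U
#'
#' One multiplicative-update step for the unlabeled-sample coefficients with
#' the centroids held fixed:
#' \deqn{H_U \leftarrow H_U \otimes \frac{(1+\alpha+\beta) V_U W^\top}
#'   {H_U W W^\top + \alpha V_U V_U^\top H_U + (\beta/2)(A + B) + \epsilon}}
#' where \eqn{A_{ij} = \|V_U^i\|_2^2} (row norms of the unlabeled data,
#' broadcast across classes) and \eqn{B_{ij} = \|W^j\|_2^2} (centroid row
#' norms, broadcast across samples). Exact zeros in `H_U` stay zero — the
#' multiplicative form cannot revive a zeroed coefficient.
#'
#' @inheritParams update_w
#' @return The updated H_U, same shape, non-negative.
#' @seealso [update_w()], [semipnmf()]
#' @export
update_h <- function(V_U, W, H_U, alpha, beta, denom_guard = 1e-12) {
  d0 <- matrix(0, 0, ncol(W))
  check_core_shapes(d0, V_U, matrix(0, 0, nrow(W)), W, H_U, alpha, beta)
  num <- (1 + alpha + beta) * tcrossprod(V_U, W)
  A <- outer(rowSums(V_U^2), rep(1, nrow(W)))
  B <- outer(rep(1, nrow(V_U)), rowSums(W^2))
  den <- H_U %*% tcrossprod(W) + alpha * (V_U %*% crossprod(V_U, H_U)) +
    (beta / 2) * (A + B) + denom_guard
  out <- H_U * num / den
  if (anyNA(out)) abort("NaN produced in update_h (zero denominator not covered by guard).")
  out
}
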