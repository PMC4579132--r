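#' Semi-PNMF objective function
#'
#' Evaluates the penalized reconstruction objective
#' \deqn{J = \tfrac12 \| [V_L; V_U] - [Q; H_U] W \|_F^2
#'       + \tfrac{\alpha}{2} \| W - H_U^\top V_U \|_F^2
#'       + \tfrac{\beta}{2} \sum_{ij} |H_{U,ij}| \, \| V_U^i - W^j \|_2^2}
#' where \eqn{V_L} (d x m) holds the labeled samples with one-hot indicator
#' \eqn{Q} (d x r), \eqn{V_U} (n_U x m) the unlabeled samples with free
#' non-negative coefficients \eqn{H_U} (n_U x r), and \eqn{W} (r x m) the
#' shared cluster centroids. The first term is the joint reconstruction, the
#' second ties centroids to the span of the unlabeled data (the projective
#' constraint, weight `alpha`), and the third is the local coordinate coding
#' penalty (weight `beta`) that pulls each sample toward nearby centroids and
#' sparsifies its coefficients. With `d = 0` the labeled block vanishes and
#' the model reduces to its unsupervised form.
#'
#' @param V_L Labeled-sample matrix, d x m (d may be 0).
#' @param V_U Unlabeled-sample matrix, n_U x m.
#' @param Q One-hot class indicator, d x r.
#' @param W Centroid matrix, r x m.
#' @param H_U Unlabeled coefficients, n_U x r.
#' @param alpha,beta Non-negative penalty weights.
#' @return The objective value, a non-negative scalar.
#' @examples
#' V <- matrix(c(1, 2, 3, 4), 2, 2)
#' semipnmf_objective(V[0, , drop = FALSE], V, matrix(0, 0, 1),
#'                    W = matrix(0, 1, 2), H_U = matrix(0, 2, 1),
#'                    alpha = 1, beta = 1)
#' @export
semipnmf_objective <- function(V_L, V_U, Q, W, H_U, alpha, beta) {
  check_core_shapes(V_L, V_U, Q, W, H_U, alpha, beta)
  V <- rbind(V_L, V_U)
  C <- rbind(Q, H_U)
  rec <- 0.5 * sum((V - C %*% W)^2)
  proj <- 0.5 * alpha * sum((W - crossprod(H_U, V_U))^2)
  lcc <- 0.5 * beta * sum(abs(H_U) * pairwise_sqdist(V_U, W))
  rec + proj + lcc
}

# Squared Euclidean distances between rows of X (n x m) and rows of W (r x m),
# returned as an n x r matrix.
pairwise_sqdist <- function(X, W) {
  outer(rowSums(X^2), rep(1, nrow(W))) - 2 * tcrossprod(X, W) +
    outer(rep(1, nrow(X)), rowSums(W^2))
}

check_core_shapes <- function(V_L, V_U, Q, W, H_U, alpha, beta) {
  for (nm in c("V_L", "V_U", "Q", "W", "H_U")) {
    x <- get(nm)
    if (!is.matrix(x) || !is.numeric(x)) abort(sprintf("`%s` must be a numeric matrix.", nm))
    if (anyNA(x) || any(is.infinite(x))) abort(sprintf("`%s` contains non-finite values.", nm))
    if (length(x) && min(x) < 0) abort(sprintf("`%s` must be non-negative.", nm))
  }
  m <- ncol(W); r <- nrow(W)
  if (ncol(V_U) != m || ncol(V_L) != m) abort("gene dimension mismatch between V and W.")
  if (nrow(Q) != nrow(V_L)) abort("`Q` must have one row per labeled sample.")
  if (ncol(Q) != r || ncol(H_U) != r) abort("class dimension mismatch with W.")
  if (nrow(H_U) != nrow(V_U)) abort("`H_U` must have one row per unlabeled sample.")
  if (alpha < 0 || beta < 0) abort("`alpha` and `beta` must be non-negative.")
  invisible(TRUE)
}
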