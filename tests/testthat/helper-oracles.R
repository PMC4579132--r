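# Independent scalar-loop transcriptions of the objective and the two
# multiplicative updates, plus a random small-instance generator. These stay
# deliberately naive (explicit sums, no matrix algebra) so they can serve as
# oracles for the vectorized implementations.

oracle_objective <- function(V_L, V_U, Q, W, H_U, alpha, beta) {
  V <- rbind(V_L, V_U)
  C <- rbind(Q, H_U)
  rec <- 0
  for (i in seq_len(nrow(V))) for (k in seq_len(ncol(V))) {
    pred <- 0
    for (j in seq_len(ncol(C))) pred <- pred + C[i, j] * W[j, k]
    rec <- rec + (V[i, k] - pred)^2
  }
  proj <- 0
  for (j in seq_len(nrow(W))) for (k in seq_len(ncol(W))) {
    hv <- 0
    for (i in seq_len(nrow(V_U))) hv <- hv + H_U[i, j] * V_U[i, k]
    proj <- proj + (W[j, k] - hv)^2
  }
  lcc <- 0
  for (i in seq_len(nrow(V_U))) for (j in seq_len(nrow(W))) {
    d2 <- 0
    for (k in seq_len(ncol(V_U))) d2 <- d2 + (V_U[i, k] - W[j, k])^2
    lcc <- lcc + abs(H_U[i, j]) * d2
  }
  0.5 * rec + 0.5 * alpha * proj + 0.5 * beta * lcc
}

oracle_update_w <- function(V_L, V_U, Q, W, H_U, alpha, beta, guard = 1e-12) {
  r <- nrow(W); m <- ncol(W)
  FU <- numeric(r)
  for (j in seq_len(r)) FU[j] <- sum(H_U[, j])
  out <- W
  for (j in seq_len(r)) for (k in seq_len(m)) {
    num <- 0
    for (i in seq_len(nrow(V_L))) num <- num + Q[i, j] * V_L[i, k]
    for (i in seq_len(nrow(V_U))) num <- num + (1 + alpha + beta) * H_U[i, j] * V_U[i, k]
    den <- alpha * W[j, k] + beta * FU[j] * W[j, k]
    for (jj in seq_len(r)) {
      qq <- 0; hh <- 0
      for (i in seq_len(nrow(Q))) qq <- qq + Q[i, j] * Q[i, jj]
      for (i in seq_len(nrow(H_U))) hh <- hh + H_U[i, j] * H_U[i, jj]
      den <- den + (qq + hh) * W[jj, k]
    }
    out[j, k] <- W[j, k] * num / (den + guard)
  }
  out
}

oracle_update_h <- function(V_U, W, H_U, alpha, beta, guard = 1e-12) {
  n_U <- nrow(H_U); r <- ncol(H_U)
  out <- H_U
  for (i in seq_len(n_U)) for (j in seq_len(r)) {
    num <- 0
    for (k in seq_len(ncol(V_U))) num <- num + V_U[i, k] * W[j, k]
    num <- (1 + alpha + beta) * num
    den <- 0
    for (jj in seq_len(r)) {
      ww <- 0
      for (k in seq_len(ncol(W))) ww <- ww + W[j, k] * W[jj, k]
      den <- den + H_U[i, jj] * ww
    }
    for (ii in seq_len(n_U)) {
      vv <- 0
      for (k in seq_len(ncol(V_U))) vv <- vv + V_U[i, k] * V_U[ii, k]
      den <- den + alpha * vv * H_U[ii, j]
    }
    A_ij <- sum(V_U[i, ]^2)
    B_ij <- sum(W[j, ]^2)
    den <- den + (beta / 2) * (A_ij + B_ij)
    out[i, j] <- H_U[i, j] * num / (den + guard)
  }
  out
}

# Random small semi-supervised instance: n <= 20 samples, m <= 10 genes,
# r in 2:4 classes, at least one labeled sample per class, >= 1 unlabeled.
random_instance <- function(seed, alpha = NULL, beta = NULL) {
  set.seed(seed)
  r <- sample(2:4, 1)
  m <- sample(2:10, 1)
  n <- sample((r + 2):20, 1)
  d <- sample(r:(n - 1), 1)
  cls <- c(seq_len(r), sample(seq_len(r), d - r, replace = TRUE))
  V <- matrix(runif(n * m, 0.05, 2), n, m)
  Q <- matrix(0, d, r)
  Q[cbind(seq_len(d), cls)] <- 1
  list(
    V_L = V[seq_len(d), , drop = FALSE],
    V_U = V[(d + 1):n, , drop = FALSE],
    Q = Q,
    W = matrix(runif(r * m), r, m),
    H_U = matrix(runif((n - d) * r), n - d, r),
    alpha = alpha %||% sample(c(0, 0.01, 1, 2), 1),
    beta = beta %||% sample(c(0, 0.01, 1, 2), 1),
    n = n, m = m, r = r, d = d
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Accuracy of the argmax prediction on the unlabeled toy samples.
toy_unlabeled_accuracy <- function(seed, ...) {
  toy <- generate_toy(seed = seed)
  fit <- semipnmf(toy, labels = toy$class, seed = seed, ...)
  pred <- predict(fit)
  truth <- toy$true_class[match(pred$sample_id, toy$sample_id)]
  mean(as.character(pred$.pred_class) == as.character(truth))
}
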