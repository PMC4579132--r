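test_that("objective trace is non-increasing across random small problems", {
  for (s in 1:40) {
    inst <- random_instance(s)
    V <- rbind(inst$V_L, inst$V_U)
    rownames(V) <- sprintf("s%d", seq_len(nrow(V)))
    lab <- c(paste0("k", max.col(inst$Q)), rep(NA_character_, nrow(inst$V_U)))
    fit <- semipnmf(V, labels = lab, classes = paste0("k", seq_len(inst$r)),
                    alpha = inst$alpha, beta = inst$beta,
                    max_iter = 60, seed = s)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * abs(tr[-length(tr)])))
    expect_lte(fit$n_iter, 60)
  }
})

test_that("converged states satisfy the multiplicative KKT stationarity condition", {
  set.seed(42)
  V <- matrix(runif(6 * 4, 0.1, 1.5), 6, 4,
              dimnames = list(sprintf("s%d", 1:6), NULL))
  lab <- c("a", "b", "a", "b", NA, NA)
  fit <- semipnmf(V, labels = lab, alpha = 0.5, beta = 0.1,
                  tol = 1e-12, max_iter = 20000, seed = 3)
  expect_true(fit$converged)
  is_lab <- !is.na(lab)
  W2 <- update_w(V[is_lab, ], V[!is_lab, ], diag(2)[match(lab[is_lab], c("a", "b")), ],
                 fit$W, fit$H_U, 0.5, 0.1)
  H2 <- update_h(V[!is_lab, ], fit$W, fit$H_U, 0.5, 0.1)
  fw <- (W2 / fit$W)[fit$W > 1e-6]
  fh <- (H2 / fit$H_U)[fit$H_U > 1e-6]
  expect_true(all(abs(fw - 1) < 1e-3))
  expect_true(all(abs(fh - 1) < 1e-3))
})

test_that("argmax prediction follows the documented tie-break and is scale invariant", {
  H <- rbind(c(0.1, 0.8, 0.05),
             c(0, 1, 0),
             c(0.5, 0.5, 0.2))
  expect_equal(predict_classes(H), c(2L, 2L, 1L))
  cls <- c("x", "y", "z")
  colnames(H) <- cls
  expect_equal(as.character(predict_classes(H)), c("y", "y", "x"))
  expect_equal(predict_classes(H * 17), predict_classes(H))
  expect_error(predict_classes(H[0, , drop = FALSE]), "non-empty")
  expect_error(predict_classes(-H), "non-negative")
})

test_that("unsupervised mode (no labels) runs and descends", {
  set.seed(5)
  V <- matrix(runif(8 * 4, 0.1, 1), 8, 4)
  fit <- semipnmf(V, labels = NULL, classes = c("u1", "u2"),
                  max_iter = 100, seed = 5)
  expect_length(fit$labeled_ids, 0)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * abs(tr[-length(tr)])))
  expect_equal(nrow(fit$H_U), 8)
})

test_that("degenerate label configurations are reported", {
  set.seed(6)
  V <- matrix(runif(4 * 3, 0.1, 1), 4, 3)
  expect_error(semipnmf(V, labels = c("a", "a", "b", "b"), seed = 1),
               "unlabeled")
  expect_warning(
    semipnmf(V, labels = c("a", NA, NA, NA), classes = c("a", "b"),
             max_iter = 5, seed = 1),
    "without a labeled sample")
  expect_error(semipnmf(V, labels = rep(NA, 4), seed = 1), "class")
})

test_that("learned centroids align one-to-one with the generating toy means", {
  # The centroid-consistency penalty pins centroid directions, not scales
  # (coefficient-weighted sums overshoot the class means by a common factor),
  # so alignment is assessed on unit-normalized rows.
  means <- rbind(c(1, 0.8, 0.8), c(0.8, 0.8, 0.8), c(0.8, 1, 0.7))
  centers <- means + c(0.1, 0.1, 0.15) / 2   # expected cloud centers
  unit <- function(M) M / sqrt(rowSums(M^2))
  cu <- unit(centers)
  ok <- vapply(1:5, function(s) {
    toy <- generate_toy(seed = s)
    fit <- semipnmf(toy, labels = toy$class, seed = s)
    nearest <- apply(unit(fit$W), 1, function(w) {
      which.min(colSums((t(cu) - w)^2))
    })
    all(nearest == 1:3)
  }, logical(1))
  expect_true(all(ok))
})

test_that("fitting is reproducible under a fixed seed", {
  toy <- generate_toy(seed = 2)
  f1 <- semipnmf(toy, labels = toy$class, seed = 11, max_iter = 50)
  f2 <- semipnmf(toy, labels = toy$class, seed = 11, max_iter = 50)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H_U, f2$H_U)
  f3 <- semipnmf(toy, labels = toy$class, seed = 12, max_iter = 50)
  expect_false(identical(f1$W, f3$W))
})
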