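test_that("confusion matrix tabulates truth rows against prediction columns", {
  cm <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(diag(cm)), rep(1L, 3))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  cm2 <- confusion_matrix(c("a", "a"), c("b", "b"), classes = c("a", "b"))
  expect_equal(cm2["a", "b"], 2L)
  expect_equal(sum(cm2), 2L)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("a", "q", classes = "a"), "outside")
})

test_that("confusion matrix equals a direct double-loop tally on random draws", {
  set.seed(10)
  for (rep in 1:5) {
    r <- sample(2:5, 1)
    n <- sample(10:60, 1)
    classes <- paste0("k", seq_len(r))
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusion_matrix(truth, pred, classes = classes)
    manual <- matrix(0L, r, r, dimnames = list(truth = classes, predicted = classes))
    for (i in seq_len(n)) {
      manual[truth[i], pred[i]] <- manual[truth[i], pred[i]] + 1L
    }
    expect_identical(cm, manual)
    expect_equal(sum(cm), n)
  }
})

test_that("sensitivity, specificity and accuracy follow the one-vs-rest definitions", {
  cm <- matrix(c(19, 1, 10, 90), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  met <- class_metrics(cm)
  expect_equal(met$per_class$sensitivity[1], 19 / 20)
  expect_equal(met$per_class$specificity[1], 90 / 100)
  expect_equal(met$accuracy, 100 * 109 / 120)
  perfect <- class_metrics(diag(5L) * 3L)
  expect_true(all(perfect$per_class$sensitivity == 1))
  expect_true(all(perfect$per_class$specificity == 1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(glance(perfect)$accuracy, 100)
})

test_that("zero-denominator metrics are missing, not zero, and match raw enumeration", {
  # class "c" never occurs in truth -> sensitivity undefined
  truth <- c("a", "a", "b")
  pred <- c("a", "b", "c")
  cm <- confusion_matrix(truth, pred, classes = c("a", "b", "c"))
  met <- class_metrics(cm)
  expect_true(is.na(met$per_class$sensitivity[3]))
  for (j in 1:3) {
    cl <- c("a", "b", "c")[j]
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    expect_equal(met$per_class$tp[j], tp)
    if (tp + fn > 0) expect_equal(met$per_class$sensitivity[j], tp / (tp + fn))
    expect_equal(met$per_class$specificity[j], tn / (tn + fp))
  }
})

test_that("permuting the class order permutes but does not change per-class metrics", {
  set.seed(11)
  classes <- c("a", "b", "c")
  truth <- sample(classes, 40, replace = TRUE)
  pred <- sample(classes, 40, replace = TRUE)
  m1 <- class_metrics(confusion_matrix(truth, pred, classes = classes))
  perm <- c("c", "a", "b")
  m2 <- class_metrics(confusion_matrix(truth, pred, classes = perm))
  expect_equal(m1$accuracy, m2$accuracy)
  reord <- match(m1$per_class$class, m2$per_class$class)
  expect_equal(m1$per_class$sensitivity, m2$per_class$sensitivity[reord])
  expect_equal(m1$per_class$specificity, m2$per_class$specificity[reord])
})

test_that("leave-one-unlabeled folds conserve counts and are deterministic under the seed", {
  toy <- generate_toy(n_per_class = 4, seed = 3)
  cv <- leave_one_unlabeled(toy, labels = toy$true_class,
                            max_iter = 400, seed = 3)
  expect_equal(sum(cv$confusion), nrow(toy))
  expect_equal(nrow(cv$predictions), nrow(toy))
  expect_identical(tidy(cv), cv$predictions)
  expect_true(cv$metrics$accuracy >= 0 && cv$metrics$accuracy <= 100)
  cv2 <- leave_one_unlabeled(toy, labels = toy$true_class,
                             max_iter = 400, seed = 3)
  expect_identical(cv$confusion, cv2$confusion)
  # a class with a single member leaves its fold without any example of it
  small <- generate_toy(n_per_class = 2, n_labeled_per_class = 1, seed = 4)
  sub <- small[c(1, 3, 4, 5, 6), ]
  # the harness warns about the singleton class; its folds additionally warn
  # that the class has no labeled example left
  warns <- capture_warnings(
    leave_one_unlabeled(sub, labels = sub$true_class, max_iter = 30, seed = 1))
  expect_match(warns, "single sample", all = FALSE)
  expect_match(warns, "without a labeled sample", all = FALSE)
})

test_that("labeled-count curve is seeded, bounded and shaped as requested", {
  toy <- generate_toy(seed = 6)
  cur <- labeled_count_curve(toy, labels = toy$true_class, counts = c(2, 4),
                             trials = 2, max_iter = 200, seed = 9)
  expect_equal(nrow(cur), 2)
  expect_equal(cur$n_labeled_per_class, c(2, 4))
  expect_true(all(cur$mean_accuracy >= 0 & cur$mean_accuracy <= 100))
  cur2 <- labeled_count_curve(toy, labels = toy$true_class, counts = c(2, 4),
                              trials = 2, max_iter = 200, seed = 9)
  expect_identical(cur, cur2)
  expect_error(
    labeled_count_curve(toy, labels = toy$true_class, counts = 10, trials = 1),
    "at least one unlabeled")
})

test_that("more labels never hurt on average (3 vs 1 labeled per class, 20 trials)", {
  toy <- generate_toy(seed = 5)
  cur <- labeled_count_curve(toy, labels = toy$true_class, counts = c(1, 3),
                             trials = 20, max_iter = 300, seed = 2)
  expect_gte(cur$mean_accuracy[2], cur$mean_accuracy[1])
})
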