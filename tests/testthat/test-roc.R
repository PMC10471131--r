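test_that("perfectly separated scores give AUC = 1 and J = 1", {
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$cutoff, 10)  # lowest threshold achieving J = 1
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("AUC equals the exhaustive concordant-pair oracle, ties included", {
  toy <- c(3, 1, 4, 4, 2, 5)
  lab <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  r <- roc_youden(toy, lab)
  expect_equal(r$auc, pairwise_auc(toy, lab), tolerance = 1e-12)

  withr::with_seed(31, {
    for (i in 1:20) {
      scores <- sample(1:8, 14, replace = TRUE)  # heavy ties
      pos <- sample(c(TRUE, FALSE), 14, replace = TRUE)
      if (length(unique(pos)) < 2) next
      expect_equal(roc_youden(scores, pos)$auc, pairwise_auc(scores, pos),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on continuous scores", {
  withr::with_seed(32, {
    scores <- c(rnorm(40, 1), rnorm(40))
    lab <- rep(c(TRUE, FALSE), each = 40)
  })
  ours <- roc_youden(scores, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, scores, direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("uninformative scores give AUC near 0.5 and an orientation note", {
  withr::with_seed(33, {
    scores <- rnorm(2000)
    lab <- rep(c(TRUE, FALSE), 1000)
  })
  r <- roc_youden(scores, lab)
  expect_lt(abs(r$auc - 0.5), 0.05)
  rev <- roc_youden(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_false(is.na(rev$orientation_note))
})

test_that("youden_j always equals sensitivity + specificity - 1 at the cutoff", {
  withr::with_seed(34, {
    for (i in 1:10) {
      scores <- round(rnorm(30), 1)
      lab <- rep(c(TRUE, FALSE), 15)
      r <- roc_youden(scores, lab)
      expect_equal(r$youden_j, r$sensitivity + r$specificity - 1,
                   tolerance = 1e-12)
      expect_true(r$auc >= 0 && r$auc <= 1)
    }
  })
})

test_that("label handling: explicit positive class, single-class errors", {
  r <- roc_youden(c(20, 21, 30, 31), c("healthy", "healthy", "HF", "HF"),
                  positive = "HF")
  expect_equal(r$auc, 1)
  expect_error(roc_youden(1:4, rep("HF", 4)), "two classes")
  expect_error(roc_youden(1:4, c("a", "a", "b", "b"), positive = "c"),
               "not present")
})
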