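# Published single- and dual-threshold evaluation tables: confusion counts
# and the metric cells they imply (percent, 1 decimal).
reference_metric_cases <- list(
  list(counts = c(1136, 635, 218, 402),                 # threshold 5, PSD+SWLDA
       precision = 64.1, sensitivity = 83.9, specificity = 38.8,
       accuracy = 64.3, f_measure = 72.7),
  list(counts = c(771, 361, 267, 514),                  # thresholds 4/6, PSD+SWLDA
       precision = 68.1, sensitivity = 74.3, specificity = 58.7,
       accuracy = 67.2, f_measure = 71.1),
  list(counts = c(477, 172, 61, 142),                   # thresholds 3/7, PSD+SWLDA
       precision = 73.5, sensitivity = 88.7, specificity = 45.2,
       accuracy = 72.7, f_measure = 80.4),
  list(counts = c(503, 245, 35, 69),                    # thresholds 3/7, AR
       precision = 67.2, sensitivity = 93.5, specificity = 22.0,
       accuracy = 67.1, f_measure = 78.2)
)

test_that("metric formulas reproduce the published table cells", {
  for (case in reference_metric_cases) {
    cc <- confusion_counts(case$counts[1], case$counts[2],
                           case$counts[3], case$counts[4])
    m <- compute_metrics(cc)
    for (metric in c("precision", "sensitivity", "specificity", "accuracy",
                     "f_measure")) {
      expect_equal(round(m[[metric]], 1), case[[metric]],
                   tolerance = 1e-9,
                   label = sprintf("%s of counts (%s)", metric,
                                   paste(case$counts, collapse = ",")))
    }
  }
})

test_that("perfect and degenerate classifiers are handled exactly", {
  perfect <- compute_metrics(confusion_counts(7, 0, 0, 5))
  expect_equal(unname(unlist(perfect[1, 1:5])), rep(100, 5))

  no_pos_pred <- compute_metrics(confusion_counts(0, 0, 3, 7))
  expect_true(is.na(no_pos_pred$precision))       # flagged, not zero
  expect_equal(no_pos_pred$sensitivity, 0)
  expect_equal(no_pos_pred$accuracy, 70)

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)),
               class = "drowsy_error")
  expect_error(confusion_counts(-1, 0, 0, 0), class = "drowsy_error")
})

test_that("ROC endpoints, symmetry, and the trapezoid AUC are correct", {
  y <- c(0, 0, 1, 1, 0, 1)
  perfect <- roc_curve(y, y)
  expect_equal(attr(perfect, "auc"), 1)

  withr::with_seed(30, {
    scores <- rnorm(40)
    labels <- rep(c(0, 1), 20)
  })
  r <- roc_curve(scores, labels)
  rn <- roc_curve(-scores, labels)
  expect_equal(attr(rn, "auc"), 1 - attr(r, "auc"), tolerance = 1e-12)
  expect_true(all(r$fpr >= 0 & r$fpr <= 1 & r$tpr >= 0 & r$tpr <= 1))
})

test_that("label-independent scores give AUC near one half", {
  aucs <- vapply(1:100, function(s) {
    withr::with_seed(4000 + s, {
      scores <- rnorm(60)
      labels <- sample(rep(c(0, 1), 30))
    })
    attr(roc_curve(scores, labels), "auc")
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("trapezoid AUC equals the exhaustive pairwise-ranking oracle", {
  withr::with_seed(31, {
    for (trial in 1:20) {
      n <- sample(20:500, 1)
      y <- rep_len(c(0, 1), n)
      scores <- rnorm(n) + y * runif(1, 0, 2)
      # include ties in some trials
      if (trial %% 3 == 0) scores <- round(scores, 1)
      auc_pkg <- attr(roc_curve(scores, y), "auc")
      expect_equal(auc_pkg, auc_pairwise_oracle(scores, y),
                   tolerance = 1e-10)
    }
  })
})

test_that("package AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(32, {
    y <- rep(c(0, 1), 50)
    scores <- rnorm(100) + y
  })
  auc_pkg <- attr(roc_curve(scores, y), "auc")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                            direction = "<")))
  expect_equal(auc_pkg, auc_ref, tolerance = 1e-10)
})

test_that("the RBF-SVM separates separable blobs and flips with labels", {
  withr::with_seed(33, {
    X <- rbind(matrix(rnorm(30, -3), ncol = 2),
               matrix(rnorm(30, 3), ncol = 2))
    colnames(X) <- c("f1", "f2")
    y <- factor(rep(c("alert", "drowsy"), each = 15),
                levels = c("alert", "drowsy"))
  })
  fit <- train_svm_rbf(X, y, C = 100, gamma = 0.5)
  pred <- predict(fit, X)
  expect_equal(as.character(pred), as.character(y))   # 100% training accuracy

  flipped <- factor(ifelse(y == "alert", "drowsy", "alert"),
                    levels = c("alert", "drowsy"))
  fit2 <- train_svm_rbf(X, flipped, C = 100, gamma = 0.5)
  pred2 <- predict(fit2, X)
  expect_equal(as.character(pred2), as.character(flipped))

  expect_error(train_svm_rbf(X, factor(rep("drowsy", 30),
                                       levels = c("alert", "drowsy"))),
               class = "drowsy_error")
  expect_error(train_svm_rbf(X, y, C = -1), class = "drowsy_error")
})

test_that("a two-point problem puts the boundary at the midpoint", {
  X <- matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("f1", "f2")))
  y <- factor(c("alert", "drowsy"), levels = c("alert", "drowsy"))
  fit <- train_svm_rbf(X, y, C = 1000, gamma = 0.5)
  mid <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  p <- predict(fit, mid)
  expect_lt(abs(attr(p, "score")), 1e-6)   # equidistant: zero decision value
  # symmetric probes classify to their own side
  left <- predict(fit, matrix(c(-0.5, 0), 1, 2,
                              dimnames = list(NULL, c("f1", "f2"))))
  right <- predict(fit, matrix(c(0.5, 0), 1, 2,
                               dimnames = list(NULL, c("f1", "f2"))))
  expect_equal(as.character(left), "alert")
  expect_equal(as.character(right), "drowsy")
})

test_that("nested CV achieves high accuracy on separable synthetic data", {
  data <- synthetic_psd_dataset()
  cv <- nested_cv(data, grid = grid_spec(c(0, 4, 8), c(-6, -3, 0)),
                  outer_k = 5, inner_k = 3, seed = 9, select = TRUE)
  expect_gt(cv$metrics$accuracy, 90)
  expect_gt(cv$metrics$auc, 0.9)
  # fold bookkeeping: pooled counts = sum of fold counts, folds partition rows
  folds <- tidy(cv)
  expect_equal(sum(folds$tp + folds$fp + folds$fn + folds$tn),
               sum(folds$n_test))
  kept <- data[data$label != "excluded", ]
  expect_equal(sum(folds$n_test), nrow(kept))
  expect_setequal(cv$predictions$row, seq_len(nrow(kept)))
})

test_that("nested CV is deterministic given the seed", {
  data <- synthetic_psd_dataset()
  g <- grid_spec(c(2, 6), c(-4, -1))
  cv1 <- nested_cv(data, grid = g, outer_k = 4, inner_k = 3, seed = 21)
  cv2 <- nested_cv(data, grid = g, outer_k = 4, inner_k = 3, seed = 21)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("label permutation drives pooled accuracy to the base rate", {
  data <- synthetic_psd_dataset()
  kept <- data[data$label != "excluded", ]
  base_rate <- max(table(kept$label)) / nrow(kept)
  accs <- vapply(1:5, function(s) {
    perm <- data
    withr::with_seed(5000 + s, {
      idx <- which(perm$label != "excluded")
      perm$label[idx] <- sample(perm$label[idx])
    })
    cv <- nested_cv(perm, grid = grid_spec(c(0, 6), c(-5, -2)),
                    outer_k = 4, inner_k = 3, seed = s)
    cv$metrics$accuracy / 100
  }, numeric(1))
  # no leakage: permuted labels cannot beat the majority rate by much
  expect_lt(mean(accs), base_rate + 0.10)
})

test_that("a degenerate single-point grid reduces to plain k-fold CV", {
  data <- synthetic_psd_dataset()
  g1 <- grid_spec(3, -3)
  cv <- nested_cv(data, grid = g1, outer_k = 4, inner_k = 2, seed = 5)
  expect_true(all(cv$folds$C == 2^3))
  expect_true(all(cv$folds$gamma == 2^-3))
  expect_equal(dim(cv$grid_surface), c(1, 1))
})

test_that("LOSOCV builds one fold per subject and requires two subjects", {
  data <- synthetic_psd_dataset()
  three <- data[data$subject_id %in% c("S01", "S02", "S03"), ]
  cv <- losocv(three, grid = grid_spec(c(2, 6), c(-4, -1)), inner_k = 3,
               seed = 4)
  expect_equal(nrow(tidy(cv)), 3)
  expect_equal(cv$fold_by, "subject")

  one <- data[data$subject_id == "S01", ]
  expect_error(losocv(one, grid = grid_spec(2, -2), seed = 1),
               class = "drowsy_error")
})

test_that("subject-constant features fool record-wise CV but not LOSOCV", {
  # No class signal at all; each subject has a private offset feature and a
  # subject-correlated label. Window-level CV can exploit the offset,
  # leave-one-subject-out cannot.
  withr::with_seed(35, {
    n_sub <- 6; n_win <- 30
    offsets <- seq(-2.5, 2.5, length.out = n_sub)
    drowsy_sub <- rep(c(TRUE, FALSE), n_sub / 2)   # alternates along offsets
    tbl <- purrr::map_dfr(seq_len(n_sub), function(s) {
      tibble::tibble(
        recording_id = sprintf("S%d_r%d", s, seq_len(n_win)),
        subject_id = sprintf("S%d", s),
        window_index = 0L, kss = NA_integer_,
        offset_feat = offsets[s] + rnorm(n_win, sd = 0.05),
        label = factor(ifelse(drowsy_sub[s], "drowsy", "alert"),
                       levels = c("alert", "drowsy", "excluded"))
      )
    })
  })
  g <- grid_spec(c(0, 5), c(-3, 0))
  cv_window <- nested_cv(tbl, grid = g, outer_k = 4, inner_k = 3, seed = 2)
  cv_loso <- losocv(tbl, grid = g, inner_k = 3, seed = 2)
  expect_gt(cv_window$metrics$accuracy, 90)   # leakage via subject identity
  expect_lt(cv_loso$metrics$accuracy, 35)     # generalises at/below chance
})

test_that("drowsiness probabilities are window means with attainable ends", {
  expect_equal(drowsiness_probability(rep(1, 30)), 1)
  expect_equal(drowsiness_probability(rep(0, 30)), 0)
  expect_equal(drowsiness_probability(c(1, 0, 1, 0)), 0.5)
  expect_equal(drowsiness_probability(factor(c("drowsy", "alert"))), 0.5)
  expect_error(drowsiness_probability(numeric(0)), class = "drowsy_error")

  preds <- tibble::tibble(
    recording_id = rep(c("a", "b"), each = 4),
    pred = c("drowsy", "drowsy", "alert", "drowsy",
             "alert", "alert", "alert", "alert")
  )
  agg <- aggregate_probabilities(preds)
  expect_equal(agg$probability[agg$recording_id == "a"], 0.75)
  expect_equal(agg$probability[agg$recording_id == "b"], 0)
  expect_equal(agg$n_windows, c(4L, 4L))
})

test_that("condition comparison handles identical and shifted inputs", {
  same <- c(0.2, 0.5, 0.8, 0.4)
  r <- compare_conditions(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  shifted <- compare_conditions(same + 0.3, same)
  expect_equal(shifted$p_value, 0)
  expect_gt(shifted$statistic, 0)

  withr::with_seed(36, {
    a <- runif(20, 0.6, 1)
    b <- runif(20, 0, 0.4)
  })
  r2 <- compare_conditions(a, b)
  expect_gt(r2$mean_a, r2$mean_b)
  expect_lt(r2$p_value, 0.05)
  # agrees with the reference paired t-test
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r2$p_value, ref$p.value)
  expect_error(compare_conditions(1, 2), class = "drowsy_error")
})

test_that("grid surfaces are finite with a deterministic argmax tie-break", {
  data <- synthetic_psd_dataset()
  cv <- nested_cv(data, grid = grid_spec(c(1, 5), c(-4, -1)),
                  outer_k = 3, inner_k = 3, seed = 8)
  expect_true(all(is.finite(cv$grid_surface)))
  expect_true(all(cv$grid_surface >= 0 & cv$grid_surface <= 1))
  # chosen hyperparameters come from the grid
  expect_true(all(cv$folds$C %in% grid_spec(c(1, 5), c(-4, -1))$C))
  expect_true(all(cv$folds$gamma %in% grid_spec(c(1, 5), c(-4, -1))$gamma))
})
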