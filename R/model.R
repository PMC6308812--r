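#' Classification metric suite from confusion counts
#'
#' Drowsy is the positive class. Precision = TP/(TP+FP), sensitivity
#' (recall) = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, F-measure = harmonic mean of precision and recall. All
#' five are reported in percent; a metric whose denominator is zero is
#' flagged undefined (`NA`), never silently reported as 0.
#'
#' @param counts A [confusion_counts()].
#' @param auc Optional area under the ROC curve (fraction in `[0, 1]`).
#' @return A one-row tibble of class `metrics_report` with columns
#'   `precision`, `sensitivity`, `specificity`, `accuracy`, `f_measure`
#'   (percent) and `auc`; the counts travel along as an attribute.
#' @export
#'
#' @examples
#' compute_metrics(confusion_counts(tp = 477, fp = 172, fn = 61, tn = 142))
compute_metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0) {
    abort("Confusion counts sum to zero.", class = "drowsy_error")
  }
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- frac(counts$tp, counts$tp + counts$fp)
  sensitivity <- frac(counts$tp, counts$tp + counts$fn)
  specificity <- frac(counts$tn, counts$tn + counts$fp)
  accuracy <- (counts$tp + counts$tn) / total
  f_measure <- if (is.na(precision) || is.na(sensitivity) ||
                   precision + sensitivity == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  out <- tibble::tibble(
    precision = 100 * precision, sensitivity = 100 * sensitivity,
    specificity = 100 * specificity, accuracy = 100 * accuracy,
    f_measure = 100 * f_measure, auc = auc
  )
  structure(out, class = c("metrics_report", class(out)), counts = counts)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> (percent, drowsy = positive class)\n")
  vals <- vapply(c("precision", "sensitivity", "specificity", "accuracy",
                   "f_measure"),
                 function(m) x[[m]][1], numeric(1))
  for (m in names(vals)) {
    cat(sprintf("  %-12s %s\n", m,
                ifelse(is.na(vals[m]), "undefined", sprintf("%.1f", vals[m]))))
  }
  if (!is.na(x$auc[1])) cat(sprintf("  %-12s %.3f\n", "auc", x$auc[1]))
  invisible(x)
}

#' ROC curve and trapezoid AUC from decision scores
#'
#' Sweeps a threshold over the decision scores (prediction is drowsy when
#' `score >= threshold`) and records the false positive rate
#' (1 - specificity) against the true positive rate (sensitivity). The AUC
#' is the trapezoid integral over the sorted points.
#'
#' @param scores Numeric decision scores, larger = more drowsy.
#' @param labels Binary labels (factor or two-valued vector), drowsy
#'   positive.
#' @param thresholds Optional threshold grid; defaults to all distinct
#'   scores.
#' @return A tibble of class `drowsy_roc` with `threshold`, `fpr`, `tpr`;
#'   the AUC is in `attr(, "auc")`.
#' @export
roc_curve <- function(scores, labels, thresholds = NULL) {
  y <- label_to_numeric(labels)
  if (length(scores) != length(y)) {
    abort("`scores` and `labels` lengths differ.", class = "drowsy_error")
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present to trace a ROC curve.",
          class = "drowsy_error")
  }
  if (is.null(thresholds)) thresholds <- sort(unique(scores))
  thresholds <- c(-Inf, sort(thresholds), Inf)
  pts <- purrr::map_dfr(thresholds, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & y == 0) / n_neg,
                   tpr = sum(pred & y == 1) / n_pos)
  })
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  # integration runs from (1,1) down to (0,0); flip the sign convention
  auc <- abs(auc)
  structure(pts, class = c("drowsy_roc", class(pts)), auc = auc)
}

#' Hyperparameter grid for the RBF-SVM search
#'
#' The default grid steps both exponents by one: `C` over `2^-2 .. 2^11`
#' and `gamma` over `2^-10 .. 2^3`.
#'
#' @param c_exponents,gamma_exponents Integer exponent ranges (base 2).
#' @return A list of class `grid_spec` with sorted positive `C` and `gamma`
#'   vectors.
#' @export
grid_spec <- function(c_exponents = -2:11, gamma_exponents = -10:3) {
  C <- sort(2^c_exponents)
  gamma <- sort(2^gamma_exponents)
  if (length(C) == 0 || length(gamma) == 0 || any(C <= 0) || any(gamma <= 0)) {
    abort("Grid values must be positive and non-empty.", class = "drowsy_error")
  }
  structure(list(C = C, gamma = gamma), class = "grid_spec")
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    abort("Both classes must be present.", class = "drowsy_error")
  }
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Thin wrapper around the standard soft-margin support vector machine with
#' the radial basis kernel `K(x, x') = exp(-gamma * ||x - x'||^2)`. Feature
#' columns are taken as already scaled; no internal rescaling is applied.
#'
#' @param features Feature tibble (or numeric matrix).
#' @param labels Binary labels (factor or two-valued vector), one per row.
#' @param C Regularisation constant (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return An object of class `drowsy_svm`.
#' @export
train_svm_rbf <- function(features, labels, C = 1, gamma = 0.1) {
  if (C <= 0 || gamma <= 0) {
    abort("`C` and `gamma` must be positive.", class = "drowsy_error")
  }
  X <- if (is.matrix(features)) features
       else as.matrix(features[, feature_names(features), drop = FALSE])
  y <- factor(ifelse(label_to_numeric(labels) == 1, "drowsy", "alert"),
              levels = c("alert", "drowsy"))
  check_two_classes(y)
  fit <- e1071::svm(x = X, y = y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, features = colnames(X), C = C, gamma = gamma),
            class = "drowsy_svm")
}

#' @export
predict.drowsy_svm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else as.matrix(newdata[, object$features, drop = FALSE])
  raw <- predict(object$fit, X, decision.values = TRUE)
  dv <- drop(attr(raw, "decision.values"))
  side <- strsplit(colnames(attr(raw, "decision.values"))[1], "/")[[1]][1]
  score <- if (side == "drowsy") dv else -dv
  pred <- factor(as.character(raw), levels = c("alert", "drowsy"))
  attr(pred, "score") <- unname(score)
  pred
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

grouped_folds <- function(groups, k) {
  gs <- sample(unique(groups))
  gf <- setNames(rep_len(seq_len(k), length(gs)), gs)
  unname(gf[as.character(groups)])
}

count_confusion <- function(truth, pred) {
  confusion_counts(
    tp = sum(truth == "drowsy" & pred == "drowsy"),
    fp = sum(truth == "alert" & pred == "drowsy"),
    fn = sum(truth == "drowsy" & pred == "alert"),
    tn = sum(truth == "alert" & pred == "alert")
  )
}

# Inner grid search: pooled k-fold accuracy for every (C, gamma).
inner_grid_accuracy <- function(train_tbl, train_y, grid, inner_k, scale) {
  fold <- stratified_folds(train_y, inner_k)
  correct <- matrix(0, length(grid$C), length(grid$gamma))
  total <- 0
  feats <- feature_names(train_tbl)
  for (f in seq_len(inner_k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te) || length(unique(train_y[tr])) < 2) next
    tr_tbl <- train_tbl[tr, ]; te_tbl <- train_tbl[te, ]
    if (scale) {
      sc <- suppressWarnings(fit_robust_scaler(tr_tbl))
      tr_tbl <- suppressWarnings(apply_robust_scaler(tr_tbl, sc))
      te_tbl <- suppressWarnings(apply_robust_scaler(te_tbl, sc))
    }
    use <- intersect(feats, names(tr_tbl))
    Xtr <- as.matrix(tr_tbl[, use, drop = FALSE])
    Xte <- as.matrix(te_tbl[, use, drop = FALSE])
    ytr <- train_y[tr]
    total <- total + sum(te)
    for (ci in seq_along(grid$C)) {
      for (gi in seq_along(grid$gamma)) {
        fit <- e1071::svm(x = Xtr, y = ytr, kernel = "radial",
                          cost = grid$C[ci], gamma = grid$gamma[gi],
                          scale = FALSE)
        pred <- predict(fit, Xte)
        correct[ci, gi] <- correct[ci, gi] + sum(pred == train_y[te])
      }
    }
  }
  correct / total
}

#' Nested cross-validated RBF-SVM classification
#'
#' Outer folds estimate generalisation; inner folds, run on outer-training
#' rows only, pick `(C, gamma)` by grid search on pooled inner-fold
#' accuracy (ties resolved towards the smallest `C`, then the smallest
#' `gamma`). Robust scaling and (optionally) SWLDA feature selection are
#' refit inside each outer fold, so held-out rows never influence scaling,
#' selection, or the hyperparameter choice. Outer-test predictions are
#' accumulated into pooled confusion counts and a pooled ROC/AUC.
#'
#' @param data Labelled feature tibble ([extract_features()] +
#'   [label_windows()]); rows labelled `excluded` are dropped.
#' @param grid A [grid_spec()].
#' @param outer_k,inner_k Fold counts (ignored for `fold_by = "subject"`,
#'   where each subject is one outer fold).
#' @param seed Integer seed; fold draws are fully deterministic given it.
#' @param scale Fit and apply the robust scaler per fold (default `TRUE`).
#' @param select Run SWLDA per outer fold and train on the selected
#'   features only (default `FALSE`).
#' @param p_enter,p_remove SWLDA thresholds when `select = TRUE`.
#' @param fold_by `"window"` (replication default: windows assigned to
#'   folds individually, stratified by class), `"recording"` (all windows
#'   of a recording stay together) or `"subject"` (leave-one-subject-out).
#' @return An object of class `drowsy_cv`: per-fold results, pooled
#'   [confusion_counts()], a [compute_metrics()] report with AUC, pooled
#'   predictions, and the grid accuracy surface averaged over outer folds.
#' @export
nested_cv <- function(data, grid = grid_spec(), outer_k = 10, inner_k = 10,
                      seed = 1, scale = TRUE, select = FALSE,
                      p_enter = 0.1, p_remove = 0.15,
                      fold_by = c("window", "recording", "subject")) {
  fold_by <- match.arg(fold_by)
  if ("label" %in% names(data)) {
    data <- data[data$label != "excluded", , drop = FALSE]
    data$label <- droplevels(data$label)
  } else {
    abort("`data` must carry a `label` column (see label_windows()).",
          class = "drowsy_error")
  }
  y <- factor(ifelse(label_to_numeric(data$label) == 1, "drowsy", "alert"),
              levels = c("alert", "drowsy"))
  check_two_classes(y)
  feats <- feature_names(data)

  withr::with_seed(as.integer(seed), {
    if (fold_by == "window") {
      if (min(table(y)) < outer_k) {
        abort("Need at least `outer_k` rows per class.",
              class = "drowsy_error")
      }
      outer_fold <- stratified_folds(y, outer_k)
    } else if (fold_by == "recording") {
      outer_fold <- grouped_folds(data$recording_id, outer_k)
    } else {
      subjects <- unique(data$subject_id)
      if (length(subjects) < 2) {
        abort("Leave-one-subject-out needs at least 2 subjects.",
              class = "drowsy_error")
      }
      outer_k <- length(subjects)
      outer_fold <- match(data$subject_id, subjects)
    }

    fold_rows <- list()
    pred_rows <- list()
    surface <- matrix(0, length(grid$C), length(grid$gamma),
                      dimnames = list(paste0("C=", grid$C),
                                      paste0("gamma=", grid$gamma)))
    surface_n <- 0
    selected_per_fold <- list()

    for (f in sort(unique(outer_fold))) {
      te <- outer_fold == f
      tr <- !te
      if (!any(te)) next
      tr_tbl <- data[tr, ]; te_tbl <- data[te, ]
      ytr <- y[tr]; yte <- y[te]
      if (length(unique(ytr)) < 2) {
        abort(sprintf("Outer fold %d has a single-class training set.", f),
              class = "drowsy_error")
      }
      if (select) {
        keep <- feats[vapply(feats, function(fc)
          diff(range(tr_tbl[[fc]])) > 0, logical(1))]
        sel <- swlda_select(tr_tbl[, c("label", keep)], labels = ytr,
                            p_enter = p_enter, p_remove = p_remove)
        use_feats <- if (length(sel$selected) > 0) sel$selected else keep
        selected_per_fold[[as.character(f)]] <- sel$selected
        drop_cols <- setdiff(feats, use_feats)
        tr_tbl <- tr_tbl[, setdiff(names(tr_tbl), drop_cols)]
        te_tbl <- te_tbl[, setdiff(names(te_tbl), drop_cols)]
      }

      acc <- inner_grid_accuracy(tr_tbl, ytr, grid, inner_k, scale)
      surface <- surface + acc
      surface_n <- surface_n + 1
      # argmax with deterministic tie-break: smallest C, then smallest gamma
      best <- which(acc == max(acc, na.rm = TRUE), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
      C_best <- grid$C[best[1]]; g_best <- grid$gamma[best[2]]

      if (scale) {
        sc <- suppressWarnings(fit_robust_scaler(tr_tbl))
        tr_tbl <- suppressWarnings(apply_robust_scaler(tr_tbl, sc))
        te_tbl <- suppressWarnings(apply_robust_scaler(te_tbl, sc))
      }
      use <- intersect(feature_names(tr_tbl), names(tr_tbl))
      model <- train_svm_rbf(as.matrix(tr_tbl[, use, drop = FALSE]), ytr,
                             C = C_best, gamma = g_best)
      pred <- predict(model, as.matrix(te_tbl[, use, drop = FALSE]))
      cc <- count_confusion(yte, pred)
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        fold = f, C = C_best, gamma = g_best, tp = cc$tp, fp = cc$fp,
        fn = cc$fn, tn = cc$tn, n_test = sum(te)
      )
      score <- attr(pred, "score")
      pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
        row = which(te), fold = f, truth = as.character(yte),
        pred = as.character(pred), score = score
      )
    }

    folds <- dplyr::bind_rows(fold_rows)
    preds <- dplyr::bind_rows(pred_rows)
    pooled <- confusion_counts(sum(folds$tp), sum(folds$fp),
                               sum(folds$fn), sum(folds$tn))
    roc <- roc_curve(preds$score, preds$truth)
    metrics <- compute_metrics(pooled, auc = attr(roc, "auc"))
    structure(
      list(folds = folds, pooled = pooled, metrics = metrics,
           predictions = preds, roc = roc,
           grid_surface = surface / max(surface_n, 1),
           selected = selected_per_fold, seed = as.integer(seed),
           fold_by = fold_by),
      class = "drowsy_cv"
    )
  })
}

#' Leave-one-subject-out cross-validation
#'
#' Each outer fold holds out every window of one subject; hyperparameters
#' are still chosen by an inner grid search on the remaining subjects'
#' windows. This is the evaluation that reflects deployment on an unseen
#' person.
#'
#' @inheritParams nested_cv
#' @return A `drowsy_cv` (see [nested_cv()]).
#' @export
losocv <- function(data, grid = grid_spec(), inner_k = 10, seed = 1,
                   scale = TRUE, select = FALSE,
                   p_enter = 0.1, p_remove = 0.15) {
  nested_cv(data, grid = grid, inner_k = inner_k, seed = seed, scale = scale,
            select = select, p_enter = p_enter, p_remove = p_remove,
            fold_by = "subject")
}

#' @export
print.drowsy_cv <- function(x, ...) {
  cat(sprintf("<drowsy_cv> %s-level folds: %d outer fold(s), pooled n = %d\n",
              x$fold_by, nrow(x$folds),
              x$pooled$tp + x$pooled$fp + x$pooled$fn + x$pooled$tn))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.drowsy_cv <- function(x, ...) x$folds

#' @export
glance.drowsy_cv <- function(x, ...) {
  m <- tibble::as_tibble(x$metrics)
  m$n_folds <- nrow(x$folds)
  m$fold_by <- x$fold_by
  m
}

#' Per-recording drowsiness probability
#'
#' The mean of the binary window-level classifier outputs for one
#' recording: 1 when every window was called drowsy, 0 when none was.
#'
#' @param window_predictions Binary vector (0/1, logical, or alert/drowsy
#'   factor) of per-window outputs for one recording.
#' @return A fraction in `[0, 1]`.
#' @export
#'
#' @examples
#' drowsiness_probability(c(1, 0, 1, 0))
drowsiness_probability <- function(window_predictions) {
  if (length(window_predictions) == 0) {
    abort("Need at least one window prediction.", class = "drowsy_error")
  }
  if (is.factor(window_predictions) || is.character(window_predictions)) {
    window_predictions <- as.character(window_predictions) == "drowsy"
  }
  mean(as.numeric(window_predictions))
}

#' Aggregate window predictions into per-recording probabilities
#'
#' @param predictions A tibble with `recording_id` and a `pred` column of
#'   window-level outputs.
#' @return A tibble with `recording_id`, `n_windows`, `probability`.
#' @export
aggregate_probabilities <- function(predictions) {
  stopifnot(all(c("recording_id", "pred") %in% names(predictions)))
  predictions |>
    dplyr::group_by(.data$recording_id) |>
    dplyr::summarise(
      n_windows = dplyr::n(),
      probability = drowsiness_probability(.data$pred),
      .groups = "drop"
    )
}

#' Compare drowsiness probabilities between two conditions
#'
#' Paired two-sample t-test on per-subject probabilities (every subject
#' completes both conditions in the practical protocol); an unpaired
#' variant is available.
#'
#' @param probs_a,probs_b Probabilities for conditions A and B, aligned by
#'   subject when `paired = TRUE`.
#' @param paired Use the paired test (default `TRUE`).
#' @return A one-row tibble: `mean_a`, `mean_b`, `statistic`, `p_value`.
#' @export
compare_conditions <- function(probs_a, probs_b, paired = TRUE) {
  if (length(probs_a) < 2 || length(probs_b) < 2) {
    abort("Need at least 2 values per condition.", class = "drowsy_error")
  }
  if (paired && length(probs_a) != length(probs_b)) {
    abort("Paired comparison needs equal-length conditions.",
          class = "drowsy_error")
  }
  if (paired && sd(probs_a - probs_b) < 1e-12) {
    d <- mean(probs_a - probs_b)
    if (abs(d) < 1e-12) {
      return(tibble::tibble(mean_a = mean(probs_a), mean_b = mean(probs_b),
                            statistic = 0, p_value = 1))
    }
    return(tibble::tibble(mean_a = mean(probs_a), mean_b = mean(probs_b),
                          statistic = Inf * sign(d), p_value = 0))
  }
  tt <- t.test(probs_a, probs_b, paired = paired)
  tibble::tibble(mean_a = mean(probs_a), mean_b = mean(probs_b),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value)
}
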