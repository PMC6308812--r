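# Step-wise linear discriminant analysis, in the stepwise-regression form
# standard in the BCI literature: ordinary least squares of a 0/1 class
# label on the features, with partial-F entry and removal tests.

design_rss <- function(X, y) {
  qr_x <- qr(cbind(`(Intercept)` = 1, X))
  res <- qr.resid(qr_x, y)
  list(rss = sum(res^2), rank = qr_x$rank)
}

label_to_numeric <- function(labels) {
  if (is.factor(labels)) labels <- as.character(droplevels(labels))
  u <- sort(unique(labels))
  if (length(u) != 2) {
    abort("Labels must contain exactly two classes.", class = "drowsy_error")
  }
  positive <- if ("drowsy" %in% u) "drowsy" else u[2]
  as.numeric(labels == positive)
}

#' Partial-F p-value for adding a feature to a linear model
#'
#' Compares the residual sum of squares of the 0/1-label regression with and
#' without the candidate feature; the statistic is referred to an
#' `F(1, n - k - 2)` distribution, `k` being the size of the current model.
#' Returns `NA` when the candidate is collinear with the current model
#' (its entry does not increase the design rank).
#'
#' @param current Character vector of feature names already in the model
#'   (may be empty).
#' @param candidate Name of the candidate feature.
#' @param features Feature tibble (only feature columns are used).
#' @param labels Binary labels (factor or two-valued vector), one per row.
#' @return The p-value, or `NA_real_` for a collinear candidate.
#' @export
partial_f_pvalue <- function(current, candidate, features, labels) {
  y <- label_to_numeric(labels)
  n <- length(y)
  X0 <- as.matrix(features[, current, drop = FALSE])
  X1 <- as.matrix(features[, c(current, candidate), drop = FALSE])
  f0 <- design_rss(X0, y)
  f1 <- design_rss(X1, y)
  if (f1$rank <= f0$rank) return(NA_real_)
  df2 <- n - f1$rank
  if (df2 <= 0) return(NA_real_)
  if (f1$rss <= .Machine$double.eps * n) return(0)
  f_stat <- (f0$rss - f1$rss) / (f1$rss / df2)
  pf(f_stat, 1, df2, lower.tail = FALSE)
}

removal_pvalue <- function(feature, model, X, y) {
  f1 <- design_rss(X[, model, drop = FALSE], y)
  f0 <- design_rss(X[, setdiff(model, feature), drop = FALSE], y)
  df2 <- length(y) - f1$rank
  if (df2 <= 0) return(NA_real_)
  if (f1$rss <= .Machine$double.eps * length(y)) return(0)
  f_stat <- (f0$rss - f1$rss) / (f1$rss / df2)
  pf(f_stat, 1, df2, lower.tail = FALSE)
}

#' Step-wise feature selection (SWLDA)
#'
#' Alternates forward and backward steps: at each forward step the candidate
#' with the smallest partial-F p-value enters if `p < p_enter`; after every
#' entry, included features whose partial-F p-value has risen above
#' `p_remove` are removed (largest first). Ties on equal p-values are broken
#' by feature-name order, so the result does not depend on row or column
#' order. Terminates when no candidate can enter, when a model state
#' repeats, or after `max_steps` actions.
#'
#' @param features Feature tibble; feature columns are taken from
#'   [feature_names()] (metadata columns are ignored). Alternatively any
#'   data frame of numeric columns.
#' @param labels Binary labels, one per row; defaults to the table's
#'   `label` column.
#' @param p_enter Entry threshold on the partial-F p-value (default 0.1).
#' @param p_remove Removal threshold (default 0.15; must exceed `p_enter`).
#' @param max_steps Cap on add/remove actions (default `2 * n_features`).
#' @return An object of class `swlda_result`: `selected` (ordered feature
#'   names), `step_log` (tibble of step, action, feature, p_value), and the
#'   thresholds.
#' @export
swlda_select <- function(features, labels = features$label,
                         p_enter = 0.1, p_remove = 0.15, max_steps = NULL) {
  if (p_enter >= p_remove) {
    abort("`p_enter` must be smaller than `p_remove`.", class = "drowsy_error")
  }
  feats <- sort(feature_names(features))
  if (length(feats) == 0) {
    abort("No feature columns found.", class = "drowsy_error")
  }
  y <- label_to_numeric(labels)
  X <- as.matrix(features[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    abort(sprintf("Constant feature(s) must be filtered first: %s",
                  paste(feats[const], collapse = ", ")),
          class = "drowsy_error")
  }
  if (is.null(max_steps)) max_steps <- 2L * length(feats)
  if (max_steps < 1) abort("`max_steps` must be >= 1.", class = "drowsy_error")

  model <- character(0)
  log_rows <- list()
  seen_states <- character(0)
  step <- 0L
  Xdf <- tibble::as_tibble(as.data.frame(X))

  repeat {
    if (step >= max_steps) break
    candidates <- setdiff(feats, model)
    if (length(candidates) == 0) break
    pvals <- vapply(candidates, function(f) {
      partial_f_pvalue(model, f, Xdf, y)
    }, numeric(1))
    skipped <- candidates[is.na(pvals)]
    for (f in skipped) {
      step <- step + 1L
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(step = step, action = "skip", feature = f,
                       p_value = NA_real_)
    }
    ok <- !is.na(pvals)
    if (!any(ok) || min(pvals[ok]) >= p_enter) break
    best <- candidates[ok][which.min(pvals[ok])]   # ties: first in name order
    model <- c(model, best)
    step <- step + 1L
    log_rows[[length(log_rows) + 1L]] <-
      tibble::tibble(step = step, action = "add", feature = best,
                     p_value = min(pvals[ok]))

    # backward sweep
    repeat {
      if (length(model) == 0 || step >= max_steps) break
      rem_p <- vapply(sort(model), function(f) {
        removal_pvalue(f, model, X, y)
      }, numeric(1))
      worst_p <- suppressWarnings(max(rem_p, na.rm = TRUE))
      if (!is.finite(worst_p) || worst_p <= p_remove) break
      worst <- names(rem_p)[which.max(rem_p)]
      model <- setdiff(model, worst)
      step <- step + 1L
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(step = step, action = "remove", feature = worst,
                       p_value = worst_p)
    }

    state <- paste(sort(model), collapse = "|")
    if (state %in% seen_states) break   # cycle guard
    seen_states <- c(seen_states, state)
  }

  structure(
    list(selected = model,
         step_log = if (length(log_rows) > 0) dplyr::bind_rows(log_rows)
                    else tibble::tibble(step = integer(), action = character(),
                                        feature = character(),
                                        p_value = numeric()),
         p_enter = p_enter, p_remove = p_remove),
    class = "swlda_result"
  )
}

#' @export
print.swlda_result <- function(x, ...) {
  cat(sprintf("<swlda_result> %d feature(s) selected in %d step(s)\n",
              length(x$selected), nrow(x$step_log)))
  if (length(x$selected) > 0) {
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.swlda_result <- function(x, ...) x$step_log

#' @export
glance.swlda_result <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_steps = nrow(x$step_log),
                 p_enter = x$p_enter, p_remove = x$p_remove)
}
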