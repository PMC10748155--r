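#' @title Evaluation statistics
#' @description
#' ROC/AUC, bootstrap resampling of classification metrics, ANOVA with
#' Tukey-Kramer post-hoc comparison across models, and top-3 model
#' selection. AUC is the tie-aware rank statistic
#' P(score+ > score-) + 0.5 P(score+ = score-); bootstrap resampling is at
#' patient level with replacement (degenerate single-class resamples are
#' redrawn), default 2000 resamples.
#' @name evaluation-stats
NULL

#' Area under the ROC curve
#'
#' @param scores numeric anomaly scores.
#' @param labels binary labels (logical or 0/1); both classes required.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stopf("roc_auc needs both classes")
  r <- rank(scores)                 # average ranks handle ties at 0.5
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Thresholded classification metrics
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold operating point on the probability scale (0.5).
#' @return named vector: `f1`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  c(f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Bootstrap distribution of AUC, F1, sensitivity and specificity
#'
#' Patients are resampled with replacement `B` times; resamples missing a
#' class are redrawn.
#'
#' @param scores,labels record-level scores and binary labels.
#' @param B number of resamples (2000).
#' @param seed RNG seed for the resample indices.
#' @param threshold operating point for the thresholded metrics.
#' @param model optional model name carried into reports.
#' @return object of class `bootstrap_report`: `samples` (B x 4 matrix),
#'   `mean`, `sd`, `B`, `model`.
#' @export
bootstrap_metrics <- function(scores, labels, B = 2000L, seed = 1L,
                              threshold = 0.5, model = "model") {
  labels <- as.logical(labels)
  B <- as.integer(B)
  if (B < 1) stopf("B must be >= 1")
  if (sum(labels) == 0 || sum(!labels) == 0)
    stopf("bootstrap_metrics needs both classes")
  n <- length(scores)
  samples <- with_seed(seed, {
    out <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, c("auc", "f1", "sensitivity",
                                          "specificity")))
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(labels[idx]) && any(!labels[idx])) break
      }
      out[b, ] <- c(roc_auc(scores[idx], labels[idx]),
                    threshold_metrics(scores[idx], labels[idx], threshold))
    }
    out
  })
  structure(list(samples = samples,
                 mean = colMeans(samples),
                 sd = if (B > 1) apply(samples, 2, sd)
                      else stats::setNames(numeric(4), colnames(samples)),
                 B = B, threshold = threshold, model = model),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report> %s (B = %d)\n", x$model, x$B))
  for (m in colnames(x$samples))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Compare bootstrapped models by ANOVA and Tukey-Kramer HSD
#'
#' One-way ANOVA over the bootstrapped AUC vectors of two or more models,
#' followed by all-pairs Tukey-Kramer comparisons at level `alpha`. Note
#' the bootstrap resamples of one model are not independent draws; the
#' procedure mirrors the reference analysis rather than a fresh-sample
#' design.
#'
#' @param reports named list of `bootstrap_report`s with equal `B`.
#' @param alpha family-wise significance level (0.05).
#' @param metric which bootstrapped metric to compare (`"auc"`).
#' @return object of class `comparison_result`: `anova` (F statistic and
#'   p value), `pairwise` data frame (pair, difference, CI, adjusted p,
#'   `different`), `ranking` (models by mean AUC), `top3`.
#' @export
compare_models <- function(reports, alpha = 0.05, metric = "auc") {
  if (length(reports) < 2) stopf("need at least two models to compare")
  Bs <- vapply(reports, function(r) r$B, integer(1))
  if (length(unique(Bs)) != 1) stopf("mismatched B across models")
  nm <- names(reports) %||% paste0("model", seq_along(reports))
  values <- unlist(lapply(reports, function(r) r$samples[, metric]),
                   use.names = FALSE)
  group <- factor(rep(nm, each = Bs[1]), levels = nm)
  fit <- aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         different = tk[, "p adj"] < alpha,
                         row.names = NULL)
  means_auc <- vapply(reports, function(r) r$mean[["auc"]], numeric(1))
  means_f1 <- vapply(reports, function(r) r$mean[["f1"]], numeric(1))
  ord <- order(-means_auc, -means_f1)
  ranking <- data.frame(model = nm[ord], mean_auc = means_auc[ord],
                        mean_f1 = means_f1[ord], row.names = NULL)
  structure(list(
    anova = list(statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1]),
    pairwise = pairwise, ranking = ranking,
    top3 = head(ranking$model, 3L), alpha = alpha, metric = metric),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> ANOVA F = %.2f (p = %.3g); top 3: %s\n",
              x$anova$statistic, x$anova$p_value,
              paste(x$top3, collapse = ", ")))
  invisible(x)
}

#' Select the top-3 methods from a methods-by-folds evaluation grid
#'
#' For each method, the fold with the highest test AUC survives; survivors
#' are ranked by test AUC. Ties break by the documented method order (the
#' order of first appearance in `grid$method`), then by fold index.
#'
#' @param grid data frame with columns `method`, `fold`, `test_auc`
#'   covering every (method, fold) cell.
#' @param n_top how many methods to return (3).
#' @return list: `survivors` (one row per method: method, fold, test_auc,
#'   ranked) and `top` (the first `n_top` rows).
#' @export
select_models <- function(grid, n_top = 3L) {
  need <- c("method", "fold", "test_auc")
  if (!all(need %in% names(grid))) stopf("grid needs columns %s",
                                         paste(need, collapse = ", "))
  methods <- unique(grid$method)
  folds <- sort(unique(grid$fold))
  full <- expand.grid(method = methods, fold = folds, stringsAsFactors = FALSE)
  key <- function(d) paste(d$method, d$fold)
  missing <- setdiff(key(full), key(grid))
  if (length(missing)) stopf("missing evaluation cells: %s",
                             paste(missing, collapse = "; "))
  surv <- do.call(rbind, lapply(methods, function(m) {
    g <- grid[grid$method == m, ]
    g <- g[order(-g$test_auc, g$fold), ]
    g[1, need]
  }))
  surv$method_rank <- match(surv$method, methods)
  surv <- surv[order(-surv$test_auc, surv$method_rank), ]
  surv$method_rank <- NULL
  rownames(surv) <- NULL
  list(survivors = surv, top = head(surv, n_top))
}

#' Format bootstrap reports like the reference result tables
#'
#' @param reports named list of `bootstrap_report`s.
#' @return data frame with columns Model, AUC, F1, Sensitivity,
#'   Specificity, each metric printed as `mean +/- sd`.
#' @export
format_bootstrap_reports <- function(reports) {
  fmt <- function(r, m) sprintf("%.3f ± %.3f", r$mean[[m]], r$sd[[m]])
  data.frame(
    Model = vapply(reports, function(r) r$model, character(1)),
    AUC = vapply(reports, fmt, character(1), m = "auc"),
    F1 = vapply(reports, fmt, character(1), m = "f1"),
    Sensitivity = vapply(reports, fmt, character(1), m = "sensitivity"),
    Specificity = vapply(reports, fmt, character(1), m = "specificity"),
    row.names = NULL)
}
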