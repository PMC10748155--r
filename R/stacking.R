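#' @title Probability fusion by stacked tree ensembles
#' @description
#' Record-level anomaly probabilities from the six single-modal CNNs
#' (three auscultation sites, three ECG views) are joined into per-patient
#' feature rows under one of four stacking patterns and fed to a
#' meta-learner: a random forest or a gradient-boosted tree ensemble.
#' Hyperparameters are chosen by exhaustive grid search maximizing the F1
#' score on the development split (probability cut at 0.5; ties resolved by
#' grid order), and per-source importances (mean impurity decrease for the
#' forest, total gain for the boosted learner) are normalized to sum to 1.
#' @name fusion-stacking
NULL

#' The six single-modal probability sources
#' @export
STACK_SOURCES <- c("PCG-2RSB", "PCG-ERB", "PCG-APX",
                   "ECG-all12", "ECG-limb", "ECG-precordial")

#' The four stacking patterns
#'
#' @return named list mapping pattern name to its enabled sources:
#'   `PCG3ch+ECG2pt` (3 heart sounds + limb + precordial, 5 features),
#'   `PCG3ch+ECG1pt` (3 heart sounds + the 12-lead page, 4), `PCG3ch` (3),
#'   `ECG2pt` (limb + precordial, 2).
#' @export
stacking_patterns <- function() {
  list(
    "PCG3ch+ECG2pt" = c("PCG-2RSB", "PCG-ERB", "PCG-APX",
                        "ECG-limb", "ECG-precordial"),
    "PCG3ch+ECG1pt" = c("PCG-2RSB", "PCG-ERB", "PCG-APX", "ECG-all12"),
    "PCG3ch" = c("PCG-2RSB", "PCG-ERB", "PCG-APX"),
    "ECG2pt" = c("ECG-limb", "ECG-precordial"))
}

#' Build a prediction table row block
#'
#' @param patient_id,source,probability equal-length vectors; probabilities
#'   must lie in [0, 1].
#' @return data frame of class `prediction_table`.
#' @export
prediction_table <- function(patient_id, source, probability) {
  if (any(probability < 0 | probability > 1))
    stopf("probabilities must lie in [0, 1]")
  bad <- setdiff(unique(source), STACK_SOURCES)
  if (length(bad)) stopf("unknown source(s): %s", paste(bad, collapse = ", "))
  out <- data.frame(patient_id = patient_id, source = source,
                    probability = probability, stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", class(out))
  out
}

#' Assemble the stacking feature matrix for a pattern
#'
#' One row per patient, columns in the pattern's documented source order.
#'
#' @param table a `prediction_table` (long format: patient_id, source,
#'   probability).
#' @param pattern a pattern name from [stacking_patterns()] or a character
#'   vector of sources.
#' @param labels optional named logical/0-1 vector of patient targets.
#' @return list with `x` (patients x sources matrix), `patient_id`, and
#'   `y` (if labels were given).
#' @export
assemble_features <- function(table, pattern, labels = NULL) {
  sources <- if (length(pattern) == 1 && pattern %in% names(stacking_patterns()))
    stacking_patterns()[[pattern]] else pattern
  bad <- setdiff(sources, STACK_SOURCES)
  if (length(bad)) stopf("unknown source(s): %s", paste(bad, collapse = ", "))
  ids <- unique(table$patient_id)
  x <- matrix(NA_real_, length(ids), length(sources),
              dimnames = list(ids, sources))
  for (s in sources) {
    rows <- table[table$source == s, ]
    x[match(rows$patient_id, ids), s] <- rows$probability
  }
  if (anyNA(x)) {
    miss <- which(is.na(x), arr.ind = TRUE)
    stopf("missing source %s for patient %s",
          colnames(x)[miss[1, 2]], rownames(x)[miss[1, 1]])
  }
  out <- list(x = x, patient_id = ids)
  if (!is.null(labels)) out$y <- as.integer(as.logical(labels[ids]))
  out
}

#' Meta-learner specification
#'
#' @param learner `"rf"` (random forest) or `"xgb"` (gradient-boosted
#'   trees).
#' @param grid data frame of hyperparameter combinations searched in row
#'   order; `NULL` selects the default grid (forest: 100/300 trees x depth
#'   3/5/unlimited; boosted: 100/300 rounds x depth 2/3 x learning rate
#'   0.1/0.3).
#' @param seed RNG seed for the fits.
#' @param threshold probability cut used when scoring F1 during the grid
#'   search.
#' @return list of class `stacker_spec`.
#' @export
stacker_spec <- function(learner = "rf", grid = NULL, seed = 1L,
                         threshold = 0.5) {
  learner <- match_one(learner, c("rf", "xgb"), "learner")
  grid <- grid %||% switch(learner,
    rf = expand.grid(n_trees = c(100L, 300L), max_depth = c(3L, 5L, 0L)),
    xgb = expand.grid(n_rounds = c(100L, 300L), max_depth = c(2L, 3L),
                      learning_rate = c(0.1, 0.3)))
  if (nrow(grid) == 0) stopf("grid must be non-empty")
  structure(list(learner = learner, grid = grid, seed = as.integer(seed),
                 threshold = threshold),
            class = "stacker_spec")
}

fit_learner <- function(x, y, learner, params, seed) {
  with_seed(seed, {
    if (learner == "rf") {
      forest_fit(x, as.integer(y), n_trees = params$n_trees,
                 max_depth = params$max_depth,
                 mtry = max(1L, floor(sqrt(ncol(x)))), min_split = 2L)
    } else {
      gbt_fit(x, as.integer(y), n_rounds = params$n_rounds,
              max_depth = params$max_depth,
              learning_rate = params$learning_rate, lambda = 1,
              subsample = 1, min_child_weight = 1e-3)
    }
  })
}

#' Fit a stacking meta-learner with grid search
#'
#' Every grid row is fit on the training features and scored by F1 on the
#' development features; the first row attaining the maximal development F1
#' wins and is refit on the training data.
#'
#' @param x,y training feature matrix (per-patient probabilities) and
#'   binary labels; both classes must be present.
#' @param spec a `stacker_spec`.
#' @param x_dev,y_dev development split used for grid scoring.
#' @return object of class `stacker_fit`: `model`, `learner`, `params`
#'   (chosen row), `dev_f1`, `grid_results`, `sources`.
#' @export
fit_stacker <- function(x, y, spec, x_dev, y_dev) {
  y <- as.integer(as.logical(y))
  if (sum(y) == 0 || sum(1 - y) == 0)
    stopf("stacker training labels must contain both classes")
  scores <- numeric(nrow(spec$grid))
  for (i in seq_len(nrow(spec$grid))) {
    fit <- fit_learner(x, y, spec$learner, as.list(spec$grid[i, , drop = FALSE]),
                       spec$seed)
    p <- predict_learner(fit, spec$learner, x_dev)
    scores[i] <- threshold_metrics(p, y_dev, spec$threshold)[["f1"]]
  }
  best <- which.max(scores)          # first index on ties
  params <- as.list(spec$grid[best, , drop = FALSE])
  model <- fit_learner(x, y, spec$learner, params, spec$seed)
  structure(list(model = model, learner = spec$learner, params = params,
                 dev_f1 = scores[best],
                 grid_results = cbind(spec$grid, dev_f1 = scores),
                 sources = colnames(x), seed = spec$seed),
            class = "stacker_fit")
}

predict_learner <- function(model, learner, x) {
  if (learner == "rf") forest_predict_prob(model, x)
  else gbt_predict_prob(model, x)
}

#' @export
#' @param object a `stacker_fit`.
#' @param newdata feature matrix with the fit's source columns.
#' @param ... unused.
#' @rdname fit_stacker
predict.stacker_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && all(object$sources %in% colnames(newdata)))
    newdata <- newdata[, object$sources, drop = FALSE]
  predict_learner(object$model, object$learner, newdata)
}

#' Normalized per-source importances of a fitted meta-learner
#'
#' Mean impurity decrease (forest) or total split gain (boosted trees),
#' rescaled to sum to 1. If no split was ever made (degenerate data) the
#' mass is spread uniformly.
#'
#' @param fit a `stacker_fit`.
#' @return named nonnegative vector over the fit's sources, summing to 1.
#' @export
stacker_importances <- function(fit) {
  if (!inherits(fit, "stacker_fit")) stopf("not a fitted stacker")
  imp <- as.numeric(fit$model$importance)
  names(imp) <- fit$sources
  s <- sum(imp)
  if (s <= 0) rep(1 / length(imp), length(imp)) |> stats::setNames(fit$sources)
  else imp / s
}
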