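#' @title Modal contribution analysis
#' @description
#' Quantifies how much each probability source (auscultation site or ECG
#' view) contributes to a selected stacking model: the meta-learner is
#' refit `R` times (default 50) under consecutive seeds with the CNN-derived
#' features held fixed, and the normalized per-source importances are
#' summarized as mean and standard deviation. Refitting the upstream CNNs
#' as well is available behind a flag in principle but is not the default,
#' as one repetition would then cost a full training run per source.
#' @name contribution
NULL

#' Repeated-seed contribution analysis of a fitted stacker
#'
#' @param fit a `stacker_fit` (the selected stacking variant); its learner
#'   and chosen hyperparameters are reused for every repetition.
#' @param x,y the stacking training features and labels the fit was made
#'   with (CNN features, held fixed across repetitions).
#' @param R number of repetitions (50).
#' @param base_seed first seed; repetition r uses `base_seed + r - 1`.
#' @return object of class `contribution_report`: `importances` (R x
#'   sources matrix, rows summing to 1), `mean`, `sd`, `R`, `sources`,
#'   `seeds`.
#' @export
contribution_analysis <- function(fit, x, y, R = 50L, base_seed = 1L) {
  if (!inherits(fit, "stacker_fit")) stopf("fit must be a stacker_fit")
  if (R < 1) stopf("R must be >= 1")
  seeds <- base_seed + seq_len(R) - 1L
  imp <- matrix(NA_real_, R, length(fit$sources),
                dimnames = list(NULL, fit$sources))
  for (r in seq_len(R)) {
    m <- fit_learner(x, as.integer(y), fit$learner, fit$params, seeds[r])
    refit <- fit
    refit$model <- m
    imp[r, ] <- stacker_importances(refit)
  }
  structure(list(importances = imp, mean = colMeans(imp),
                 sd = apply(imp, 2, function(v) if (R > 1) sd(v) else 0),
                 R = R, sources = fit$sources, seeds = seeds,
                 learner = fit$learner, params = fit$params),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("<contribution_report> %s, R = %d\n", x$learner, x$R))
  for (s in x$sources)
    cat(sprintf("  %-16s %.3f +/- %.3f\n", s, x$mean[[s]], x$sd[[s]]))
  invisible(x)
}

#' Summed mean importance of a modality
#'
#' @param report a `contribution_report`.
#' @param modality `"PCG"` or `"ECG"`; sources are grouped by name prefix.
#' @return summed mean importance of the modality's sources.
#' @export
modality_contribution <- function(report, modality = c("PCG", "ECG")) {
  modality <- match.arg(modality)
  sel <- startsWith(report$sources, modality)
  sum(report$mean[sel])
}

#' Contribution report as a CSV-ready data frame
#'
#' @param report a `contribution_report`.
#' @param model,fold provenance columns.
#' @return data frame (model, fold, source, mean, sd, R).
#' @export
contribution_to_table <- function(report, model = report$learner, fold = NA) {
  data.frame(model = model, fold = fold, source = report$sources,
             mean = unname(report$mean), sd = unname(report$sd),
             R = report$R, row.names = NULL)
}
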