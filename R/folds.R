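#' @title Modified stratified 4-fold cross-validation
#' @description
#' The dataset is split into a single test set shared by all folds and four
#' disjoint development blocks over the remaining patients; fold k trains
#' on the three blocks not used as its development set. Sampling is
#' stratified jointly on the three severity grades so every split carries
#' approximately the cohort's grade mix.
#' @name cv-orchestrator
NULL

#' Build the fold assignment
#'
#' @param cohort a `cohort_manifest` (or its `$patients` data frame).
#' @param test_fraction fraction of patients in the shared test set (0.2).
#' @param seed RNG seed; the assignment is deterministic per seed.
#' @param n_folds number of train/development groups (4).
#' @param tolerance optional maximal absolute deviation of any per-disease
#'   severe-share in any split from the cohort share; violations raise an
#'   error naming the stratum unless `relax = TRUE`.
#' @param relax if `TRUE`, tolerance violations only warn.
#' @return object of class `fold_assignment`: `test_ids`, `folds` (list of
#'   `list(train_ids, dev_ids)`), `n_folds`, `stratum` (per-patient joint
#'   grade key).
#' @export
make_folds <- function(cohort, test_fraction = 0.2, seed = 1L, n_folds = 4L,
                       tolerance = NULL, relax = FALSE) {
  pts <- if (inherits(cohort, "cohort_manifest")) cohort$patients else cohort
  ids <- pts$patient_id
  stratum <- paste(pts$as_grade, pts$mr_grade, pts$lvd_grade, sep = "/")
  test_ids <- character(0)
  dev_blocks <- vector("list", n_folds)
  with_seed(seed, {
    rr <- 0L  # global round-robin cursor keeps dev blocks balanced
    for (s in unique(stratum)) {
      sid <- sample(ids[stratum == s])
      nt <- round(test_fraction * length(sid))
      test_ids <- c(test_ids, sid[seq_len(nt)])
      rest <- sid[setdiff(seq_along(sid), seq_len(nt))]
      for (id in rest) {
        k <- (rr %% n_folds) + 1L
        dev_blocks[[k]] <- c(dev_blocks[[k]], id)
        rr <- rr + 1L
      }
    }
  })
  nontest <- setdiff(ids, test_ids)
  folds <- lapply(seq_len(n_folds), function(k)
    list(train_ids = setdiff(nontest, dev_blocks[[k]]),
         dev_ids = dev_blocks[[k]]))
  fa <- structure(list(test_ids = test_ids, folds = folds,
                       n_folds = n_folds,
                       stratum = stats::setNames(stratum, ids)),
                  class = "fold_assignment")
  if (!is.null(tolerance)) check_fold_balance(fa, pts, tolerance, relax)
  fa
}

check_fold_balance <- function(fa, pts, tolerance, relax) {
  targets <- c(AS = "as_target", MR = "mr_target", LVD = "lvd_target")
  splits <- c(list(test = fa$test_ids),
              stats::setNames(lapply(fa$folds, `[[`, "dev_ids"),
                              paste0("dev", seq_len(fa$n_folds))),
              stats::setNames(lapply(fa$folds, `[[`, "train_ids"),
                              paste0("train", seq_len(fa$n_folds))))
  for (d in names(targets)) {
    overall <- mean(pts[[targets[[d]]]])
    for (sp in names(splits)) {
      share <- mean(pts[[targets[[d]]]][pts$patient_id %in% splits[[sp]]])
      if (abs(share - overall) > tolerance) {
        msg <- sprintf(
          "stratum 'severe %s' share in %s (%.3f) deviates from cohort (%.3f) by more than %.3f",
          d, sp, share, overall, tolerance)
        if (relax) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Tag a cohort manifest with a fold's split labels
#'
#' @param cohort a `cohort_manifest`.
#' @param fa a `fold_assignment`.
#' @param fold fold index whose train/dev labels to apply.
#' @return the cohort with `split` ("train"/"dev"/"test") and `fold` filled.
#' @export
apply_fold <- function(cohort, fa, fold) {
  pts <- cohort$patients
  pts$split <- NA_character_
  pts$split[pts$patient_id %in% fa$test_ids] <- "test"
  pts$split[pts$patient_id %in% fa$folds[[fold]]$train_ids] <- "train"
  pts$split[pts$patient_id %in% fa$folds[[fold]]$dev_ids] <- "dev"
  pts$fold <- fold
  cohort$patients <- pts
  cohort
}

#' Fold assignment as a data frame (CSV-ready)
#'
#' @param fa a `fold_assignment`.
#' @return data frame: patient_id, split per fold (`fold1`..`foldK`
#'   columns with train/dev, or "test").
#' @export
folds_to_table <- function(fa) {
  ids <- c(fa$test_ids, fa$folds[[1]]$train_ids, fa$folds[[1]]$dev_ids)
  ids <- sort(ids)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(fa$n_folds)) {
    lab <- rep("test", length(ids))
    lab[ids %in% fa$folds[[k]]$train_ids] <- "train"
    lab[ids %in% fa$folds[[k]]$dev_ids] <- "dev"
    out[[paste0("fold", k)]] <- lab
  }
  out
}
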