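#' @title Experiment orchestration
#' @description
#' Drives the full screening experiment for one target disease: per fold,
#' six single-modal CNNs (three auscultation sites, three ECG views) are
#' trained on the fold's training split with augmentation and checkpointed
#' by development AUC; record-level anomaly probabilities feed the four
#' stacking patterns under two meta-learners (8 stacking fits per fold);
#' all 14 variants (6 single + 8 stacked) are evaluated on the shared test
#' set. Two compute profiles share the identical pipeline: `"paper"`
#' (243 x 128 spectrograms, 512/256-pixel page views) and `"tiny"`
#' (coarser spectrograms, 1/8-scale pages, narrow CNN) for CPU-bound runs.
#' @name experiment
NULL

SOURCE_SITE <- c("PCG-2RSB" = "2RSB", "PCG-ERB" = "ERB", "PCG-APX" = "APX")
SOURCE_VIEW <- c("ECG-all12" = "all12", "ECG-limb" = "limb",
                 "ECG-precordial" = "precordial")

target_col <- function(disease) {
  c(AS = "as_target", MR = "mr_target", LVD = "lvd_target")[[disease]]
}
grade_col <- function(disease) {
  c(AS = "as_grade", MR = "mr_grade", LVD = "lvd_grade")[[disease]]
}

#' Experiment configuration
#'
#' @param disease target disease (`"AS"`, `"MR"`, `"LVD"`).
#' @param profile `"paper"` (full-size inputs) or `"tiny"` (CPU-scale:
#'   448-sample hop / 32 Mel filters, 1/8-scale page views, narrow CNN).
#' @param seed global seed; all stage seeds derive from it.
#' @param sources enabled single-modal sources.
#' @param folds_run fold indices actually trained (the job graph always
#'   enumerates all folds).
#' @param epochs,batch_size,learning_rate CNN training parameters.
#' @param test_fraction shared-test-set fraction for fold construction.
#' @param aggregate record-level aggregation of segment probabilities.
#' @param mixup_alpha,n_masks training-time augmentation parameters for the
#'   heart-sound models (mask widths scale with the grid).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(disease = "AS", profile = "tiny", seed = 1L,
                              sources = STACK_SOURCES, folds_run = 1L,
                              epochs = NULL, batch_size = 16L,
                              learning_rate = 1e-3, test_fraction = 0.2,
                              aggregate = "mean", mixup_alpha = 0.2,
                              n_masks = 2L) {
  disease <- match_one(disease, DISEASES, "disease")
  profile <- match_one(profile, c("paper", "tiny"), "profile")
  pcg <- switch(profile,
    paper = pcg_preproc_params(disease),
    tiny = pcg_preproc_params(disease, hop = 448L, n_mels = 32L))
  structure(list(
    disease = disease, profile = profile, seed = as.integer(seed),
    sources = sources, folds_run = folds_run,
    pcg = pcg,
    ecg_scale = if (profile == "paper") 1 else 0.125,
    cnn_profile = if (profile == "paper") "default" else "tiny",
    epochs = as.integer(epochs %||% if (profile == "paper") 10L else 3L),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    test_fraction = test_fraction, aggregate = aggregate,
    mixup_alpha = mixup_alpha, n_masks = as.integer(n_masks),
    patterns = names(stacking_patterns()), learners = c("rf", "xgb")),
    class = "experiment_config")
}

ecg_params_for <- function(cohort, view, config) {
  # the crop geometry follows the cohort's page scale
  scale <- cohort$params$page_height / ECG_PAGE_HEIGHT
  ecg_crop_params(view, config$disease, scale = scale)
}

pcg_augmenter <- function(config, n_frames) {
  fw <- max(1L, config$pcg$n_mels %/% 8L)
  tw <- max(1L, n_frames %/% 10L)
  alpha <- config$mixup_alpha
  nm <- config$n_masks
  function(x_list, y_soft) {
    n <- length(x_list)
    x_list <- lapply(x_list, spec_augment, freq_mask_width = fw,
                     time_mask_width = tw, n_masks = nm)
    perm <- sample.int(n)
    lam <- rbeta(n, alpha, alpha)
    y_out <- y_soft
    for (i in seq_len(n)) {
      m <- mixup(x_list[[i]], x_list[[perm[i]]], y_soft[i, ],
                 y_soft[perm[i], ], lambda = lam[i])
      x_list[[i]] <- m$values
      y_out[i, ] <- m$label
    }
    list(x = x_list, y = y_out)
  }
}

# Per-source feature extraction: generates each record once and returns the
# oversampled training grids (for ids in train_ids) plus the deterministic
# evaluation-time grids for every id.
extract_source_features <- function(cohort, source, config,
                                    ids, train_ids = character(0)) {
  disease <- config$disease
  pts <- cohort$patients
  gcol <- grade_col(disease)
  tcol <- target_col(disease)
  is_pcg <- source %in% names(SOURCE_SITE)
  if (!is_pcg && !source %in% names(SOURCE_VIEW))
    stopf("unknown source: %s", source)
  if (!is_pcg) cp <- ecg_params_for(cohort, SOURCE_VIEW[[source]], config)
  train_x <- list(); train_y <- integer(0); train_pid <- character(0)
  eval_x <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    i <- match(id, pts$patient_id)
    grade <- pts[[gcol]][i]
    y <- as.integer(pts[[tcol]][i])
    if (is_pcg) {
      rec <- cohort_pcg(cohort, i, SOURCE_SITE[[source]])
      ev <- lapply(segment_record(rec, config$pcg, "none"),
                   log_mel, params = config$pcg,
                   sample_rate = rec$sample_rate)
      eval_x[[id]] <- lapply(ev, unclass)
      if (id %in% train_ids) {
        tr <- if (grade == "none") eval_x[[id]]
          else lapply(segment_record(rec, config$pcg, grade),
                      function(w) unclass(log_mel(w, config$pcg,
                                                  rec$sample_rate)))
        train_x <- c(train_x, tr)
        train_y <- c(train_y, rep(y, length(tr)))
        train_pid <- c(train_pid, rep(id, length(tr)))
      }
    } else {
      scan <- cohort_ecg(cohort, i)
      eval_x[[id]] <- list(resize_view(crop_view(scan, cp), cp) / 255)
      if (id %in% train_ids) {
        tr <- lapply(shift_augment(scan, cp, grade), function(m) {
          attr(m, "shift_px") <- NULL
          m / 255
        })
        train_x <- c(train_x, tr)
        train_y <- c(train_y, rep(y, length(tr)))
        train_pid <- c(train_pid, rep(id, length(tr)))
      }
    }
  }
  y_record <- stats::setNames(as.integer(pts[[tcol]][match(ids, pts$patient_id)]),
                              ids)
  list(train = list(x = train_x, y = train_y, pid = train_pid),
       eval_x = eval_x, y_record = y_record, is_pcg = is_pcg)
}

#' Train one single-modal CNN for a fold
#'
#' Builds the fold's oversampled training set and deterministic
#' development set for the given source, trains the 10-block CNN
#' (SpecAugment + mixup on the training path of heart-sound models), and
#' returns the checkpoint with the best development AUC together with
#' record-level probabilities for the ids in `predict_ids`.
#'
#' @param cohort a `cohort_manifest`.
#' @param source one of [STACK_SOURCES].
#' @param fa a `fold_assignment`.
#' @param fold fold index.
#' @param config an `experiment_config`.
#' @param predict_ids patients to score (default: dev + test of the fold).
#' @return list: `fit` (a `cnn_fit`), `source`, `probs` (named vector of
#'   record-level anomaly probabilities), `labels`.
#' @export
train_single_modal <- function(cohort, source, fa, fold, config,
                               predict_ids = NULL) {
  f <- fa$folds[[fold]]
  predict_ids <- predict_ids %||% c(f$dev_ids, fa$test_ids)
  ids <- unique(c(f$train_ids, f$dev_ids, predict_ids))
  feats <- extract_source_features(cohort, source, config, ids, f$train_ids)
  if (sum(feats$train$y) == 0)
    stopf("no positive-class records in the training split for %s", source)
  dev_x <- unlist(feats$eval_x[f$dev_ids], recursive = FALSE)
  dev_y <- rep(feats$y_record[f$dev_ids],
               vapply(feats$eval_x[f$dev_ids], length, integer(1)))
  shape <- dim(feats$train$x[[1]])
  si <- match(source, STACK_SOURCES)
  cfg <- cnn_config(shape, profile = config$cnn_profile,
                    epochs = config$epochs, batch_size = config$batch_size,
                    learning_rate = config$learning_rate,
                    seed = config$seed * 1000L + fold * 10L + si)
  aug <- if (feats$is_pcg) pcg_augmenter(config, shape[1]) else NULL
  fit <- cnn_train(feats$train$x, feats$train$y, dev_x, dev_y, cfg,
                   augment_fn = aug)
  probs <- vapply(predict_ids, function(id)
    predict_record(fit$model, feats$eval_x[[id]], config$aggregate),
    numeric(1))
  list(fit = fit, source = source, probs = probs,
       labels = feats$y_record[predict_ids])
}

#' Enumerate the experiment job graph
#'
#' @param config an `experiment_config`.
#' @param n_folds number of cross-validation folds (4).
#' @return data frame of jobs: per fold, one `train_cnn` job per source,
#'   one `fit_stacker` job per pattern x learner, and one `evaluate` job
#'   per variant (6 single + 8 stacked = 14).
#' @export
experiment_jobs <- function(config, n_folds = 4L) {
  jobs <- list()
  for (fold in seq_len(n_folds)) {
    for (s in config$sources)
      jobs[[length(jobs) + 1L]] <- data.frame(
        stage = "train_cnn", disease = config$disease, fold = fold,
        target = s)
    for (p in config$patterns)
      for (l in config$learners)
        jobs[[length(jobs) + 1L]] <- data.frame(
          stage = "fit_stacker", disease = config$disease, fold = fold,
          target = sprintf("%s(%s)", toupper(l), p))
    for (v in c(config$sources,
                unlist(lapply(config$patterns, function(p)
                  sprintf("%s(%s)", toupper(config$learners), p)))))
      jobs[[length(jobs) + 1L]] <- data.frame(
        stage = "evaluate", disease = config$disease, fold = fold,
        target = v)
  }
  out <- do.call(rbind, jobs)
  out$job_id <- seq_len(nrow(out))
  out[, c("job_id", "stage", "disease", "fold", "target")]
}

#' Run the experiment for one disease
#'
#' Executes training, stacking and test-set evaluation for the folds in
#' `config$folds_run`. With `dry_run = TRUE` only the job graph is
#' returned and nothing is trained.
#'
#' @param cohort a `cohort_manifest`.
#' @param config an `experiment_config`.
#' @param fa optional pre-built `fold_assignment`.
#' @param dry_run if `TRUE`, return the enumerated job graph.
#' @param verbose print stage progress.
#' @return for a dry run, the jobs data frame. Otherwise a list of class
#'   `experiment_result`: `folds`, `models`, `tables` (per fold: dev/test
#'   `prediction_table`s), `stackers`, `variant_grid` (method, fold,
#'   test_auc), `test_scores` (per method x fold score vectors), `config`.
#' @export
run_experiment <- function(cohort, config, fa = NULL, dry_run = FALSE,
                           verbose = FALSE) {
  if (dry_run) return(experiment_jobs(config))
  fa <- fa %||% make_folds(cohort, config$test_fraction, seed = config$seed)
  tcol <- target_col(config$disease)
  pts <- cohort$patients
  models <- tables <- stackers <- list()
  grid_rows <- list()
  test_scores <- list()
  for (fold in config$folds_run) {
    f <- fa$folds[[fold]]
    dev_ids <- f$dev_ids; test_ids <- fa$test_ids
    probs <- list()
    for (s in config$sources) {
      if (verbose) message(sprintf("[fold %d] training %s", fold, s))
      tm <- train_single_modal(cohort, s, fa, fold, config)
      models[[paste(fold, s)]] <- tm$fit
      probs[[s]] <- tm$probs
    }
    mk_table <- function(ids) {
      do.call(rbind, lapply(config$sources, function(s)
        prediction_table(ids, rep(s, length(ids)), unname(probs[[s]][ids]))))
    }
    tables[[as.character(fold)]] <- list(dev = mk_table(dev_ids),
                                         test = mk_table(test_ids))
    labels <- stats::setNames(pts[[tcol]], pts$patient_id)
    # single-modal variants
    for (s in config$sources) {
      sc <- probs[[s]][test_ids]
      grid_rows[[length(grid_rows) + 1L]] <- data.frame(
        method = s, fold = fold, test_auc = roc_auc(sc, labels[test_ids]))
      test_scores[[paste(s, fold)]] <- list(scores = sc,
                                            labels = labels[test_ids])
    }
    # stacked variants: meta-learner trained and tuned on the dev split
    feasible <- Filter(function(p)
      all(stacking_patterns()[[p]] %in% config$sources), config$patterns)
    for (p in feasible) {
      dev_feat <- assemble_features(tables[[as.character(fold)]]$dev, p, labels)
      test_feat <- assemble_features(tables[[as.character(fold)]]$test, p, labels)
      for (l in config$learners) {
        vname <- sprintf("%s(%s)", toupper(l), p)
        if (verbose) message(sprintf("[fold %d] stacking %s", fold, vname))
        spec <- stacker_spec(l, seed = config$seed * 100L + fold)
        sf <- fit_stacker(dev_feat$x, dev_feat$y, spec, dev_feat$x, dev_feat$y)
        stackers[[paste(fold, vname)]] <- sf
        sc <- predict(sf, test_feat$x)
        names(sc) <- test_ids
        grid_rows[[length(grid_rows) + 1L]] <- data.frame(
          method = vname, fold = fold,
          test_auc = roc_auc(sc, test_feat$y))
        test_scores[[paste(vname, fold)]] <- list(scores = sc,
                                                  labels = labels[test_ids])
      }
    }
  }
  structure(list(folds = fa, models = models, tables = tables,
                 stackers = stackers,
                 variant_grid = do.call(rbind, grid_rows),
                 test_scores = test_scores, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, %d fold(s) run, %d variants\n",
              x$config$disease, length(x$config$folds_run),
              length(unique(x$variant_grid$method))))
  invisible(x)
}
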