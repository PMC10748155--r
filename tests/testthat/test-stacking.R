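test_that("stacking patterns enable exactly the tabulated source sets", {
  p <- stacking_patterns()
  expect_equal(lengths(p)[c("PCG3ch+ECG2pt", "PCG3ch+ECG1pt", "PCG3ch",
                            "ECG2pt")],
               c("PCG3ch+ECG2pt" = 5L, "PCG3ch+ECG1pt" = 4L,
                 "PCG3ch" = 3L, "ECG2pt" = 2L))
  expect_false("ECG-all12" %in% p$`PCG3ch+ECG2pt`)
  expect_true("ECG-all12" %in% p$`PCG3ch+ECG1pt`)
})

test_that("feature assembly equals a brute-force per-patient join", {
  set.seed(4)
  ids <- sprintf("P%02d", 1:15)
  long <- do.call(rbind, lapply(STACK_SOURCES, function(s)
    prediction_table(ids, rep(s, 15), runif(15))))
  long <- long[sample(nrow(long)), ]          # scrambled row order
  f <- assemble_features(long, "PCG3ch+ECG2pt")
  expect_equal(dim(f$x), c(15L, 5L))
  for (i in seq_along(ids)) {
    for (s in colnames(f$x)) {
      oracle <- long$probability[long$patient_id == ids[i] & long$source == s]
      expect_equal(f$x[ids[i], s], oracle)
    }
  }
  expect_equal(ncol(assemble_features(long, "ECG2pt")$x), 2L)
  # empty patient set: empty matrix, no error
  empty <- long[0, ]
  expect_equal(nrow(assemble_features(empty, "PCG3ch")$x), 0L)
  # missing source names the patient
  expect_error(assemble_features(long[long$patient_id != "P03" |
                                        long$source != "PCG-ERB", ],
                                 "PCG3ch"),
               "PCG-ERB.*P03")
})

test_that("grid search maximizes development F1 with first-hit tie-breaking", {
  set.seed(6)
  # perfectly separable toy set on feature 1
  n <- 40
  x <- cbind(f1 = c(runif(n / 2, 0.9, 1), runif(n / 2, 0, 0.1)),
             f2 = runif(n))
  colnames(x) <- c("PCG-2RSB", "PCG-ERB")
  y <- rep(c(1L, 0L), each = n / 2)
  spec <- stacker_spec("rf", seed = 2)
  fit <- fit_stacker(x, y, spec, x, y)
  expect_equal(fit$dev_f1, 1.0)
  expect_true(all(fit$grid_results$dev_f1 <= 1))
  # grid of size 1 returns that configuration
  g1 <- stacker_spec("xgb", grid = data.frame(n_rounds = 25L, max_depth = 2L,
                                              learning_rate = 0.3), seed = 2)
  fit1 <- fit_stacker(x, y, g1, x, y)
  expect_equal(fit1$params$n_rounds, 25L)
  expect_equal(predict(fit1, x) >= 0.5, y == 1L)
  # exact ties resolve to the first grid row
  gtie <- stacker_spec("rf", grid = data.frame(n_trees = c(50L, 50L),
                                               max_depth = c(3L, 3L)),
                       seed = 2)
  ftie <- fit_stacker(x, y, gtie, x, y)
  expect_equal(ftie$params, as.list(gtie$grid[1, , drop = FALSE]))
  expect_error(fit_stacker(x, rep(1L, n), spec, x, y), "both classes")
})

test_that("importances are normalized and track the informative feature", {
  set.seed(8)
  n <- 60
  x <- cbind(a = c(runif(n / 2, 0.9, 1), runif(n / 2, 0, 0.1)),
             b = runif(n), const = rep(0.5, n))
  colnames(x) <- c("PCG-2RSB", "ECG-limb", "ECG-precordial")
  y <- rep(c(1L, 0L), each = n / 2)
  for (learner in c("rf", "xgb")) {
    fit <- fit_stacker(x, y, stacker_spec(learner, seed = 3), x, y)
    imp <- stacker_importances(fit)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    expect_gt(imp[["PCG-2RSB"]], 0.9)
    expect_equal(imp[["ECG-precordial"]], 0)   # constant feature never splits
  }
  expect_error(stacker_importances(list()), "not a fitted stacker")
})

test_that("stacked development F1 is at least the best single-threshold F1", {
  set.seed(13)
  n <- 80
  y <- rep(c(1L, 0L), each = n / 2)
  x <- cbind(0.35 * y + runif(n, 0, 0.6), 0.35 * y + runif(n, 0, 0.6))
  colnames(x) <- c("PCG-2RSB", "ECG-limb")
  fit <- fit_stacker(x, y, stacker_spec("rf", seed = 4), x, y)
  single_best <- max(apply(x, 2, function(col)
    threshold_metrics(col, y, 0.5)[["f1"]]))
  expect_gte(fit$dev_f1, single_best)
})
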