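test_that("AUC equals the tie-aware pairwise probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  # brute-force pairwise oracle on 100 random instances (with ties)
  set.seed(20)
  for (i in 1:100) {
    n <- sample(8:25, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    oracle <- {
      pos <- scores[labels == 1]; neg <- scores[labels == 0]
      tot <- 0
      for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
      tot / (length(pos) * length(neg))
    }
    expect_equal(roc_auc(scores, labels), oracle, tolerance = 1e-12)
  }
})

test_that("bootstrap report honours degenerate and perfect inputs", {
  y <- rep(c(1, 0), each = 10)
  s <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  r <- bootstrap_metrics(s, y, B = 50, seed = 1)
  expect_equal(unname(r$mean[["auc"]]), 1.0)
  expect_equal(unname(r$sd[["auc"]]), 0.0)
  r1 <- bootstrap_metrics(s, y, B = 1, seed = 1)
  expect_true(all(r1$sd == 0))
  expect_error(bootstrap_metrics(s, rep(1, 20), B = 10), "both classes")
  # uninformative scores: mean AUC near 1/2 at n = 200
  set.seed(2)
  s0 <- runif(200); y0 <- rep(c(0, 1), 100)
  r0 <- bootstrap_metrics(s0, y0, B = 400, seed = 3)
  expect_lt(abs(r0$mean[["auc"]] - 0.5), 0.05)
})

test_that("bootstrap AUC dispersion shrinks roughly as 1/sqrt(n)", {
  sds <- vapply(c(50, 100, 200, 400), function(n) {
    set.seed(n)
    y <- rep(c(0, 1), n / 2)
    s <- rnorm(n, mean = y)          # fixed true separation
    bootstrap_metrics(s, y, B = 400, seed = 7)$sd[["auc"]]
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  ratio <- sds[1] / sds[4]           # expected ~ sqrt(8) = 2.83
  expect_gt(ratio, sqrt(8) / 2)
  expect_lt(ratio, sqrt(8) * 2)
})

test_that("model comparison separates the separable and spares the identical", {
  set.seed(31)
  y <- rep(c(0, 1), 100)
  s <- runif(200)
  same <- list(
    A = bootstrap_metrics(s, y, B = 300, seed = 11, model = "A"),
    B = bootstrap_metrics(s, y, B = 300, seed = 12, model = "B"))
  cmp_same <- compare_models(same)
  expect_false(any(cmp_same$pairwise$different))
  # true AUC 0.95 vs 0.55 at n = 200, B = 500: declared different
  strong <- rnorm(200, mean = 2.33 * y)    # binormal AUC ~0.95
  weak <- rnorm(200, mean = 0.18 * y)      # AUC ~0.55
  cmp <- compare_models(list(
    strong = bootstrap_metrics(strong, y, B = 500, seed = 13, model = "strong"),
    weak = bootstrap_metrics(weak, y, B = 500, seed = 14, model = "weak")))
  expect_true(all(cmp$pairwise$different))
  expect_equal(cmp$ranking$model[1], "strong")
  # three models -> exactly 3 pairwise comparisons
  three <- c(same, list(C = bootstrap_metrics(s, y, B = 300, seed = 15,
                                              model = "C")))
  expect_equal(nrow(compare_models(three)$pairwise), 3L)
  bad <- list(A = same$A, B = bootstrap_metrics(s, y, B = 100, seed = 1))
  expect_error(compare_models(bad), "mismatched B")
})

test_that("top-3 selection keeps the best fold per method", {
  methods <- c("m1", "m2", "m3", "m4")
  grid <- expand.grid(method = methods, fold = 1:4, stringsAsFactors = FALSE)
  set.seed(40)
  grid$test_auc <- runif(nrow(grid))
  grid$test_auc[grid$method == "m3" & grid$fold == 2] <- 0.999
  sel <- select_models(grid)
  expect_equal(nrow(sel$survivors), 4L)
  expect_equal(sel$top$method[1], "m3")
  expect_equal(sel$top$fold[1], 2)
  for (m in methods)
    expect_equal(sel$survivors$test_auc[sel$survivors$method == m],
                 max(grid$test_auc[grid$method == m]))
  # deterministic tie-break by documented method order
  grid$test_auc <- 0.7
  sel_tie <- select_models(grid)
  expect_equal(sel_tie$top$method, c("m1", "m2", "m3"))
  expect_error(select_models(grid[-1, ]), "missing evaluation cells")
})

test_that("report formatting mirrors the results-table layout", {
  y <- rep(c(1, 0), each = 15)
  s <- c(runif(15, 0.6, 1), runif(15, 0, 0.4))
  r <- bootstrap_metrics(s, y, B = 30, seed = 2, model = "PCG1 (2RSB)")
  tab <- format_bootstrap_reports(list(r))
  expect_equal(names(tab), c("Model", "AUC", "F1", "Sensitivity",
                             "Specificity"))
  expect_match(tab$AUC, "^\\d\\.\\d{3} ± \\d\\.\\d{3}$")
})
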