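test_that("segmentation start times follow the even-spacing formula", {
  rec <- generate_pcg(list(), "ERB", seed = 1)
  p3 <- pcg_preproc_params(segment_counts = c(none = 3L, mild = 3L,
                                              moderate = 3L, severe = 20L))
  segs <- segment_record(rec, p3, "none")
  expect_length(segs, 3L)
  expect_equal(vapply(segs, attr, numeric(1), "start_s"), c(0, 5.5, 11))
  expect_true(all(lengths(segs) == 16000L))
  # k = 20: starts within [0, 11], evenly spaced
  segs20 <- segment_record(rec, p3, "severe")
  starts <- vapply(segs20, attr, numeric(1), "start_s")
  expect_length(segs20, 20L)
  expect_true(all(starts >= 0 & starts <= 11))
  expect_equal(diff(starts), rep(11 / 19, 19))
  expect_true(all(lengths(segs20) == 16000L))
  # 4-s record, k = 1 -> single window at 0
  rec4 <- generate_pcg(list(), "ERB", seed = 1, duration = 4)
  p1 <- pcg_preproc_params(segment_counts = c(none = 1L, mild = 1L,
                                              moderate = 1L, severe = 1L))
  s1 <- segment_record(rec4, p1, "none")
  expect_length(s1, 1L)
  expect_equal(attr(s1[[1]], "start_s"), 0)
  # record shorter than the window is rejected
  rec2 <- generate_pcg(list(), "ERB", seed = 1, duration = 2)
  expect_error(segment_record(rec2, p1, "none"), "shorter")
})

test_that("oversampling counts equal the per-grade multiplying factors", {
  expect_equal(unname(grade_factors("AS")), c(3L, 3L, 3L, 20L))
  expect_equal(unname(grade_factors("MR")), c(3L, 3L, 3L, 44L))
  expect_equal(unname(grade_factors("LVD")), c(3L, 3L, 3L, 42L))
  rec <- generate_pcg(list(), "APX", seed = 2)
  for (d in c("AS", "MR", "LVD")) {
    p <- pcg_preproc_params(d)
    for (g in c("none", "severe"))
      expect_length(segment_record(rec, p, g), grade_factors(d)[[g]])
  }
})

test_that("log-Mel output matches the stated defaults and degenerate cases", {
  p <- pcg_preproc_params()
  lm <- log_mel(rep(0, 16000), p)
  expect_equal(dim(unclass(lm)), c(243L, 128L))
  expect_true(all(abs(lm - log(p$log_floor)) < 1e-12))
  expect_error(log_mel(rep(0, 100), p), "shorter")
})

test_that("frame count equals a brute-force sliding-window enumeration", {
  set.seed(42)
  for (i in 1:50) {
    L <- sample(600:5000, 1)
    win <- sample(c(64L, 128L, 256L, 512L), 1)
    hop <- sample(seq_len(win - 1L), 1)
    # oracle: count windows by walking starts until one no longer fits
    n_oracle <- 0L
    s <- 1L
    while (s + win - 1L <= L) {
      n_oracle <- n_oracle + 1L
      s <- s + hop
    }
    p <- pcg_preproc_params(fft_window = win, hop = hop, n_mels = 8L)
    out <- log_mel(rnorm(L), p)
    expect_equal(nrow(out), n_oracle)
  }
})

test_that("a pure tone lands in the Mel bin bracketing its frequency", {
  p <- pcg_preproc_params()
  tone <- sin(2 * pi * 1000 * (0:15999) / 4000)
  lm <- unclass(log_mel(tone, p))
  peaks <- apply(lm, 1, which.max)
  expect_length(unique(peaks), 1L)
  # independent bin-edge oracle from the Mel-scale formula
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- mel2hz(seq(0, hz2mel(2000), length.out = 130))
  bracket <- which(edges[1:128] < 1000 & 1000 < edges[3:130])
  expect_true(peaks[1] %in% bracket)
})

test_that("SpecAugment masks exactly the requested bands with the grid mean", {
  set.seed(7)
  g <- matrix(rnorm(243 * 128), 243, 128)
  expect_identical(spec_augment(g, 0, 0, 2), g)
  masked <- spec_augment(g, freq_mask_width = 8, time_mask_width = 0,
                         n_masks = 1)
  changed <- which(masked != g)
  expect_length(changed, 243L * 8L)
  expect_true(all(masked[changed] == mean(g)))
  # same RNG state twice -> identical masks
  set.seed(99); a <- spec_augment(g, 16, 24, 2)
  set.seed(99); b <- spec_augment(g, 16, 24, 2)
  expect_identical(a, b)
  expect_error(spec_augment(g, freq_mask_width = 1000, time_mask_width = 0),
               "wider than axis")
})

test_that("mixup is a convex combination of segments and labels", {
  set.seed(5)
  a <- random_logmel_grid(); b <- random_logmel_grid()
  m1 <- mixup(a, b, 1, 0, lambda = 1)
  expect_identical(m1$values, a)
  expect_equal(m1$label, c(0, 1))
  m0 <- mixup(a, -a, 0, 0, lambda = 0.5)
  expect_true(all(abs(m0$values) < 1e-12))
  for (i in 1:10) {
    m <- mixup(a, b, 1, 0, alpha = 0.2)
    expect_true(all(m$values >= pmin(a, b) - 1e-12))
    expect_true(all(m$values <= pmax(a, b) + 1e-12))
    expect_equal(sum(m$label), 1)
  }
  expect_error(mixup(a, b[1:10, ], 1, 0), "shape mismatch")
})
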