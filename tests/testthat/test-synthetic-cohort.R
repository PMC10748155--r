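test_that("phonocardiogram generator honours its shape and determinism contracts", {
  r1 <- generate_pcg(list(AS = "severe"), "2RSB", seed = 11)
  r2 <- generate_pcg(list(AS = "severe"), "2RSB", seed = 11)
  expect_identical(r1$samples, r2$samples)
  expect_length(r1$samples, 60000L)
  expect_true(all(is.finite(r1$samples)))
  expect_equal(r1$sample_rate, 4000)
  # zero effect size disables every disease term bit for bit
  for (g in list(list(AS = "severe"), list(MR = "severe"),
                 list(LVD = "severe"),
                 list(AS = "severe", MR = "severe", LVD = "severe"))) {
    expect_identical(generate_pcg(g, "ERB", seed = 5, effect_size = 0)$samples,
                     generate_pcg(list(), "ERB", seed = 5, effect_size = 0)$samples)
  }
  expect_error(generate_pcg(list(), "chest", seed = 1), "site")
  expect_error(generate_pcg(list(AS = "huge"), "APX", seed = 1), "grade")
})

test_that("severe-AS murmur is loudest at 2RSB in systole (20-seed ordering)", {
  hits <- 0L
  for (s in 1:20) {
    rms <- vapply(c("2RSB", "APX"), function(site)
      systolic_rms(generate_pcg(list(AS = "severe"), site, seed = 100 + s,
                                effect_size = 1)),
      numeric(1))
    if (rms[["2RSB"]] > rms[["APX"]]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("systolic separability is non-decreasing in effect size", {
  sep <- vapply(c(0, 0.5, 1, 2), function(eff) {
    d <- vapply(1:8, function(s) {
      systolic_rms(generate_pcg(list(AS = "severe"), "2RSB", seed = 300 + s,
                                effect_size = eff)) -
        systolic_rms(generate_pcg(list(), "2RSB", seed = 300 + s,
                                  effect_size = eff))
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(sep) >= 0))
})

test_that("ECG page render matches the scan geometry and disease signatures", {
  s <- generate_ecg_scan(list(), seed = 4)
  expect_equal(dim(s$pixels), c(1840L, 3187L))
  expect_true(all(s$pixels >= 0 & s$pixels <= 255))
  expect_identical(s$pixels, generate_ecg_scan(list(), seed = 4)$pixels)
  # zero effect: severe page identical to healthy page
  expect_identical(
    generate_ecg_scan(list(AS = "severe", MR = "severe", LVD = "severe"),
                      seed = 9, effect_size = 0)$pixels,
    generate_ecg_scan(list(), seed = 9, effect_size = 0)$pixels)
  # severe LVD widens the rendered QRS template
  none <- generate_ecg_scan(list(), seed = 21)
  lvd <- generate_ecg_scan(list(LVD = "severe"), seed = 21, effect_size = 1)
  expect_gt(lvd$meta$qrs_sigma_s, none$meta$qrs_sigma_s)
  # severe MR perturbs rhythm regularity
  mr <- generate_ecg_scan(list(MR = "severe"), seed = 21, effect_size = 1)
  expect_gt(sd(mr$meta$rr_intervals), sd(none$meta$rr_intervals))
  expect_error(generate_ecg_scan(list(), seed = 1, page_width = 0), "page size")
})

test_that("cohort grade draws replay the seeded categorical stream", {
  prev <- list(AS = c(none = 0.8, mild = 0, moderate = 0, severe = 0.2),
               MR = c(none = 1, mild = 0, moderate = 0, severe = 0),
               LVD = c(none = 1, mild = 0, moderate = 0, severe = 0))
  cohort <- generate_cohort(100, prev, seed = 77)
  # oracle: replay the first sample() call of the seeded stream
  oracle <- local({
    set.seed(77)
    sample(c("none", "mild", "moderate", "severe"), 100, replace = TRUE,
           prob = prev$AS)
  })
  expect_identical(cohort$patients$as_grade, oracle)
  expect_equal(sum(cohort$patients$as_target), sum(oracle == "severe"))
})

test_that("cohort manifest has three PCG records and one scan per patient", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(
    1, prevalences = list(AS = c(1, 0, 0, 0), MR = c(1, 0, 0, 0),
                          LVD = c(1, 0, 0, 0)),
    seed = 3, dir = dir, page_width = TINY_PAGE_W, page_height = TINY_PAGE_H)
  p <- cohort$patients
  paths <- unlist(p[1, c("pcg_2RSB", "pcg_ERB", "pcg_APX", "ecg_scan")])
  expect_length(paths, 4L)
  expect_true(all(file.exists(paths)))
  expect_length(list.files(dir, pattern = "\\.wav$"), 3L)
  expect_length(list.files(dir, pattern = "\\.png$"), 1L)
  # round trip through the manifest
  back <- read_cohort(dir)
  expect_equal(back$patients$patient_id, p$patient_id)
  rec <- cohort_pcg(back, 1, "2RSB")
  expect_length(rec$samples, 60000L)
})

test_that("all-none prevalences yield zero binary positives", {
  cohort <- generate_cohort(
    10, prevalences = list(AS = c(1, 0, 0, 0), MR = c(1, 0, 0, 0),
                           LVD = c(1, 0, 0, 0)), seed = 8,
    page_width = TINY_PAGE_W, page_height = TINY_PAGE_H)
  expect_equal(sum(cohort$patients$as_target), 0)
  expect_equal(sum(cohort$patients$mr_target), 0)
  expect_equal(sum(cohort$patients$lvd_target), 0)
  expect_error(generate_cohort(5, prevalences = list(
    AS = c(0.5, 0, 0, 0), MR = c(1, 0, 0, 0), LVD = c(1, 0, 0, 0))),
    "distribution")
})

test_that("binary target is a pure function of grade", {
  expect_identical(grade_to_target(c("none", "mild", "moderate", "severe")),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_error(grade_to_target("critical"), "unknown grade")
})
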