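#' @title Synthetic phonocardiograms
#' @description
#' Disease-conditioned heart-sound generator. A recording is a periodic train
#' of S1/S2 Gaussian-windowed tone bursts (fundamentals in the 50-150 Hz
#' band) over broadband background noise, with murmurs modelled as
#' band-pass-filtered noise under disease-specific temporal envelopes:
#' \itemize{
#'   \item severe aortic stenosis: mid-systolic crescendo-decrescendo burst,
#'     loudest at the second right sternal border (2RSB), attenuated at Erb
#'     and most at the apex;
#'   \item severe mitral regurgitation: holosystolic burst, loudest at the
#'     apex;
#'   \item severe left-ventricular dysfunction: attenuated S1.
#' }
#' All random draws are consumed regardless of the grades, so a zero effect
#' size reproduces the all-healthy waveform bit for bit at the same seed.
#' @name synthetic-pcg
NULL

PCG_SITES <- c("2RSB", "ERB", "APX")
DISEASES <- c("AS", "MR", "LVD")
GRADES <- c("none", "mild", "moderate", "severe")

# auscultation-site loudness of each murmur (radiation pattern)
AS_SITE_GAIN <- c("2RSB" = 1.0, "ERB" = 0.6, "APX" = 0.3)
MR_SITE_GAIN <- c("2RSB" = 0.3, "ERB" = 0.6, "APX" = 1.0)

check_grades <- function(disease_grades) {
  g <- as.list(disease_grades)
  for (d in DISEASES) {
    g[[d]] <- g[[d]] %||% "none"
    match_one(g[[d]], GRADES, sprintf("%s grade", d))
  }
  g[DISEASES]
}

#' Convert a severity grade to the binary screening target
#'
#' The positive class is "severe" throughout (severe AS, severe MR,
#' severely reduced ejection fraction).
#'
#' @param grade character vector of grades in none/mild/moderate/severe.
#' @return logical vector, `TRUE` iff the grade is `"severe"`.
#' @export
grade_to_target <- function(grade) {
  if (!all(grade %in% GRADES)) stopf("unknown grade(s): %s",
                                     paste(setdiff(grade, GRADES), collapse = ", "))
  grade == "severe"
}

# Zero-phase band-pass via FFT masking; output rescaled to unit variance so
# murmur loudness is controlled purely by its amplitude coefficient.
fft_bandpass <- function(x, lo, hi, fs) {
  n <- length(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  mask <- freq >= lo & freq <= hi
  y <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
  s <- sd(y)
  if (s > 0) y / s else y
}

gauss_burst <- function(t, fs, n, center, freq, sigma, amp) {
  # supported on +-4 sigma to keep the cost linear in beats
  i0 <- max(1L, ceiling((center - 4 * sigma) * fs) + 1L)
  i1 <- min(n, floor((center + 4 * sigma) * fs) + 1L)
  if (i0 > i1) return(NULL)
  idx <- i0:i1
  tt <- t[idx] - center
  list(idx = idx, val = amp * exp(-tt^2 / (2 * sigma^2)) * sin(2 * pi * freq * tt))
}

#' Generate one synthetic phonocardiogram record
#'
#' @param disease_grades named list/vector with entries `AS`, `MR`, `LVD`,
#'   each one of none/mild/moderate/severe (missing entries default to none).
#' @param site auscultation site: `"2RSB"`, `"ERB"` or `"APX"`.
#' @param seed integer seed; the record is a pure function of the arguments.
#' @param effect_size nonnegative scalar scaling all disease signatures;
#'   0 disables them entirely.
#' @param duration record length in seconds (15 s as recorded by the
#'   emulated device).
#' @param sample_rate sampling rate in Hz (4000).
#' @param patient_id optional identifier carried through to the record.
#' @return object of class `pcg_record`: `samples`, `sample_rate`,
#'   `duration`, `site`, `patient_id` and a `meta` list with the drawn heart
#'   rate, beat onsets and per-beat systolic windows (seconds).
#' @export
generate_pcg <- function(disease_grades, site, seed, effect_size = 1,
                         duration = 15, sample_rate = 4000,
                         patient_id = NULL) {
  site <- match_one(site, PCG_SITES, "auscultation site")
  g <- check_grades(disease_grades)
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0)
    stopf("effect_size must be a nonnegative scalar")
  fs <- sample_rate
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs

  rec <- with_seed(seed, {
    hr <- runif(1, 60, 100)
    period <- 60 / hr
    t0 <- runif(1, 0.05, 0.15)
    f_s1 <- runif(1, 50, 90)
    f_s2 <- runif(1, 90, 150)
    base_noise <- rnorm(n)
    as_src <- fft_bandpass(rnorm(n), 100, 400, fs)
    mr_src <- fft_bandpass(rnorm(n), 60, 300, fs)

    beats <- seq(t0, duration, by = period)
    systole <- 0.35 * period                  # S1 onset -> S2 onset
    sys_win <- cbind(start = beats + 0.06, end = beats + systole - 0.02)

    lvd_on <- g$LVD == "severe"
    s1_scale <- if (lvd_on) 1 / (1 + effect_size) else 1

    x <- 0.004 * base_noise
    for (b in beats) {
      s1 <- gauss_burst(t, fs, n, b, f_s1, 0.025, 0.35 * s1_scale)
      if (!is.null(s1)) x[s1$idx] <- x[s1$idx] + s1$val
      s2 <- gauss_burst(t, fs, n, b + systole, f_s2, 0.018, 0.25)
      if (!is.null(s2)) x[s2$idx] <- x[s2$idx] + s2$val
    }

    # murmur envelopes (zero outside systole)
    as_env <- mr_env <- numeric(n)
    for (k in seq_len(nrow(sys_win))) {
      a <- sys_win[k, 1]; bb <- sys_win[k, 2]
      i0 <- max(1L, ceiling(a * fs) + 1L)
      i1 <- min(n, floor(bb * fs) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      mid <- (a + bb) / 2; half <- (bb - a) / 2
      as_env[idx] <- 1 - abs(t[idx] - mid) / half   # diamond
      mr_env[idx] <- 1                               # holosystolic
    }
    as_amp <- if (g$AS == "severe") 0.12 * effect_size * AS_SITE_GAIN[[site]] else 0
    mr_amp <- if (g$MR == "severe") 0.12 * effect_size * MR_SITE_GAIN[[site]] else 0
    x <- x + as_amp * as_env * as_src + mr_amp * mr_env * mr_src

    list(samples = x, heart_rate = hr, beats = beats,
         systolic_windows = sys_win, s1_scale = s1_scale,
         as_amp = as_amp, mr_amp = mr_amp)
  })

  structure(list(
    samples = rec$samples, sample_rate = fs, duration = duration,
    site = site, patient_id = patient_id,
    meta = rec[c("heart_rate", "beats", "systolic_windows", "s1_scale",
                 "as_amp", "mr_amp")]),
    class = "pcg_record")
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record> site=%s, %g s @ %g Hz (%d samples), HR %.1f bpm\n",
              x$site, x$duration, x$sample_rate, length(x$samples),
              x$meta$heart_rate))
  invisible(x)
}

#' Root-mean-square amplitude inside the systolic windows of a record
#'
#' Convenience statistic for separability checks: murmurs of the emulated
#' diseases live inside systole, so their site-dependent loudness shows up
#' directly in this number.
#'
#' @param record a `pcg_record`.
#' @return RMS over all samples falling in the generator-reported systolic
#'   windows.
#' @export
systolic_rms <- function(record) {
  stopifnot(inherits(record, "pcg_record"))
  t <- (seq_along(record$samples) - 1) / record$sample_rate
  w <- record$meta$systolic_windows
  sel <- rep(FALSE, length(t))
  for (k in seq_len(nrow(w))) sel <- sel | (t >= w[k, 1] & t <= w[k, 2])
  sqrt(mean(record$samples[sel]^2))
}
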