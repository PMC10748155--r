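#' @title Phonocardiogram preprocessing
#' @description
#' Turns 15-s heart-sound records into model-ready log-Mel spectrogram
#' segments: severity-dependent oversampling into 4-s windows, a
#' non-centered short-time Fourier transform (Hann window, 512-sample
#' frames, 64-sample hop), a 128-filter triangular Mel bank spanning 0 to
#' Nyquist, and a log compression. At these defaults a 4-s window at
#' 4000 Hz yields a 243 x 128 (time x Mel) grid. Amplitudes are deliberately
#' not normalised. SpecAugment and mixup are training-time-only
#' augmentations.
#' @name pcg-frontend
NULL

#' Per-grade multiplying factors for oversampling / shift augmentation
#'
#' Severity-dependent multiplying factors: grades below severe map to 3;
#' severe maps to 20 (AS), 44 (MR) or 42 (LVD).
#'
#' @param disease `"AS"`, `"MR"` or `"LVD"`.
#' @return named integer vector over none/mild/moderate/severe.
#' @export
grade_factors <- function(disease) {
  disease <- match_one(disease, DISEASES, "disease")
  severe <- c(AS = 20L, MR = 44L, LVD = 42L)[[disease]]
  c(none = 3L, mild = 3L, moderate = 3L, severe = severe)
}

#' Phonocardiogram preprocessing parameters
#'
#' @param disease active target disease; sets the default per-grade segment
#'   counts via [grade_factors()].
#' @param window_length_s analysis window length in seconds (4).
#' @param fft_window STFT frame length in samples (512).
#' @param hop STFT hop in samples (64).
#' @param n_mels number of Mel filters (128).
#' @param segment_counts named integer vector over grades; overrides the
#'   disease default.
#' @param log_floor additive floor inside the logarithm.
#' @return list of class `pcg_preproc_params`.
#' @export
pcg_preproc_params <- function(disease = "AS", window_length_s = 4,
                               fft_window = 512L, hop = 64L, n_mels = 128L,
                               segment_counts = NULL, log_floor = 1e-6) {
  if (fft_window <= hop || hop <= 0) stopf("need fft_window > hop > 0")
  if (n_mels < 1) stopf("n_mels must be >= 1")
  counts <- segment_counts %||% grade_factors(disease)
  if (!all(GRADES %in% names(counts)))
    stopf("segment_counts must name all grades")
  if (counts[["severe"]] < counts[["none"]])
    stopf("segment_counts[severe] must be >= segment_counts[none]")
  structure(list(window_length_s = window_length_s,
                 fft_window = as.integer(fft_window), hop = as.integer(hop),
                 n_mels = as.integer(n_mels),
                 segment_counts = counts, log_floor = log_floor),
            class = "pcg_preproc_params")
}

#' Divide a record into evenly spaced analysis windows
#'
#' The number of windows is the per-grade oversampling count; start times
#' are evenly spaced over the feasible range, so windows of a record
#' oversampled more heavily overlap more.
#'
#' @param record a `pcg_record`.
#' @param params a `pcg_preproc_params`.
#' @param grade severity grade of the active disease for this record.
#' @return list of numeric sample vectors, each of
#'   `window_length_s * sample_rate` samples, with a `start_s` attribute.
#' @export
segment_record <- function(record, params, grade) {
  grade <- match_one(grade, GRADES, "grade")
  w <- params$window_length_s
  d <- record$duration
  if (d < w) stopf("record (%.2f s) shorter than window (%.2f s)", d, w)
  k <- params$segment_counts[[grade]]
  starts <- if (k == 1) 0 else (seq_len(k) - 1) * (d - w) / (k - 1)
  fs <- record$sample_rate
  wn <- round(w * fs)
  lapply(starts, function(s) {
    i0 <- round(s * fs)
    out <- record$samples[(i0 + 1):(i0 + wn)]
    attr(out, "start_s") <- s
    out
  })
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filter bank
#'
#' Filters are triangles with unit peak, centred on `n_mels` points equally
#' spaced on the Mel scale (HTK formula, 2595 log10(1 + f/700)) between 0 Hz
#' and Nyquist.
#'
#' @param n_mels number of filters.
#' @param fft_window frame length; the bank covers `fft_window/2 + 1` bins.
#' @param sample_rate sampling rate in Hz.
#' @return `n_mels` x `fft_window/2 + 1` weight matrix.
#' @export
.mel_cache <- new.env(parent = emptyenv())

mel_filterbank <- function(n_mels, fft_window, sample_rate) {
  key <- paste(n_mels, fft_window, sample_rate)
  cached <- .mel_cache[[key]]
  if (!is.null(cached)) return(cached)
  n_bins <- fft_window %/% 2L + 1L
  f_bins <- (seq_len(n_bins) - 1) * sample_rate / fft_window
  edges <- mel_to_hz(seq(0, hz_to_mel(sample_rate / 2), length.out = n_mels + 2))
  bank <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; c0 <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f_bins - lo) / (c0 - lo)
    down <- (hi - f_bins) / (hi - c0)
    bank[m, ] <- pmax(0, pmin(up, down))
  }
  .mel_cache[[key]] <- bank
  bank
}

#' Log-Mel spectrogram of one analysis window
#'
#' Non-centered framing (no padding): the frame count is
#' `1 + floor((L - fft_window) / hop)`; each frame is Hann-windowed, power
#' spectra are pooled through the Mel bank and log-compressed.
#'
#' @param window numeric sample vector (16 000 samples at the defaults).
#' @param params a `pcg_preproc_params`.
#' @param sample_rate sampling rate of the window in Hz.
#' @return `n_frames` x `n_mels` matrix (243 x 128 at the defaults) of class
#'   `log_mel_segment`.
#' @export
log_mel <- function(window, params = pcg_preproc_params(),
                    sample_rate = 4000) {
  L <- length(window)
  nfft <- params$fft_window
  if (L < nfft) stopf("window (%d samples) shorter than fft_window (%d)", L, nfft)
  hop <- params$hop
  nf <- 1L + (L - nfft) %/% hop
  idx <- outer(seq_len(nfft), (seq_len(nf) - 1L) * hop, "+")
  frames <- matrix(window[idx], nrow = nfft) * hann_window(nfft)
  spec <- Mod(stats::mvfft(frames))^2               # nfft x nf
  spec <- spec[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  bank <- mel_filterbank(params$n_mels, nfft, sample_rate)
  out <- t(bank %*% spec)                           # nf x n_mels
  out <- log(out + params$log_floor)
  structure(out, class = c("log_mel_segment", class(out)),
            start_s = attr(window, "start_s"))
}

#' SpecAugment masking
#'
#' Replaces `n_masks` random frequency bands (columns) and `n_masks` random
#' time bands (rows) with the grid mean. Mask positions come from the
#' caller's RNG stream; the operation is for the training path only.
#'
#' @param segment time x Mel matrix.
#' @param freq_mask_width,time_mask_width band widths in bins/frames
#'   (0 disables that mask type).
#' @param n_masks number of masks per axis.
#' @return masked copy of `segment`.
#' @export
spec_augment <- function(segment, freq_mask_width = 16L,
                         time_mask_width = 24L, n_masks = 2L) {
  nt <- nrow(segment); nm <- ncol(segment)
  if (freq_mask_width > nm || time_mask_width > nt)
    stopf("mask wider than axis (%d x %d grid)", nt, nm)
  fill <- mean(segment)
  for (j in seq_len(n_masks)) {
    if (freq_mask_width > 0) {
      f0 <- sample.int(nm - freq_mask_width + 1L, 1L) - 1L
      segment[, (f0 + 1L):(f0 + freq_mask_width)] <- fill
    }
    if (time_mask_width > 0) {
      t0 <- sample.int(nt - time_mask_width + 1L, 1L) - 1L
      segment[(t0 + 1L):(t0 + time_mask_width), ] <- fill
    }
  }
  segment
}

#' Mixup of two segments
#'
#' Convex combination of two equal-shape segments and of their one-hot
#' labels, with weight `lambda ~ Beta(alpha, alpha)` drawn from the caller's
#' RNG stream (training path only).
#'
#' @param seg_a,seg_b equal-shape matrices.
#' @param label_a,label_b binary labels (0/1) or soft two-vectors
#'   `(p_negative, p_positive)`.
#' @param alpha Beta concentration (> 0).
#' @param lambda optional fixed mixing weight overriding the Beta draw.
#' @return list with `values` (mixed matrix) and `label` (soft two-vector
#'   summing to 1).
#' @export
mixup <- function(seg_a, seg_b, label_a, label_b, alpha = 0.2,
                  lambda = NULL) {
  if (!all(dim(seg_a) == dim(seg_b))) stopf("segment shape mismatch")
  if (alpha <= 0) stopf("alpha must be > 0")
  lam <- lambda %||% rbeta(1, alpha, alpha)
  soft <- function(l) if (length(l) == 2) l else c(1 - l, l)
  list(values = lam * seg_a + (1 - lam) * seg_b,
       label = lam * soft(label_a) + (1 - lam) * soft(label_b))
}
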