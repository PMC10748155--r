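#' @title Synthetic scanned 12-lead ECG pages
#' @description
#' Renders a printed-and-scanned 12-lead ECG page as a grayscale raster:
#' dark traces over a white background with a light calibration grid, no
#' anti-aliasing (deterministic pixels). The page is laid out as four strips
#' of three leads: the upper half carries the six limb leads, the lower half
#' the six precordial leads. Each lead shows a sum-of-Gaussians PQRST
#' template repeated along an RR sequence.
#'
#' Disease signatures (each scaled by `effect_size`, all disabled at 0):
#' severe aortic stenosis raises precordial R-wave amplitude; severe mitral
#' regurgitation makes the RR sequence irregular and flattens the P wave;
#' severe left-ventricular dysfunction widens the QRS and lowers R amplitude.
#' @name synthetic-ecg
NULL

ECG_PAGE_WIDTH <- 3187L
ECG_PAGE_HEIGHT <- 1840L

LIMB_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF")
PRECORDIAL_LEADS <- c("V1", "V2", "V3", "V4", "V5", "V6")

# PQRST as five Gaussians; phases in seconds relative to the R peak.
pqrst_wave <- function(tt, r_amp, qrs_sigma, p_amp) {
  comp <- rbind(
    c(-0.20, p_amp, 0.035),          # P
    c(-0.04, -0.15 * r_amp, 0.012),  # Q
    c(0.00, r_amp, qrs_sigma),       # R
    c(0.04, -0.25 * r_amp, 0.015),   # S
    c(0.25, 0.30, 0.060))            # T
  y <- numeric(length(tt))
  for (i in seq_len(nrow(comp)))
    y <- y + comp[i, 2] * exp(-(tt - comp[i, 1])^2 / (2 * comp[i, 3]^2))
  y
}

#' Generate one synthetic scanned ECG page
#'
#' @inheritParams generate_pcg
#' @param page_width,page_height raster dimensions in pixels (default
#'   3187 x 1840, the scan resolution the pipeline expects).
#' @return object of class `ecg_scan`: `pixels` (integer matrix
#'   `page_height` rows x `page_width` columns, 0 = black, 255 = white),
#'   `patient_id`, and `meta` with the drawn heart rate, RR intervals,
#'   effective QRS sigma (seconds and pixels) and per-lead-group R gains.
#' @export
generate_ecg_scan <- function(disease_grades, seed, effect_size = 1,
                              page_width = ECG_PAGE_WIDTH,
                              page_height = ECG_PAGE_HEIGHT,
                              patient_id = NULL) {
  g <- check_grades(disease_grades)
  if (page_width < 12 || page_height < 8) stopf("page size not positive/usable")
  if (!is.numeric(effect_size) || length(effect_size) != 1 || effect_size < 0)
    stopf("effect_size must be a nonnegative scalar")

  res <- with_seed(seed, {
    hr <- runif(1, 60, 100)
    period <- 60 / hr
    rr_jitter <- rnorm(64, 0, 0.012)          # always drawn
    lead_gain <- runif(12, 0.75, 1.25)
    p_amp0 <- runif(1, 0.10, 0.16)
    qrs_sigma0 <- runif(1, 0.016, 0.022)

    as_on <- g$AS == "severe"; mr_on <- g$MR == "severe"; lvd_on <- g$LVD == "severe"
    qrs_sigma <- qrs_sigma0 * (1 + (if (lvd_on) effect_size else 0))
    r_gain_limb <- 1 / (1 + (if (lvd_on) 0.5 * effect_size else 0))
    r_gain_prec <- r_gain_limb * (1 + (if (as_on) 0.6 * effect_size else 0))
    p_amp <- p_amp0 / (1 + (if (mr_on) effect_size else 0))
    jitter_scale <- 1 + (if (mr_on) 5 * effect_size else 0)
    rr <- period * (1 + jitter_scale * rr_jitter)
    beat_times <- cumsum(c(0.3 * period, rr))

    list(hr = hr, rr = rr, beat_times = beat_times, lead_gain = lead_gain,
         p_amp = p_amp, qrs_sigma = qrs_sigma,
         r_gain_limb = r_gain_limb, r_gain_prec = r_gain_prec)
  })

  img <- matrix(255L, nrow = page_height, ncol = page_width)
  # light calibration grid
  grid_step <- max(8L, round(40 * page_height / ECG_PAGE_HEIGHT))
  img[seq(1L, page_height, by = grid_step), ] <- 225L
  img[, seq(1L, page_width, by = grid_step)] <- 225L

  band_h <- page_height %/% 4L
  cell_w <- page_width %/% 3L
  seconds_per_cell <- 2.5
  pps <- cell_w / seconds_per_cell          # pixels per second
  amp_px <- 0.30 * band_h                   # pixels per unit amplitude
  leads <- c(LIMB_LEADS, PRECORDIAL_LEADS)

  for (li in seq_along(leads)) {
    strip <- (li - 1L) %/% 3L               # 0..3 top to bottom
    colix <- (li - 1L) %% 3L
    y_c <- strip * band_h + band_h %/% 2L
    x0 <- colix * cell_w
    t_off <- colix * seconds_per_cell
    r_gain <- if (li <= 6L) res$r_gain_limb else res$r_gain_prec
    tt <- t_off + (seq_len(cell_w) - 1) / pps
    y <- numeric(cell_w)
    for (b in res$beat_times) {
      if (b > max(tt) + 0.5 || b < min(tt) - 0.5) next
      y <- y + pqrst_wave(tt - b, r_gain * res$lead_gain[li],
                          res$qrs_sigma, res$p_amp)
    }
    yr <- y_c - round(y * amp_px)
    yr <- pmax(strip * band_h + 2L, pmin((strip + 1L) * band_h - 1L, yr))
    lo <- pmin(yr[-1L], yr[-cell_w]); hi <- pmax(yr[-1L], yr[-cell_w])
    lens <- hi - lo + 1L
    rows <- sequence(lens) - 1L + rep(lo, lens)
    cols <- rep(x0 + 2:cell_w, lens)
    img[cbind(rows, cols)] <- 20L
    img[cbind(pmin(rows + 1L, page_height), cols)] <- 20L
  }

  structure(list(
    pixels = img, patient_id = patient_id,
    meta = list(heart_rate = res$hr, rr_intervals = res$rr,
                qrs_sigma_s = res$qrs_sigma,
                qrs_sigma_px = res$qrs_sigma * pps,
                r_gain_limb = res$r_gain_limb,
                r_gain_precordial = res$r_gain_prec,
                p_amp = res$p_amp, layout = list(
                  band_height = band_h, cell_width = cell_w,
                  pixels_per_second = pps))),
    class = "ecg_scan")
}

#' @export
print.ecg_scan <- function(x, ...) {
  cat(sprintf("<ecg_scan> %d x %d px (width x height), HR %.1f bpm\n",
              ncol(x$pixels), nrow(x$pixels), x$meta$heart_rate))
  invisible(x)
}
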