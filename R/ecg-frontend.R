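#' @title Scanned-ECG preprocessing
#' @description
#' Crops a scanned 12-lead page into the three model-input views and
#' resizes them: the full-height square (all 12 leads, 1840 x 1840 resized
#' to 512 x 512), a 960 x 960 square from the upper half (limb leads) and a
#' 960 x 960 square from the lower half (precordial leads), both resized to
#' 256 x 256. Severity-dependent horizontal shifting of the cropping window
#' provides augmentation. Coordinates are 0-based with row 0 at the top;
#' pages are single-channel grayscale.
#' @name ecg-frontend
NULL

ECG_VIEWS <- c("all12", "limb", "precordial")

#' ECG cropping / resizing parameters
#'
#' Defaults follow the standard page geometry: view `all12` crops the
#' full-height 1840-pixel square and resizes to 512; `limb` and
#' `precordial` crop 960-pixel squares from the upper / lower half and
#' resize to 256. Default shift offsets are chosen so the largest per-grade
#' factor (x44) stays on the 3187-pixel page: 31 px for `all12`,
#' 51 px for the half views.
#'
#' @param view `"all12"`, `"limb"` or `"precordial"`.
#' @param disease active target disease, setting `shift_counts` via
#'   [grade_factors()].
#' @param crop_side crop square side in pixels.
#' @param resize_to output side in pixels.
#' @param shift_offset horizontal shift per augmentation iteration (px).
#' @param shift_counts named integer vector over grades.
#' @param origin horizontal anchor (0-based column) of the first crop.
#' @param scale scale factor applied to the pixel-valued defaults, for
#'   reduced-size pages (e.g. `0.25` with a 797 x 460 page).
#' @return list of class `ecg_crop_params`.
#' @export
ecg_crop_params <- function(view, disease = "AS", crop_side = NULL,
                            resize_to = NULL, shift_offset = NULL,
                            shift_counts = NULL, origin = 0L, scale = 1) {
  view <- match_one(view, ECG_VIEWS, "view")
  def <- switch(view,
    all12 = list(crop = 1840L, out = 512L, off = 31L),
    limb = ,
    precordial = list(crop = 960L, out = 256L, off = 51L))
  counts <- shift_counts %||% grade_factors(disease)
  if (counts[["severe"]] < counts[["none"]])
    stopf("shift_counts[severe] must be >= shift_counts[none]")
  structure(list(
    view = view,
    crop_side = as.integer(crop_side %||% round(def$crop * scale)),
    resize_to = as.integer(resize_to %||% round(def$out * scale)),
    shift_offset = as.integer(shift_offset %||% max(1L, round(def$off * scale))),
    shift_counts = counts, origin = as.integer(origin)),
    class = "ecg_crop_params")
}

as_pixels <- function(scan) {
  if (inherits(scan, "ecg_scan")) scan$pixels else scan
}

#' Crop one view from a scanned page
#'
#' @param scan an `ecg_scan` or a pixel matrix (rows = page rows, top first).
#' @param params an `ecg_crop_params`.
#' @param origin optional override of the horizontal anchor (0-based).
#' @return `crop_side` x `crop_side` pixel matrix. The `all12` view spans
#'   the full page height; `limb` is anchored to the top edge, `precordial`
#'   to the bottom edge (its centre lies in the lower half of the page).
#' @export
crop_view <- function(scan, params, origin = NULL) {
  px <- as_pixels(scan)
  h <- nrow(px); w <- ncol(px)
  s <- params$crop_side
  x0 <- origin %||% params$origin
  if (x0 < 0 || x0 + s > w)
    stopf("crop [%d, %d) exceeds page width %d", x0, x0 + s, w)
  rows <- switch(params$view,
    all12 = {
      if (s != h) stopf("all12 crop side %d must equal page height %d", s, h)
      seq_len(h)
    },
    limb = {
      if (s > h) stopf("crop side %d exceeds page height %d", s, h)
      seq_len(s)
    },
    precordial = {
      if (s > h) stopf("crop side %d exceeds page height %d", s, h)
      (h - s + 1L):h
    })
  px[rows, (x0 + 1L):(x0 + s), drop = FALSE]
}

bilinear_weights <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- pmax(0L, pmin(n_in - 1L, floor(src)))
  i1 <- pmin(n_in - 1L, i0 + 1L)
  frac <- pmax(0, pmin(1, src - i0))
  w <- matrix(0, n_out, n_in)
  w[cbind(seq_len(n_out), i0 + 1L)] <- 1 - frac
  w[cbind(seq_len(n_out), i1 + 1L)] <- w[cbind(seq_len(n_out), i1 + 1L)] + frac
  w
}

#' Bilinear resize of a square image
#'
#' @param image square pixel matrix.
#' @param resize_to output side in pixels, or an `ecg_crop_params` whose
#'   `resize_to` is used.
#' @return `resize_to` x `resize_to` numeric matrix; intensity range is
#'   preserved up to interpolation.
#' @export
resize_view <- function(image, resize_to) {
  if (inherits(resize_to, "ecg_crop_params")) resize_to <- resize_to$resize_to
  if (nrow(image) != ncol(image))
    stopf("resize_view expects a square input, got %d x %d",
          nrow(image), ncol(image))
  n <- nrow(image)
  if (n == resize_to) return(image * 1)
  w <- bilinear_weights(resize_to, n)
  w %*% image %*% t(w)
}

#' Severity-dependent shift augmentation
#'
#' Crops the page `shift_counts[grade]` times, advancing the horizontal
#' anchor by `shift_offset` pixels per iteration, and resizes each crop.
#'
#' @param scan an `ecg_scan` or pixel matrix.
#' @param params an `ecg_crop_params`.
#' @param grade severity grade of the active disease.
#' @return list of `resize_to` x `resize_to` matrices, one per shift, each
#'   with a `shift_px` attribute.
#' @export
shift_augment <- function(scan, params, grade) {
  grade <- match_one(grade, GRADES, "grade")
  px <- as_pixels(scan)
  k <- params$shift_counts[[grade]]
  w <- ncol(px)
  need <- params$origin + (k - 1L) * params$shift_offset + params$crop_side
  if (need > w) {
    feasible <- if (params$shift_offset > 0)
      (w - params$origin - params$crop_side) %/% params$shift_offset + 1L
    else Inf
    stopf("cannot place %d crops (page width %d, maximal feasible count %d)",
          k, w, feasible)
  }
  lapply(seq_len(k) - 1L, function(i) {
    img <- resize_view(crop_view(px, params,
                                 origin = params$origin + i * params$shift_offset),
                       params$resize_to)
    attr(img, "shift_px") <- i * params$shift_offset
    img
  })
}
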