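#' @title Synthetic patient cohorts
#' @description
#' Draws per-patient severity grades for the three screening targets from
#' configurable prevalence distributions, assigns each patient a private
#' record seed, and exposes the three-site phonocardiograms and the scanned
#' ECG page either as files (WAV / PNG plus a CSV manifest and JSON metadata
#' sidecar) or regenerated on demand from the stored seeds - every record is
#' a pure function of (grades, seed, effect size), so nothing needs to be
#' cached.
#' @name synthetic-cohort
NULL

#' Default grade prevalences
#'
#' AS and MR follow the grade proportions of the emulated screening
#' population (no/I/II/III = 785/68/66/132 and 469/385/130/67 of 1051
#' patients); ventricular-dysfunction grades are not tabulated there and
#' default to 78/8/6/8 percent.
#'
#' @return named list of per-disease probability vectors over
#'   none/mild/moderate/severe.
#' @export
default_prevalences <- function() {
  list(
    AS = c(none = 785, mild = 68, moderate = 66, severe = 132) / 1051,
    MR = c(none = 469, mild = 385, moderate = 130, severe = 67) / 1051,
    LVD = c(none = 0.78, mild = 0.08, moderate = 0.06, severe = 0.08))
}

norm_effect <- function(effect_size) {
  if (is.list(effect_size)) {
    e <- list(pcg = effect_size$pcg %||% 0, ecg = effect_size$ecg %||% 0)
  } else {
    e <- list(pcg = effect_size, ecg = effect_size)
  }
  if (any(unlist(e) < 0)) stopf("effect sizes must be nonnegative")
  e
}

check_prevalences <- function(prevalences) {
  for (d in DISEASES) {
    p <- prevalences[[d]]
    if (is.null(p) || length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stopf("invalid grade distribution for %s: must be 4 nonnegative values summing to 1", d)
  }
  prevalences
}

#' Generate a synthetic cohort
#'
#' @param n number of patients (>= 1).
#' @param prevalences named list of per-disease grade distributions over
#'   none/mild/moderate/severe; see [default_prevalences()].
#' @param seed integer seed controlling grades and per-patient record seeds.
#' @param effect_size scalar, or list with elements `pcg` and `ecg`, scaling
#'   the disease signatures planted in each modality (a list with `ecg = 0`
#'   plants signal in the heart sounds only).
#' @param dir if non-`NULL`, records are written below this directory
#'   (`<id>_<site>.wav`, `<id>_ecg.png`) together with `manifest.csv` and
#'   `cohort_meta.json`; otherwise records are regenerated on demand.
#' @param duration,sample_rate phonocardiogram length (s) and rate (Hz).
#' @param page_width,page_height ECG page raster size in pixels.
#' @return object of class `cohort_manifest`: `$patients` data frame
#'   (patient_id, per-disease grade and binary target, record seeds, file
#'   paths or NA, split/fold tags initialised to NA) plus the generator
#'   parameters in `$params`.
#' @export
generate_cohort <- function(n, prevalences = default_prevalences(), seed = 1,
                            effect_size = 1, dir = NULL,
                            duration = 15, sample_rate = 4000,
                            page_width = ECG_PAGE_WIDTH,
                            page_height = ECG_PAGE_HEIGHT) {
  if (n < 1) stopf("n must be >= 1")
  check_prevalences(prevalences)
  eff <- norm_effect(effect_size)

  drawn <- with_seed(seed, {
    grades <- lapply(DISEASES, function(d)
      sample(GRADES, n, replace = TRUE, prob = prevalences[[d]]))
    names(grades) <- DISEASES
    list(grades = grades,
         pcg_seeds = sample.int(2147483646L, n),
         ecg_seeds = sample.int(2147483646L, n))
  })

  ids <- sprintf("P%04d", seq_len(n))
  patients <- data.frame(
    patient_id = ids,
    as_grade = drawn$grades$AS, mr_grade = drawn$grades$MR,
    lvd_grade = drawn$grades$LVD,
    as_target = grade_to_target(drawn$grades$AS),
    mr_target = grade_to_target(drawn$grades$MR),
    lvd_target = grade_to_target(drawn$grades$LVD),
    pcg_seed = drawn$pcg_seeds, ecg_seed = drawn$ecg_seeds,
    pcg_2RSB = NA_character_, pcg_ERB = NA_character_,
    pcg_APX = NA_character_, ecg_scan = NA_character_,
    split = NA_character_, fold = NA_integer_,
    stringsAsFactors = FALSE)

  cohort <- structure(list(
    patients = patients,
    params = list(effect_size = eff, duration = duration,
                  sample_rate = sample_rate, page_width = page_width,
                  page_height = page_height, seed = seed,
                  prevalences = prevalences)),
    class = "cohort_manifest")

  if (!is.null(dir)) cohort <- write_cohort(cohort, dir)
  cohort
}

patient_grades <- function(cohort, i) {
  p <- cohort$patients[i, ]
  list(AS = p$as_grade, MR = p$mr_grade, LVD = p$lvd_grade)
}

#' Fetch one phonocardiogram of a cohort patient
#'
#' Reads the WAV file when the cohort was written to disk, otherwise
#' regenerates the record from the patient's stored seed.
#'
#' @param cohort a `cohort_manifest`.
#' @param i patient row index or patient id.
#' @param site auscultation site (`"2RSB"`, `"ERB"`, `"APX"`).
#' @return a `pcg_record`.
#' @export
cohort_pcg <- function(cohort, i, site) {
  site <- match_one(site, PCG_SITES, "auscultation site")
  if (is.character(i)) i <- match(i, cohort$patients$patient_id)
  p <- cohort$patients[i, ]
  path <- p[[paste0("pcg_", site)]]
  if (!is.na(path) && file.exists(path)) {
    wav <- read_wav(path)
    # rebuild metadata (systolic windows) from the generating seed
    rec <- generate_pcg(patient_grades(cohort, i), site, p$pcg_seed,
                        cohort$params$effect_size$pcg,
                        cohort$params$duration, cohort$params$sample_rate,
                        patient_id = p$patient_id)
    rec$samples <- wav$samples
    return(rec)
  }
  generate_pcg(patient_grades(cohort, i), site, p$pcg_seed,
               cohort$params$effect_size$pcg, cohort$params$duration,
               cohort$params$sample_rate, patient_id = p$patient_id)
}

#' Fetch the scanned ECG page of a cohort patient
#'
#' @inheritParams cohort_pcg
#' @return an `ecg_scan`.
#' @export
cohort_ecg <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$patients$patient_id)
  p <- cohort$patients[i, ]
  if (!is.na(p$ecg_scan) && file.exists(p$ecg_scan)) {
    scan <- generate_ecg_scan(patient_grades(cohort, i), p$ecg_seed,
                              cohort$params$effect_size$ecg,
                              cohort$params$page_width,
                              cohort$params$page_height,
                              patient_id = p$patient_id)
    scan$pixels <- read_png_gray(p$ecg_scan)
    return(scan)
  }
  generate_ecg_scan(patient_grades(cohort, i), p$ecg_seed,
                    cohort$params$effect_size$ecg, cohort$params$page_width,
                    cohort$params$page_height, patient_id = p$patient_id)
}

#' Write a cohort's records, manifest and metadata sidecar to a directory
#'
#' @param cohort a `cohort_manifest`.
#' @param dir target directory (created if missing).
#' @return the cohort with file-path columns filled in.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create directory %s", dir)
  pts <- cohort$patients
  for (i in seq_len(nrow(pts))) {
    id <- pts$patient_id[i]
    for (site in PCG_SITES) {
      rec <- cohort_pcg(cohort, i, site)
      path <- file.path(dir, sprintf("%s_%s.wav", id, site))
      write_wav(rec$samples, path, rec$sample_rate)
      pts[[paste0("pcg_", site)]][i] <- path
    }
    scan <- cohort_ecg(cohort, i)
    path <- file.path(dir, sprintf("%s_ecg.png", id))
    write_png_gray(scan$pixels, path)
    pts$ecg_scan[i] <- path
  }
  cohort$patients <- pts
  write.csv(pts, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$params, file.path(dir, "cohort_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  cohort
}

#' Read a cohort manifest back from a directory
#'
#' @param dir directory previously populated by [write_cohort()].
#' @return a `cohort_manifest`.
#' @export
read_cohort <- function(dir) {
  man <- file.path(dir, "manifest.csv")
  if (!file.exists(man)) stopf("no manifest.csv under %s", dir)
  patients <- read.csv(man, stringsAsFactors = FALSE)
  params <- jsonlite::read_json(file.path(dir, "cohort_meta.json"),
                                simplifyVector = TRUE)
  params$prevalences <- lapply(params$prevalences, unlist)
  structure(list(patients = patients, params = params),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  p <- x$patients
  cat(sprintf("<cohort_manifest> %d patients (severe AS %d, MR %d, LVD %d)%s\n",
              nrow(p), sum(p$as_target), sum(p$mr_target), sum(p$lvd_target),
              if (all(is.na(p$ecg_scan))) ", in-memory" else ", on disk"))
  invisible(x)
}
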