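# VOI volumetry: per-kidney and total parenchymal volume, mean T2 intensity
# and mean ADC, normative-band comparison, and age-volume correlation.

#' Normative total renal volume table (normal population, 6-48 months)
#'
#' Half-year age bands with the population mean total renal volume and the
#' mean +/- 2 SD limits (cm^3), as packaged with the installed package.
#'
#' @return data.frame with columns age_lo, age_hi, n_subjects, upper_cm3,
#'   mean_cm3, lower_cm3.
#' @export
normative_table <- function() {
  path <- system.file("extdata", "normative_renal_volume.csv", package = "renalrad")
  if (path == "") path <- file.path("inst", "extdata", "normative_renal_volume.csv")
  utils::read.csv(path)
}

#' Per-subject VOI summary
#'
#' Volume = voxel count x voxel volume (reported in cm^3), computed per kidney;
#' the total is the exact sum of left and right. Mean T2 intensity and mean ADC
#' are taken over the union of the two parenchyma masks on the raw
#' (unfiltered) images.
#'
#' @param subject a `subject_volumes` object (see [generate_kidney_phantom()]).
#' @return one-row data.frame: subject_id, left_volume_cm3, right_volume_cm3,
#'   total_volume_cm3, mean_t2_intensity, mean_adc.
#' @export
compute_voi_summary <- function(subject) {
  stopifnot(all(subject$spacing > 0))
  nl <- sum(subject$mask_left); nr <- sum(subject$mask_right)
  if (nl == 0 || nr == 0) {
    stop("empty VOI: mask_", if (nl == 0) "left" else "right",
         " contains no voxels for subject ", subject$subject_id)
  }
  voxvol_cm3 <- prod(subject$spacing) / 1000
  mask <- subject$mask_left | subject$mask_right
  lv <- nl * voxvol_cm3; rv <- nr * voxvol_cm3
  data.frame(subject_id = subject$subject_id,
             left_volume_cm3 = lv, right_volume_cm3 = rv,
             total_volume_cm3 = lv + rv,
             mean_t2_intensity = mean(subject$t2w[mask]),
             mean_adc = mean(subject$adc[mask]))
}

#' Look up the normative volume band for an age
#'
#' Band membership is half-open on half-year intervals labelled
#' 6-11.99, 12-17.99, ..., 42-47.99 months; age 48 exactly is out of range.
#'
#' @param age_months numeric age in months, 6 <= age < 48.
#' @return list(age_band = c(lo, hi), upper_cm3, mean_cm3, lower_cm3).
#' @export
normative_lookup <- function(age_months) {
  if (is.na(age_months) || age_months < 6 || age_months >= 48) {
    stop("age ", age_months, " months is outside the normative range [6, 48)")
  }
  tab <- normative_table()
  row <- tab[age_months >= tab$age_lo & age_months < tab$age_lo + 6, ]
  stopifnot(nrow(row) == 1L)
  list(age_band = c(row$age_lo, row$age_hi), upper_cm3 = row$upper_cm3,
       mean_cm3 = row$mean_cm3, lower_cm3 = row$lower_cm3)
}

#' Classify a total renal volume against a normative band
#'
#' Strict inequalities: a volume is `"above"` only if it exceeds the upper
#' limit, `"below"` only if it is under the lower limit; boundary values are
#' `"within"`.
#'
#' @param total_volume_cm3 total renal volume.
#' @param band result of [normative_lookup()].
#' @return `"above"`, `"within"` or `"below"`.
#' @export
classify_vs_normative <- function(total_volume_cm3, band) {
  if (total_volume_cm3 > band$upper_cm3) "above"
  else if (total_volume_cm3 < band$lower_cm3) "below"
  else "within"
}

#' Pearson age-volume correlation within one genotype class
#'
#' @param records clinical data.frame (subject_id, age_months, class_label).
#' @param summaries data.frame of VOI summaries (subject_id, total_volume_cm3).
#' @param class_label class to subset, or NULL for all subjects.
#' @return list(r, p, n) from the two-sided t transform.
#' @export
age_volume_correlation <- function(records, summaries, class_label = NULL) {
  m <- merge(records[, c("subject_id", "age_months", "class_label")],
             summaries[, c("subject_id", "total_volume_cm3")],
             by = "subject_id")
  if (!is.null(class_label)) m <- m[m$class_label == class_label, ]
  if (nrow(m) < 3) stop("need at least 3 subjects for a correlation")
  if (stats::sd(m$age_months) == 0 || stats::sd(m$total_volume_cm3) == 0) {
    stop("degenerate input: constant age or volume series")
  }
  ct <- stats::cor.test(m$age_months, m$total_volume_cm3, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}

#' Volumetry report for a cohort
#'
#' @param subjects list of `subject_volumes`.
#' @param clinical clinical data.frame (for ages).
#' @return data.frame of VOI summaries with the normative classification
#'   (`"above"`/`"within"`/`"below"`) appended where the age is in range.
#' @export
volumetry_report <- function(subjects, clinical) {
  out <- do.call(rbind, lapply(subjects, compute_voi_summary))
  out <- merge(out, clinical[, c("subject_id", "age_months", "class_label")],
               by = "subject_id")
  out$vs_normative <- vapply(seq_len(nrow(out)), function(i) {
    if (out$age_months[i] >= 6 && out$age_months[i] < 48) {
      classify_vs_normative(out$total_volume_cm3[i],
                            normative_lookup(out$age_months[i]))
    } else NA_character_
  }, character(1))
  out
}
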