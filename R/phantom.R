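# Synthetic kidney-MRI phantom cohorts.
#
# Each subject is a pair of axis-aligned ellipsoidal kidneys rasterized on a
# regular grid. The parenchyma mask excludes a concentric central cavity
# standing in for the renal collecting system, so that masks are
# parenchyma-only by construction. T2 texture is a Gaussian random field whose
# correlation length differs between the two genotype classes; ADC values are
# drawn around a class-specific subject mean. Class differences in total
# volume, age-volume coupling, lesion incidence and clinical-flag rates follow
# the defaults in [cohort_spec()].

CLINICAL_FLAGS <- c("hemihypertrophy", "macrosomia", "nevus_flammeus",
                    "ear_creases_pits", "omphalocele_umbilical_hernia",
                    "renal_anomaly", "nonrenal_abdominal_anomaly")

CLASS_LABELS <- c("UPD+IC1", "IC2")

#' Cohort specification for the phantom generator
#'
#' Defaults encode the two genotype classes the analysis assumes: a renal
#' predisposition class with larger kidneys (median total volume about
#' 116 cm^3 at the mid-range age), weaker age-volume coupling (Pearson r
#' about 0.38), short texture correlation length, and higher benign renal
#' lesion incidence; and a second class with median volume about 91 cm^3,
#' r about 0.71 and smoother parenchyma. ADC class means are 1340.13 and
#' 1343.81 (10^-6 mm^2/s scale) with SDs 67.53 and 75.81. Clinical-flag
#' Bernoulli rates per class follow the observed incidences (for example
#' omphalocele/umbilical hernia 0.375 vs 0.68, ear creases/pits 0.1667 vs
#' 0.40, renal anomaly 0.375 vs 0.08).
#'
#' The volume model is linear in age, `total = intercept + slope * age + N(0, sd)`,
#' with ages drawn uniformly on integer months 6..48 (SD 12.41). The default
#' slopes/SDs are solved so that the analytic Pearson correlation
#' `slope * SD_age / SD_total` equals the per-class targets 0.38 and 0.71 and
#' the volume at the mean age (27 months) equals the class medians.
#'
#' @param n_per_class integer length 1 or 2; subjects per class (default 24, 25).
#' @param age_range integer months, inclusive; default c(6, 48).
#' @param volume_model per-class list(intercept, slope, sd) in cm^3 (vs months).
#' @param texture_model per-class list(corr_mm, amplitude) for the T2 random field.
#' @param adc_model per-class list(mean, sd, corr_mm, amplitude) on the 10^-6 mm^2/s scale.
#' @param lesion_model per-class list(rate) of cyst-like hyperintense inclusions.
#' @param clinical_rates per-class named vector of Bernoulli rates over
#'   the declared phenotype flags.
#' @param sex_male_rate per-class male probability.
#' @param t2_base baseline parenchymal T2 signal (a.u.).
#' @param grid list(shape, spacing_mm); default 96 x 96 x 32 voxels at
#'   0.9375 x 0.9375 x 5 mm (240 mm FOV / 256 matrix; 4 mm slices + 1 mm gap).
#' @param master_seed integer master seed; all per-subject substreams derive
#'   from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(24L, 25L),
                        age_range = c(6L, 48L),
                        volume_model = list(
                          "UPD+IC1" = list(intercept = 91.88, slope = 0.90, sd = 27.18),
                          "IC2"     = list(intercept = 64.46, slope = 1.00, sd = 12.31)),
                        texture_model = list(
                          "UPD+IC1" = list(corr_mm = 2, amplitude = 45),
                          "IC2"     = list(corr_mm = 6, amplitude = 45)),
                        adc_model = list(
                          "UPD+IC1" = list(mean = 1340.13, sd = 67.53, corr_mm = 2, amplitude = 80),
                          "IC2"     = list(mean = 1343.81, sd = 75.81, corr_mm = 6, amplitude = 80)),
                        lesion_model = list(
                          "UPD+IC1" = list(rate = 0.375),
                          "IC2"     = list(rate = 0.08)),
                        clinical_rates = list(
                          "UPD+IC1" = c(hemihypertrophy = 11 / 24, macrosomia = 11 / 24,
                                        nevus_flammeus = 3 / 24, ear_creases_pits = 4 / 24,
                                        omphalocele_umbilical_hernia = 9 / 24,
                                        renal_anomaly = 9 / 24,
                                        nonrenal_abdominal_anomaly = 7 / 24),
                          "IC2"     = c(hemihypertrophy = 9 / 25, macrosomia = 6 / 25,
                                        nevus_flammeus = 9 / 25, ear_creases_pits = 10 / 25,
                                        omphalocele_umbilical_hernia = 17 / 25,
                                        renal_anomaly = 2 / 25,
                                        nonrenal_abdominal_anomaly = 0)),
                        sex_male_rate = c("UPD+IC1" = 10 / 24, "IC2" = 17 / 25),
                        t2_base = 372,
                        grid = list(shape = c(96L, 96L, 32L),
                                    spacing = c(0.9375, 0.9375, 5)),
                        master_seed = 1L) {
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, 2L)
  stopifnot(all(n_per_class >= 2L), length(age_range) == 2L,
            age_range[1] >= 6, age_range[2] <= 48,
            all(grid$spacing > 0), length(grid$shape) == 3L)
  for (cl in CLASS_LABELS) {
    r <- clinical_rates[[cl]]
    if (!all(CLINICAL_FLAGS %in% names(r))) {
      stop("clinical_rates for class ", cl, " must cover every declared flag")
    }
    if (any(r < 0 | r > 1)) stop("clinical rates must lie in [0,1]")
    if (volume_model[[cl]]$sd < 0) stop("volume noise SD must be >= 0")
  }
  structure(list(n_per_class = as.integer(n_per_class), age_range = age_range,
                 volume_model = volume_model, texture_model = texture_model,
                 adc_model = adc_model, lesion_model = lesion_model,
                 clinical_rates = clinical_rates, sex_male_rate = sex_male_rate,
                 t2_base = t2_base, grid = grid,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Voxel-centre coordinates (mm) along each axis.
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * spacing[a])
}

# Rasterize an axis-aligned ellipsoid shell (outer minus concentric cavity).
rasterize_kidney <- function(shape, spacing, centre, semi, cavity_scale) {
  cx <- grid_coords(shape, spacing)
  dx2 <- ((cx[[1]] - centre[1]) / semi[1])^2
  dy2 <- ((cx[[2]] - centre[2]) / semi[2])^2
  dz2 <- ((cx[[3]] - centre[3]) / semi[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  outer_in <- q <= 1
  cavity_in <- q <= cavity_scale^2   # concentric, same axis ratios
  outer_in & !cavity_in
}

# Gaussian random field: unit-variance smoothed white noise (reflect boundary).
grf_field <- function(shape, spacing, corr_mm) {
  w <- array(stats::rnorm(prod(shape)), shape)
  for (a in 1:3) {
    k <- gaussian_kernel(corr_mm / spacing[a])
    if (length(k) > 1L) w <- conv_axis(w, k, a, "reflect")
  }
  s <- stats::sd(w)
  if (s > 0) w <- w / s
  w
}

#' Generate one phantom subject
#'
#' Draws the subject's total renal volume from the class volume model, splits
#' it between two ellipsoidal kidneys (left fraction uniform on 0.47..0.53),
#' rasterizes parenchyma-only masks (a concentric central cavity emulating the
#' collecting system is excluded, and the outer ellipsoid is inflated so the
#' parenchymal volume matches the drawn total analytically), then paints T2
#' and ADC intensities.
#'
#' @param spec a [cohort_spec()].
#' @param class_label `"UPD+IC1"` or `"IC2"`.
#' @param age_months integer age within the spec range.
#' @param subject_seed integer substream seed (see [derive_seed()] usage in
#'   [generate_cohort()]).
#' @param subject_id identifier string.
#' @return object of class `subject_volumes`: list(t2w, adc, mask_left,
#'   mask_right, spacing, subject_id, meta) where meta records the drawn
#'   volumes and lesion count.
#' @export
generate_kidney_phantom <- function(spec, class_label, age_months, subject_seed,
                                    subject_id = "S1") {
  stopifnot(inherits(spec, "cohort_spec"))
  class_label <- match.arg(class_label, CLASS_LABELS)
  if (age_months < spec$age_range[1] || age_months > spec$age_range[2]) {
    stop("age ", age_months, " months outside the configured range [",
         spec$age_range[1], ",", spec$age_range[2], "]")
  }
  shape <- spec$grid$shape; spacing <- spec$grid$spacing
  vm <- spec$volume_model[[class_label]]
  tm <- spec$texture_model[[class_label]]
  am <- spec$adc_model[[class_label]]
  lm <- spec$lesion_model[[class_label]]
  cavity_scale <- 0.35  # cavity volume fraction = 0.35^3 ~ 4.3% of outer ellipsoid

  with_seed(subject_seed, {
    total_cm3 <- max(30, vm$intercept + vm$slope * age_months +
                       stats::rnorm(1, 0, vm$sd))
    ufrac <- stats::runif(1, 0.47, 0.53)
    vols <- c(left = total_cm3 * ufrac, right = total_cm3 * (1 - ufrac))

    fov <- shape * spacing
    masks <- list()
    for (side in c("left", "right")) {
      v_out_mm3 <- vols[[side]] * 1000 / (1 - cavity_scale^3)
      ratios <- c(0.45, 0.62, 1) * c(1, stats::runif(2, 0.95, 1.05))
      kappa <- (v_out_mm3 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
      semi <- kappa * ratios
      centre <- c(fov[1] * ifelse(side == "left", 0.25, 0.75),
                  fov[2] * 0.5 + stats::runif(1, -2, 2),
                  fov[3] * 0.5 + stats::runif(1, -2, 2))
      if (semi[1] > fov[1] * 0.25 || semi[2] > fov[2] * 0.45 ||
          semi[3] > fov[3] * 0.48) {
        stop("requested volume ", round(vols[[side]], 1),
             " cm^3 not realizable on the configured grid (capacity error)")
      }
      masks[[side]] <- rasterize_kidney(shape, spacing, centre, semi, cavity_scale)
    }
    mask <- masks$left | masks$right

    t2 <- array(0, shape)
    t2_field <- spec$t2_base + tm$amplitude * grf_field(shape, spacing, tm$corr_mm)
    t2[mask] <- t2_field[mask]

    adc <- array(0, shape)
    subj_mean <- stats::rnorm(1, am$mean, am$sd)
    adc_field <- subj_mean + am$amplitude * grf_field(shape, spacing, am$corr_mm)
    adc[mask] <- adc_field[mask]

    n_lesions <- stats::rbinom(1, 1, lm$rate)
    if (n_lesions > 0) {
      cx <- grid_coords(shape, spacing)
      for (l in seq_len(n_lesions)) {
        side <- sample(c("left", "right"), 1)
        vox <- which(masks[[side]], arr.ind = TRUE)
        c0 <- vox[sample(nrow(vox), 1), ]
        centre <- c(cx[[1]][c0[1]], cx[[2]][c0[2]], cx[[3]][c0[3]])
        rad <- stats::runif(1, 3, 6)
        d2 <- outer(outer((cx[[1]] - centre[1])^2, (cx[[2]] - centre[2])^2, "+"),
                    (cx[[3]] - centre[3])^2, "+")
        inles <- d2 <= rad^2 & mask
        t2[inles] <- t2[inles] + 8 * tm$amplitude   # hyperintense, > 6-SD envelope
        adc[inles] <- adc[inles] + 4 * am$amplitude
      }
    }

    structure(list(t2w = t2, adc = adc,
                   mask_left = masks$left, mask_right = masks$right,
                   spacing = spacing, subject_id = subject_id,
                   meta = list(class_label = class_label,
                               age_months = age_months,
                               target_total_cm3 = total_cm3,
                               target_left_cm3 = vols[["left"]],
                               target_right_cm3 = vols[["right"]],
                               n_lesions = n_lesions,
                               seed = subject_seed)),
              class = "subject_volumes")
  })
}

#' Generate the clinical covariate table
#'
#' Ages are uniform integer months over the configured range, sex and every
#' phenotype flag are independent Bernoulli draws at the class rates, all
#' deterministic under the spec's master seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns subject_id, age_months, sex, class_label
#'   and one 0/1 column per declared flag.
#' @export
generate_clinical_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$master_seed, 0L), {
    rows <- list()
    idx <- 0L
    for (ci in seq_along(CLASS_LABELS)) {
      cl <- CLASS_LABELS[ci]
      n <- spec$n_per_class[ci]
      rates <- spec$clinical_rates[[cl]][CLINICAL_FLAGS]
      if (any(is.na(rates))) stop("missing rate for a declared flag in class ", cl)
      for (s in seq_len(n)) {
        idx <- idx + 1L
        flags <- stats::rbinom(length(CLINICAL_FLAGS), 1, rates)
        names(flags) <- CLINICAL_FLAGS
        rows[[idx]] <- data.frame(
          subject_id = sprintf("S%03d", idx),
          age_months = sample(seq(spec$age_range[1], spec$age_range[2]), 1),
          sex = ifelse(stats::rbinom(1, 1, spec$sex_male_rate[[cl]]) == 1, "M", "F"),
          class_label = cl, t(flags), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a full phantom cohort
#'
#' @param spec a [cohort_spec()].
#' @param out_dir if non-NULL, volumes are written as NIfTI (4 files per
#'   subject), the clinical table as CSV and a JSON manifest recording the
#'   spec and per-subject seeds; re-running with the same spec reproduces
#'   identical files.
#' @return list(subjects = list of `subject_volumes`, clinical = data.frame,
#'   manifest = list).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  clinical <- generate_clinical_table(spec)
  subjects <- vector("list", nrow(clinical))
  seeds <- integer(nrow(clinical))
  for (i in seq_len(nrow(clinical))) {
    seeds[i] <- derive_seed(spec$master_seed, i)
    subjects[[i]] <- generate_kidney_phantom(
      spec, clinical$class_label[i], clinical$age_months[i], seeds[i],
      subject_id = clinical$subject_id[i])
  }
  manifest <- list(grid = spec$grid, master_seed = spec$master_seed,
                   n_per_class = spec$n_per_class,
                   subject_seeds = stats::setNames(as.list(seeds),
                                                   clinical$subject_id))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop("cannot create output directory: ", out_dir)
    }
    for (s in subjects) {
      base <- file.path(out_dir, s$subject_id)
      write_nifti(s$t2w, paste0(base, "_t2w.nii.gz"), s$spacing, "float32")
      write_nifti(s$adc, paste0(base, "_adc.nii.gz"), s$spacing, "float32")
      write_nifti(s$mask_left * 1, paste0(base, "_mask_left.nii.gz"), s$spacing, "uint8")
      write_nifti(s$mask_right * 1, paste0(base, "_mask_right.nii.gz"), s$spacing, "uint8")
    }
    utils::write.csv(clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(subjects = subjects, clinical = clinical, manifest = manifest)
}
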