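test_that("phantom masks match the drawn volume within rasterization error", {
  spec <- small_spec()
  s <- small_phantom()
  voxvol <- prod(s$spacing) / 1000
  mask <- s$mask_left | s$mask_right
  raster_cm3 <- sum(mask) * voxvol
  # surface voxel count bounds the rasterization error of an ellipsoid shell
  pl <- renalrad:::padded_levels(array(as.integer(mask), dim(mask)))
  nb_all <- rowSums(vapply(seq_len(26), function(r) {
    pl$lv[pl$idx + pl$delta(renalrad:::offsets26()[r, ])] > 0
  }, logical(length(pl$idx))))
  n_surface <- sum(nb_all < 26)
  expect_lt(abs(raster_cm3 - s$meta$target_total_cm3), voxvol * n_surface)
})

test_that("phantom generation is deterministic and masks are disjoint, nonempty", {
  spec <- small_spec()
  a <- generate_kidney_phantom(spec, "IC2", 24, 123, "A")
  b <- generate_kidney_phantom(spec, "IC2", 24, 123, "A")
  expect_identical(a$t2w, b$t2w)
  expect_identical(a$adc, b$adc)
  expect_identical(a$mask_left, b$mask_left)
  expect_true(any(a$mask_left) && any(a$mask_right))
  expect_false(any(a$mask_left & a$mask_right))
})

test_that("age bounds and grid capacity are enforced", {
  spec <- small_spec()
  expect_error(generate_kidney_phantom(spec, "IC2", 60, 1), "outside")
  tiny <- cohort_spec(grid = list(shape = c(16L, 16L, 8L), spacing = c(1, 1, 1)),
                      n_per_class = 2L)
  expect_error(generate_kidney_phantom(tiny, "UPD+IC1", 24, 1), "capacity|not realizable")
})

test_that("zero lesion rate leaves no voxel above the 6-SD texture envelope", {
  spec <- small_spec()
  spec$lesion_model <- list("UPD+IC1" = list(rate = 0), "IC2" = list(rate = 0))
  s <- generate_kidney_phantom(spec, "UPD+IC1", 12, 99, "L0")
  mask <- s$mask_left | s$mask_right
  amp <- spec$texture_model[["UPD+IC1"]]$amplitude
  expect_true(all(s$t2w[mask] < spec$t2_base + 6 * amp))
})

test_that("clinical table matches Bernoulli rates and is deterministic", {
  spec <- small_spec(n_per_class = 2000L, master_seed = 31L)
  tab <- generate_clinical_table(spec)
  expect_identical(tab, generate_clinical_table(spec))
  expect_equal(nrow(tab), 4000L)
  for (cl in c("UPD+IC1", "IC2")) {
    p <- spec$clinical_rates[[cl]][["omphalocele_umbilical_hernia"]]
    phat <- mean(tab$omphalocele_umbilical_hernia[tab$class_label == cl])
    se <- sqrt(p * (1 - p) / 2000)
    expect_lt(abs(phat - p), 3 * max(se, 1e-9))
  }
  # degenerate rate 1 flags every record
  spec2 <- small_spec(n_per_class = 50L)
  spec2$clinical_rates[["IC2"]]["macrosomia"] <- 1
  t2 <- generate_clinical_table(spec2)
  expect_true(all(t2$macrosomia[t2$class_label == "IC2"] == 1))
  expect_true(all(t2$age_months >= 6 & t2$age_months <= 48))
})

test_that("volume model calibration: per-class means and age correlation", {
  # volumes checked from rasterized masks over many subjects on a small grid
  spec <- small_spec(n_per_class = 100L, master_seed = 17L)
  co <- generate_cohort(spec)
  vol <- volumetry_report(co$subjects, co$clinical)
  m <- merge(vol, co$clinical[, c("subject_id", "age_months")], by = "subject_id")
  for (cl in c("UPD+IC1", "IC2")) {
    vm <- spec$volume_model[[cl]]
    sub <- vol[vol$class_label == cl, ]
    ages <- sub$age_months
    mu_target <- vm$intercept + vm$slope * mean(ages)
    se <- sqrt(vm$sd^2 / nrow(sub))
    expect_lt(abs(mean(sub$total_volume_cm3) - mu_target), 2.5 * se + 1)
    # analytic r target: slope * sd(age) / sd(volume)
    r_target <- vm$slope * sd(ages) /
      sqrt(vm$slope^2 * var(ages) + vm$sd^2)
    r_obs <- cor(sub$age_months, sub$total_volume_cm3)
    expect_lt(abs(r_obs - r_target), 0.15)
  }
})

test_that("generate_cohort writes the full artifact set and reproduces it", {
  spec <- small_spec(n_per_class = 3L, master_seed = 9L)
  d1 <- withr::local_tempdir()
  co <- generate_cohort(spec, out_dir = d1)
  expect_length(co$subjects, 6L)
  expect_equal(sum(grepl("\\.nii\\.gz$", list.files(d1))), 24L)
  expect_true(file.exists(file.path(d1, "clinical.csv")))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  d2 <- withr::local_tempdir()
  generate_cohort(spec, out_dir = d2)
  for (f in grep("nii.gz$", list.files(d1), value = TRUE)) {
    expect_identical(read_nifti(file.path(d1, f))$data,
                     read_nifti(file.path(d2, f))$data)
  }
})

test_that("volume as a score separates engineered classes and not null ones", {
  spec <- small_spec(n_per_class = 12L, master_seed = 21L)
  # disjoint volume ranges -> AUC 1
  spec$volume_model <- list(
    "UPD+IC1" = list(intercept = 150, slope = 0, sd = 0),
    "IC2"     = list(intercept = 70, slope = 0, sd = 0))
  co <- generate_cohort(spec)
  vol <- volumetry_report(co$subjects, co$clinical)
  auc <- roc_auc(vol$total_volume_cm3, vol$class_label)$auc
  expect_equal(auc, 1)  # UPD+IC1 sorts as class 1 and has the larger volumes
  # identical class models -> chance-level AUC
  specn <- small_spec(n_per_class = 20L, master_seed = 22L)
  specn$volume_model <- list(
    "UPD+IC1" = list(intercept = 80, slope = 0.5, sd = 15),
    "IC2"     = list(intercept = 80, slope = 0.5, sd = 15))
  con <- generate_cohort(specn)
  voln <- volumetry_report(con$subjects, con$clinical)
  aucn <- roc_auc(voln$total_volume_cm3, voln$class_label)$auc
  expect_lt(abs(aucn - 0.5), 0.15 + 1e-9)
})
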