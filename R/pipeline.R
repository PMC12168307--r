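# End-to-end orchestration: cohort (synthetic or on-disk) -> volumetry ->
# filter bank -> feature tables -> selection cascade -> model grid for the
# T2WI, ADC and combined models -> DeLong / contingency statistics, with all
# artifacts written under one output directory and every stochastic choice
# derived from a single master seed.

#' Read one subject from NIfTI files
#'
#' @param paths named list/vector with entries `t2w`, `adc`, `mask_left`,
#'   `mask_right`.
#' @param subject_id identifier.
#' @return a `subject_volumes` object. Masks are binarized at > 0 (with a
#'   warning when non-0/1 values occur); mismatched shapes or spacings across
#'   the four volumes are a hard error.
#' @export
read_subject <- function(paths, subject_id = "S1") {
  need <- c("t2w", "adc", "mask_left", "mask_right")
  stopifnot(all(need %in% names(paths)))
  vols <- lapply(paths[need], read_nifti)
  shp <- dim(vols$t2w$data)
  for (nm in need) {
    if (!identical(dim(vols[[nm]]$data), shp)) {
      stop("shape mismatch: ", nm, " is ", paste(dim(vols[[nm]]$data), collapse = "x"),
           " but t2w is ", paste(shp, collapse = "x"))
    }
    if (max(abs(vols[[nm]]$spacing - vols$t2w$spacing)) > 1e-4) {
      stop("spacing mismatch between t2w and ", nm)
    }
  }
  binarize <- function(a, nm) {
    u <- unique(as.vector(a))
    if (!all(u %in% c(0, 1))) {
      warning("mask ", nm, " contains values other than 0/1; binarizing at > 0")
    }
    a > 0
  }
  structure(list(t2w = vols$t2w$data, adc = vols$adc$data,
                 mask_left = binarize(vols$mask_left$data, "mask_left"),
                 mask_right = binarize(vols$mask_right$data, "mask_right"),
                 spacing = vols$t2w$spacing, subject_id = subject_id,
                 meta = list()),
            class = "subject_volumes")
}

#' Read a cohort directory written by [generate_cohort()]
#'
#' @param dir directory containing `clinical.csv` and per-subject NIfTI files.
#' @return list(subjects, clinical).
#' @export
read_cohort <- function(dir) {
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"))
  subjects <- lapply(clinical$subject_id, function(sid) {
    base <- file.path(dir, sid)
    read_subject(list(t2w = paste0(base, "_t2w.nii.gz"),
                      adc = paste0(base, "_adc.nii.gz"),
                      mask_left = paste0(base, "_mask_left.nii.gz"),
                      mask_right = paste0(base, "_mask_right.nii.gz")),
                 subject_id = sid)
  })
  list(subjects = subjects, clinical = clinical)
}

#' Run the full radiomics analysis pipeline
#'
#' Stages: cohort generation (or ingest) -> volumetry report -> per-sequence
#' feature extraction over the 15-type filter bank -> cascade selection with
#' 5-fold voting (T2WI, ADC, combined) -> 104-pipeline model grid per model ->
#' best-model DeLong comparisons and clinical contingency report.
#'
#' @param spec a [cohort_spec()] (synthetic input), or NULL with `input_dir`.
#' @param input_dir directory of an existing cohort (exclusive with `spec`).
#' @param out_dir output directory for artifacts (NULL = no files written).
#' @param selection_cfg a [selection_config()].
#' @param grid_cfg a [grid_config()].
#' @param manifest feature bank manifest.
#' @param master_seed master seed; fold seeds and noise seeds derive from it.
#' @param n_bins discretization bins.
#' @return list(clinical, volumetry, correlations, features, selection, grids,
#'   best, delong, clinical_tests, manifest_info).
#' @export
run_pipeline <- function(spec = NULL, input_dir = NULL, out_dir = NULL,
                         selection_cfg = NULL, grid_cfg = NULL,
                         manifest = default_bank_manifest(),
                         master_seed = 1L, n_bins = 32L) {
  if (is.null(spec) == is.null(input_dir)) {
    stop("exactly one of spec (synthetic) or input_dir (files) must be given")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  co <- if (!is.null(spec)) generate_cohort(spec, out_dir = NULL) else read_cohort(input_dir)
  subjects <- co$subjects; clinical <- co$clinical
  if (is.null(selection_cfg)) {
    selection_cfg <- selection_config(fold_seed = derive_seed(master_seed, 101L))
  }
  if (is.null(grid_cfg)) grid_cfg <- grid_config(seed = derive_seed(master_seed, 202L))
  fb_cfg <- filter_bank_config(noise_seed = derive_seed(master_seed, 303L))

  vol <- volumetry_report(subjects, clinical)
  cors <- lapply(stats::setNames(nm = CLASS_LABELS), function(cl) {
    tryCatch(age_volume_correlation(clinical, vol, cl), error = function(e) NULL)
  })

  ft_t2 <- compute_feature_table(subjects, "t2w", manifest, n_bins, fb_cfg)
  ft_adc <- compute_feature_table(subjects, "adc", manifest, n_bins, fb_cfg)
  colnames(ft_t2) <- paste0("t2w_", colnames(ft_t2))
  colnames(ft_adc) <- paste0("adc_", colnames(ft_adc))
  labels <- clinical$class_label

  sel <- combined_model_selection(ft_t2, ft_adc, labels, selection_cfg)
  sets <- list(t2w = sel$t2w$final, adc = sel$adc$final,
               combined = sel$combined$final)
  pooled <- cbind(ft_t2, ft_adc)
  grids <- list(); best <- list()
  for (model in names(sets)) {
    feats <- sets[[model]]
    if (length(feats) == 0L) {
      grids[[model]] <- NULL
      best[[model]] <- NULL
      next
    }
    grids[[model]] <- fit_evaluate_grid(pooled[, feats, drop = FALSE], labels,
                                        grid_cfg)
    best[[model]] <- select_best(grids[[model]])
  }

  # fold-wise DeLong comparisons between the best pipelines of each model pair
  delong <- list()
  fitted_models <- names(Filter(Negate(is.null), best))
  pairs <- if (length(fitted_models) >= 2) {
    utils::combn(fitted_models, 2, simplify = FALSE)
  } else list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    fa <- pipeline_fold_scores(grids[[a]], best[[a]]$index)
    fb <- pipeline_fold_scores(grids[[b]], best[[b]]$index)
    pv <- vapply(seq_along(fa), function(k) {
      tryCatch(delong_test(fa[[k]]$labels, fa[[k]]$scores, fb[[k]]$scores)$p,
               error = function(e) NA_real_)
    }, numeric(1))
    delong[[paste(a, "vs", b)]] <- pv
  }

  ctests <- clinical_comparison(
    clinical, continuous = list(total_volume_cm3 = vol$total_volume_cm3,
                                mean_adc = vol$mean_adc,
                                mean_t2 = vol$mean_t2_intensity))

  out <- list(clinical = clinical, volumetry = vol, correlations = cors,
              features = list(t2w = ft_t2, adc = ft_adc),
              selection = sel, grids = grids, best = best, delong = delong,
              clinical_tests = ctests,
              manifest_info = list(n_features = nrow(manifest),
                                   master_seed = master_seed))
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

# Write the standard artifact files for a pipeline run.
write_pipeline_artifacts <- function(res, out_dir) {
  utils::write.csv(res$volumetry, file.path(out_dir, "volumetry.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(res$features$t2w),
                              res$features$t2w, check.names = FALSE),
                   file.path(out_dir, "features_t2w.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(res$features$adc),
                              res$features$adc, check.names = FALSE),
                   file.path(out_dir, "features_adc.csv"), row.names = FALSE)
  sel_json <- list(
    t2w = list(votes = as.list(res$selection$t2w$votes[res$selection$t2w$votes > 0]),
               final = res$selection$t2w$final),
    adc = list(votes = as.list(res$selection$adc$votes[res$selection$adc$votes > 0]),
               final = res$selection$adc$final),
    combined = list(final = res$selection$combined$final,
                    votes = as.list(res$selection$combined$votes)))
  jsonlite::write_json(sel_json, file.path(out_dir, "selection_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (model in names(res$grids)) {
    utils::write.csv(res$grids[[model]]$summary,
                     file.path(out_dir, paste0("grid_", model, ".csv")),
                     row.names = FALSE)
  }
  best_json <- lapply(res$best, function(b) b[setdiff(names(b), "index")])
  jsonlite::write_json(best_json, file.path(out_dir, "best_models.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(res$clinical_tests, file.path(out_dir, "clinical_tests.csv"),
                   row.names = FALSE)
  delong_df <- do.call(rbind, lapply(names(res$delong), function(nm) {
    data.frame(comparison = nm, fold = seq_along(res$delong[[nm]]),
               p = res$delong[[nm]])
  }))
  if (!is.null(delong_df)) {
    utils::write.csv(delong_df, file.path(out_dir, "delong_folds.csv"),
                     row.names = FALSE)
  }
  manifest <- c(res$manifest_info,
                list(written = format(Sys.time(), tz = "UTC", usetz = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
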