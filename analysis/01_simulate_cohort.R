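#!/usr/bin/env Rscript
# Simulate the phantom cohort: two genotype classes (renal-predisposition
# UPD+IC1 vs IC2) with planted differences in total renal volume, age-volume
# coupling, parenchymal texture and clinical-flag incidence. Writes NIfTI
# volumes, the clinical CSV and a manifest under results/cohort/.
#
# The demo runs 50 subjects per class on a coarsened grid (the cross-validated
# voting needs a reasonable n to be stable; the whole sequence takes ~10 min);
# pass --scanner-grid for the default scanner geometry instead.

library(renalrad)

scanner <- "--scanner-grid" %in% commandArgs(trailingOnly = TRUE)
spec <- if (scanner) {
  cohort_spec(n_per_class = 50L, master_seed = 1L)
} else {
  cohort_spec(n_per_class = 50L,
              grid = list(shape = c(64L, 64L, 24L), spacing = c(1.875, 1.875, 5)),
              master_seed = 1L)
}

dir.create("results", showWarnings = FALSE)
co <- generate_cohort(spec, out_dir = "results/cohort")
cat("Simulated", length(co$subjects), "subjects (",
    paste(spec$n_per_class, collapse = "+"), "per class ) on a",
    paste(spec$grid$shape, collapse = "x"), "grid.\n")
cat("Class volume models encode medians ~116 vs ~91 cm^3 and age-volume",
    "correlations ~0.38 vs ~0.71; texture correlation lengths 2 vs 6 mm.\n")
cat("Wrote", length(list.files("results/cohort", pattern = "nii.gz$")),
    "NIfTI files + clinical.csv + manifest.json under results/cohort/\n")
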