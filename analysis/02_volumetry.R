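#!/usr/bin/env Rscript
# Volumetry: per-kidney and total parenchymal volumes, mean T2/ADC, the
# normative-band (mean +/- 2 SD) classification per subject, and the
# per-class age-volume Pearson correlation. Reads results/cohort/, writes
# results/volumetry.csv and results/age_volume.pdf.

library(renalrad)

co <- read_cohort("results/cohort")
vol <- volumetry_report(co$subjects, co$clinical)
write.csv(vol, "results/volumetry.csv", row.names = FALSE)

cat("Per-class median total renal volume (cm^3):\n")
print(round(tapply(vol$total_volume_cm3, vol$class_label, median), 2))
above <- mean(vol$vs_normative == "above", na.rm = TRUE)
cat(sprintf("%.1f%% of subjects exceed the age-specific normal upper limit\n",
            100 * above))
for (cl in unique(vol$class_label)) {
  r <- age_volume_correlation(co$clinical, vol, cl)
  cat(sprintf("age-volume Pearson r [%s] = %.2f (p = %.3g, n = %d)\n",
              cl, r$r, r$p, r$n))
}

# scatter plot with the normative band lines
pdf("results/age_volume.pdf", width = 7, height = 5)
tab <- normative_table()
plot(vol$age_months, vol$total_volume_cm3,
     col = ifelse(vol$class_label == "UPD+IC1", "red", "blue"),
     pch = 19, xlab = "age (months)", ylab = "total renal volume (cm^3)",
     main = "Total renal volume vs age against normative bands")
for (col in c("upper_cm3", "mean_cm3", "lower_cm3")) {
  segments(tab$age_lo, tab[[col]], tab$age_lo + 6, tab[[col]],
           lty = 2, col = "darkgreen")
}
legend("topleft", c("UPD+IC1", "IC2", "normal mean +/- 2SD"),
       col = c("red", "blue", "darkgreen"), pch = c(19, 19, NA),
       lty = c(NA, NA, 2), bty = "n")
dev.off()
cat("Wrote results/volumetry.csv and results/age_volume.pdf\n")
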