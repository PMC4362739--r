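#!/usr/bin/env Rscript
# Enzyme-activity arithmetic of the optimization campaign and the pulp
# biobleaching outcome metrics.

suppressPackageStartupMessages(library(fermdoe))
dir.create("results", showWarnings = FALSE)

tab1 <- study_fixture("table1_ovat")
baseline <- tab1$activity_nkat_ml[1]
ovat_best <- max(tab1$activity_nkat_ml)
validated <- 18356  # measured activity at the model's predicted optimum

cat(sprintf("Stepwise optimization: %g -> %g nkat/mL, %.2f-fold\n",
            baseline, ovat_best, fold_change(ovat_best, baseline)))
cat(sprintf("Statistical optimization: %g nkat/mL (~%.0f U/mL), %.2f-fold overall\n",
            validated, nkat_to_units(validated),
            fold_change(validated, baseline)))

tab4 <- study_fixture("table4_bleach")
bleach <- data.frame(
  treatment = tab4$treatment,
  kappa = tab4$kappa,
  kappa_reduction_pct = round(percent_change(tab4$kappa[1], tab4$kappa,
                                             "reduction"), 2),
  brightness = tab4$brightness_iso,
  brightness_increase_pct = round(percent_change(tab4$brightness_iso[1],
                                                 tab4$brightness_iso,
                                                 "increase"), 2))
write.csv(bleach, "results/biobleaching.csv", row.names = FALSE)
cat("\nBiobleaching of softwood pulp (computed percent columns):\n")
print(bleach, row.names = FALSE)
cat("\nFixture notes:\n")
writeLines(paste(" -", attr(tab4, "notes")))

# worked assay example: absorbance ramp back-computed to activity
cond <- assay_conditions()
ser <- gen_assay_series(250, cond, n_points = 6, noise_sd = 0, seed = 1)
dA <- ser$absorbance[6] - ser$absorbance[1]
cat(sprintf("\nAssay inversion check: dA = %.4f over %g s -> %.1f nkat/mL\n",
            dA, cond$duration, activity_nkat_per_ml(dA, cond)))
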