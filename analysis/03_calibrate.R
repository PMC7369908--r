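#!/usr/bin/env Rscript
# Calibrate the LIE scaling parameters against the experimental affinities
# (no-intercept least squares over the 8 ligands with measured constants),
# report both models' predicted-vs-experimental r^2, and stress the fit
# with leave-one-out cross-validation.

suppressPackageStartupMessages(library(tyrlie))
dir.create("results", showWarnings = FALSE)

t4 <- table4_fixture()
cal <- calibrate_lie(t4, t4)
print(cal)
write_calibration_report(cal, "results/calibration.json")

loo <- leave_one_out(t4, experimental_affinities(t4))
utils::write.csv(loo$predictions, "results/calibration_loo.csv",
                 row.names = FALSE)
cat(sprintf("leave-one-out RMSE: %.2f kcal/mol over %d ligands\n",
            loo$loo_rmse, nrow(loo$predictions)))
cat(sprintf("refit alpha range: [%.3f, %.3f]; beta range: [%.3f, %.3f]\n",
            min(loo$predictions$alpha), max(loo$predictions$alpha),
            min(loo$predictions$beta), max(loo$predictions$beta)))
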