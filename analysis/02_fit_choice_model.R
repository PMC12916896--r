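#!/usr/bin/env Rscript
# Fit the 10-parameter trinomial choice model to every simulated
# participant (predictors z-scored within participant) and run the group
# one-sample t tests on the coefficients.

suppressPackageStartupMessages(library(dialexplore))

set.seed(20260921L)
events <- read_event_log("results/behavior_events.tsv")
rows <- standardize_predictors(events)
fits <- lapply(split(rows, rows$participant), fit_mle)

report <- group_coefficient_tests(fits)
utils::write.table(format(report, digits = 6), "results/group_coefficients.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("group coefficients (one-sample t vs 0, df =", report$df[1], "):\n")
print(report[, c("coefficient", "mean", "t", "p")], digits = 3)
cat(sprintf("\nmean per-participant BIC (k = 10): %.1f\n",
            mean(vapply(fits, bic, numeric(1)))))
cat(sprintf("mean prediction accuracy: %.3f\n",
            mean(mapply(prediction_accuracy, fits,
                        split(rows, rows$participant)))))
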