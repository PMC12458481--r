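#!/usr/bin/env Rscript
# Fluorescence preprocessing: 0.7x neuropil correction, Gaussian smoothing +
# 50th-percentile baseline in non-overlapping 60 s windows, dF/F (percent),
# session-wide z-score; ROIs with non-positive baselines or flat traces are
# excluded.

source(file.path("analysis", "00_config.R"))

ses <- make_study_session()
tr <- preprocess_session(ses$recording)

write.csv(tr$exclusion_report,
          file.path(results_dir, "exclusion_report.csv"), row.names = FALSE)

cat("Kept", nrow(tr$z), "of", nrow(ses$recording$raw_f), "ROIs\n")
excl <- table(tr$exclusion_report$reason)
print(excl)
cat(sprintf("Session-wide z check: max |row mean| = %.2e, max |row sd - 1| = %.2e\n",
            max(abs(rowMeans(tr$z))), max(abs(apply(tr$z, 1, sd) - 1))))
cat(sprintf("dF/F dynamic range (percent): %.1f to %.1f\n",
            min(tr$dff), max(tr$dff)))
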