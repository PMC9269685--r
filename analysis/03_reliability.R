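#!/usr/bin/env Rscript
# Reliability and agreement analysis over the extracted features:
# intra-sensor ICC(3,1) per sensor (test-retest across a subject's repeated
# trials), inter-sensor ICC(2,1) across paired trials, and Bland-Altman
# limits of agreement per feature. Outputs: results/reliability_intra.csv,
# results/reliability_inter.csv, results/reliability.json and a
# Bland-Altman panel figure.

library(transferkin)

path <- file.path("results", "features.csv")
if (!file.exists(path)) {
  stop("run analysis/02_extract_features.R first (missing ", path, ")")
}
features <- read.csv(path, stringsAsFactors = FALSE)

report <- reliability_report(features)
write_reliability_report(report, "results")

message("intra-sensor (test-retest) ICC(3,1):")
print(report$intra[c("feature", "sensor", "icc", "ci_lower", "ci_upper",
                     "category")], row.names = FALSE)
message("inter-sensor ICC(2,1) with Bland-Altman limits:")
print(report$inter[c("feature", "icc", "ci_lower", "ci_upper", "category",
                     "ba_m", "ba_inf", "ba_sup", "ba_within",
                     "interchangeable")], row.names = FALSE)

pdf(file.path("results", "bland_altman.pdf"), width = 8, height = 8)
op <- par(mfrow = c(2, 2))
for (key in names(report$bland_altman)) {
  plot_bland_altman(report$bland_altman[[key]], main = key, pch = 16)
}
par(op)
invisible(dev.off())
message("Bland-Altman panels written to results/bland_altman.pdf")
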