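#!/usr/bin/env Rscript
# Harmonize, segment and extract the four lift-phase features from every
# recording produced by 01_simulate_session.R. Failed trials are reported,
# not silently dropped. Output: results/features.csv.

library(transferkin)

in_dir <- file.path("results", "session")
if (!dir.exists(in_dir)) {
  stop("run analysis/01_simulate_session.R first (missing ", in_dir, ")")
}

files <- list.files(in_dir, pattern = "__.*\\.csv$", full.names = TRUE)
message("extracting features from ", length(files), " recordings ...")

feature_sets <- list()
failures <- character()
for (f in files) {
  key <- sub("\\.csv$", "", basename(f))
  sensor <- strsplit(key, "__", fixed = TRUE)[[1]][1]
  res <- tryCatch({
    rec <- read_recording(f, sensor)
    ct <- harmonize(rec)
    seg <- detect_phases(ct$pelvis_x, rec$sensor$nominal_rate)
    extract_features(ct, seg)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    failures[key] <- conditionMessage(res)
  } else {
    feature_sets[[key]] <- res
  }
}

features <- features_df(feature_sets)
write.csv(features, file.path("results", "features.csv"), row.names = FALSE)

message(nrow(features), " trials extracted, ", length(failures), " failed")
if (length(failures)) {
  for (k in names(failures)) message("  failed: ", k, " -- ", failures[k])
}
per_sensor <- aggregate(features[c("dswp", "lpoe", "le", "tf")],
                        by = list(sensor = features$sensor), FUN = mean)
message("per-sensor feature means:")
print(per_sensor, row.names = FALSE)
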