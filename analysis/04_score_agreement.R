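#!/usr/bin/env Rscript
# Transfer-quality score analysis: 3 subjects x 50 trials (10 proper + 10 of
# each of 4 improper techniques), scored by two simulated classifier-backed
# sensors. Computes the between-sensor per-item percent agreement and each
# sensor's confusion accuracy against the ground-truth scores, stratified by
# transfer type. Outputs: results/agreement.csv, results/accuracy.csv.

library(transferkin)

seed <- 20260104

plan <- data.frame(
  subject = rep(1:3, each = 50),
  trial = rep(1:50, 3),
  transfer_type = rep(rep(c("good", "feet", "trunk", "arm", "fist"),
                          each = 10), 3)
)
design <- session_design(
  n_subjects = 3, trials_per_subject = 50,
  sensors = list(KINECT_AZURE = sensor_noise(), KINECT_V2 = sensor_noise()),
  plan = plan, score_flip_prob = 0.08
)
session <- simulate_session(design, seed = seed, render = "features")

agree <- percent_agreement(session$score_pred$KINECT_AZURE,
                           session$score_pred$KINECT_V2)
message("per-item percent agreement between Azure and V2 predictions (",
        agree$n_trials, " transfers):")
print(agree$per_item, row.names = FALSE)
message(sprintf("overall: %.1f%% (SD %.1f)",
                agree$overall$percent_agreement[1],
                agree$overall$percent_agreement[2]))
write.csv(agree$per_item, file.path("results", "agreement.csv"),
          row.names = FALSE)

acc_rows <- list()
for (sn in names(session$score_pred)) {
  acc <- accuracy_vs_truth(session$score_pred[[sn]], session$score_truth)
  acc_rows[[sn]] <- cbind(sensor = sn, acc$by_stratum)
}
acc_df <- do.call(rbind, acc_rows)
write.csv(acc_df, file.path("results", "accuracy.csv"), row.names = FALSE)

# how often is the targeted item actually caught in its improper stratum?
targeted <- subset(
  acc_df,
  (transfer_type == "feet" & item == 7) |
  (transfer_type == "trunk" & item == 13) |
  (transfer_type == "arm" & item %in% c(9, 12)) |
  (transfer_type == "fist" & item == 11)
)
message("accuracy on the targeted item of each improper type:")
print(targeted[c("sensor", "transfer_type", "item", "accuracy")],
      row.names = FALSE)
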