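#!/usr/bin/env Rscript
# Simulate a two-sensor data-collection session: 7 subjects each performing
# 10 proper transfers, recorded simultaneously by a Kinect Azure and a
# Kinect V2. The V2 gets heavier jitter, occasional dropout and a small
# pelvis tracking lag; the Azure is cleaner. Recordings, true features and
# score tables land under results/session/.

library(transferkin)

seed <- 20260101
out_dir <- file.path("results", "session")

design <- session_design(
  n_subjects = 7, trials_per_subject = 10,
  sensors = list(
    KINECT_AZURE = sensor_noise(jitter_sd = 2, dropout_prob = 0.002),
    KINECT_V2 = sensor_noise(jitter_sd = 4, dropout_prob = 0.01,
                             pelvis_lag = 1 / 30)
  )
)

message("simulating ", design$n_subjects, " subjects x ",
        design$trials_per_subject, " trials x ",
        length(design$sensors), " sensors ...")
session <- simulate_session(design, seed = seed, render = "recordings")
write_session(session, out_dir)

n_rec <- length(session$recordings)
message("wrote ", n_rec, " recordings to ", out_dir)
stopifnot(n_rec == 7 * 10 * 2)
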