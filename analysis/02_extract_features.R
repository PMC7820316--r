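#!/usr/bin/env Rscript
# Step 2 — extract the mfVEP features.
#
# For every eye: band-limited records -> best channel per sector (highest
# windowed SNR) -> eye SNR, normative-database latency, and the scalogram
# descriptors b_max and N_max; then collapse the two eyes into the four
# patient-level variables (SNR_min, Lat_max, b_max, N_max).

suppressPackageStartupMessages(library(mfvepris))

st <- readRDS("scratch/cohort.rds")
ndb <- read_normative_db("results/normative_db.csv")

message("extracting per-eye features for ",
        2 * length(st$cohort$records), " eyes ...")
feats <- cohort_features(st$cohort, ndb)

write.csv(feats$eyes, "results/eye_features.csv", row.names = FALSE)
write_patient_table(feats$patients, "results/patients.csv")

message("patient table:")
print(feats$patients[, c("patient_id", "snr_min", "lat_max_ms", "bmax_ms",
                         "nmax", "group")], digits = 4)
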