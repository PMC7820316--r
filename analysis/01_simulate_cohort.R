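#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Calibrates the two group presets to the published group means (eye SNR
# 4.07 / 2.74; eye b_max 139.03 / 169.44 ms), simulates 5 converter and
# 10 non-converter patients (two eyes each) plus a healthy normative
# cohort, and writes the event table.  Everything downstream reads the
# outputs of this step; a single seed fixes the whole experiment.

suppressPackageStartupMessages(library(mfvepris))

seed <- 20231L
dir.create("results", showWarnings = FALSE)

config <- generator_config()
message("calibrating group presets (a few minutes) ...")
presets <- calibrate_presets(mfvep_presets(), config, seed = seed)
for (g in c("non_converter", "converter"))
  message(sprintf("  %-13s amplitude %.3f, peak %.1f ms", g,
                  presets[[g]]$amplitude_scale, presets[[g]]$peak_time))

cohort <- generate_cohort(5, 10, config, presets, seed = seed)
ndb <- build_normative_db(8, config, presets$healthy, seed = seed + 11L)

write.csv(cohort$events, "results/events.csv", row.names = FALSE)
write_normative_db(ndb, "results/normative_db.csv")
dir.create("scratch", showWarnings = FALSE)
saveRDS(list(config = config, presets = presets, cohort = cohort,
             seed = seed), "scratch/cohort.rds")
message("cohort of ", nrow(cohort$events), " patients written; ",
        sum(cohort$events$event), " converters (events at months ",
        paste(cohort$events$time_months[cohort$events$event == 1],
              collapse = ", "), ").")
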