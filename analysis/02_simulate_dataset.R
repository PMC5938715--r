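#!/usr/bin/env Rscript
# Step 2: synthetic cohort.
#
# Simulates the trial schedule for the full study design (24 participants,
# six blocks per condition, 546 trials each) and, as a worked example, the
# synthetic EEG epochs of the first participant: ground-truth TRFs convolved
# with the hazard regressors at snr 0.5, plus 1/f noise. The epoch container
# for participant 1 is written for inspection; later steps re-simulate on
# the fly (each participant is cheap to regenerate and this keeps no
# multi-gigabyte array on disk).

suppressPackageStartupMessages(library(hazardTRF))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)   # bulky binary epoch container
seed <- 20260925

spec <- simulation_spec()
sched <- simulate_schedule(spec, seed = seed)
write.csv(sched[sched$participant <= 2, ], "results/schedule_first2.csv",
          row.names = FALSE)

cat(sprintf("Schedule: %d participants x %d trials (%d rows)\n",
            spec$n_participants, nrow(sched) / spec$n_participants,
            nrow(sched)))
print(table(sched$condition[sched$participant == 1]))

regs <- study_hazard_regressors(fs = spec$fs, window = spec$window)
cfg <- ridge_config()
trfs <- lapply(setNames(nm = names(study_conditions())), function(cnd)
  simulate_ground_truth_trf(spec, cnd, cfg))

ep1 <- simulate_epochs(sched[sched$participant == 1, ], trfs, regs, spec,
                       cfg, seed = seed + 1)
print(ep1)
write_epochs(ep1, "scratch/epochs_participant1.rds")
cat("Wrote results/schedule_first2.csv, scratch/epochs_participant1.rds\n")
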