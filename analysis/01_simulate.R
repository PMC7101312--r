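#!/usr/bin/env Rscript
# Simulate one full experimental session: 3 stimulation conditions x 4
# blocks x 5 pulse trains (60 trials) of 64-channel EEG at 500 Hz, with the
# condition-specific evoked structure planted on 1/f background noise.
# Writes the session (EDF + JSON sidecars + montage CSV) under
# results/session/.

library(painmark)

cfg <- generator_config(seed = 1)
ses <- generate_session(cfg)
write_session(ses, "results/session")

ev <- ses$schedule$events
cat("Simulated session:\n")
cat(sprintf("  %d trials (%s)\n", nrow(ev),
            paste(names(table(ev$condition)), table(ev$condition),
                  sep = "=", collapse = ", ")))
cat(sprintf("  duration %.1f min at %d Hz, %d channels\n",
            ncol(ses$signal) / ses$sampling_rate / 60, ses$sampling_rate,
            nrow(ses$signal)))
cat("  planted components:\n")
for (cond in names(ses$truth))
  for (nm in names(ses$truth[[cond]])) {
    cmp <- ses$truth[[cond]][[nm]]
    cat(sprintf("    %-4s %-18s %4.1f uV at %s (%s)\n", cond, nm,
                cmp$amplitude_uv, cmp$centre_channel,
                if (cmp$locked) "phase-locked" else "induced"))
  }
cat("Written to results/session/\n")
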