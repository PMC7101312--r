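#!/usr/bin/env Rscript
# Condition the simulated session (run analysis/01_simulate.R first):
# 0.5-70 Hz zero-phase Butterworth band-pass + 60 Hz notch, epoching to
# [-500, 2000) ms around every train onset, baseline correction to the
# pre-stimulus mean and 150 uV peak-to-peak artifact rejection.
# Writes the rejection log and per-condition evoked peaks to results/.

library(painmark)

ses <- read_session("results/session")
fs <- ses$sampling_rate
sig <- notch(bandpass(ses$signal, fs), fs)
ep <- epoch_signal(sig, fs, ses$events, t_start = -500, t_end = 2000)
ep <- baseline_correct(ep)
ep <- reject_artifacts(ep, 150)

cat(sprintf("Epoched %d trials; kept %d after 150 uV peak-to-peak rejection\n",
            length(ep$kept), sum(ep$kept)))
rej <- attr(ep, "rejection_report")
utils::write.csv(rej, "results/rejection_log.csv", row.names = FALSE)

epc <- crop_epochs(ep, -500, 1000)
peaks <- do.call(rbind, lapply(c("INNO", "MOD", "NOX"), function(cond) {
  evk <- average_evoked(epc, cond)
  pk <- find_peak(evk, window = c(0, 1000))
  early <- find_peak(evk, window = c(0, 150))
  data.frame(condition = cond, n_trials = evk$n_trials,
             peak_channel = pk$channel, peak_latency_ms = pk$latency,
             peak_uv = round(pk$amplitude, 2),
             early_channel = early$channel,
             early_latency_ms = early$latency)
}))
print(peaks, row.names = FALSE)
utils::write.csv(peaks, "results/evoked_peaks.csv", row.names = FALSE)
cat("Wrote results/rejection_log.csv and results/evoked_peaks.csv\n")
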