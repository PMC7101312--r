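#!/usr/bin/env Rscript
# The window-sweep decoding study on the 60 original 1 s epochs: for every
# 100 ms window between 50 and 950 ms and each of the five classifiers
# (KNN, SVM, NB, LDA, QLDA), stratified 10-fold cross-validated balanced
# accuracy on the 64 max-amplitude features; then greedy sequential forward
# channel selection in the winning window.
# Writes results/sweep.csv and results/selected_channels.json.

library(painmark)

ses <- read_session("results/session")
fs <- ses$sampling_rate
sig <- notch(bandpass(ses$signal, fs), fs)
ep <- epoch_signal(sig, fs, ses$events, t_start = -500, t_end = 2000)
ep <- baseline_correct(ep)
ep <- reject_artifacts(ep, 150)
ep1 <- crop_epochs(ep, 0, 1000)

dc <- decode_config(seed = 1)
sw <- sweep_windows(ep1, dc)
cat("Mean validation bACC by window (across classifiers):\n")
print(transform(sw$window_means, mean_bacc = round(mean_bacc, 3)),
      row.names = FALSE)
cat(sprintf("Best window: [%d, %d) ms\n", sw$best_window[1], sw$best_window[2]))
utils::write.csv(sw$table, "results/sweep.csv", row.names = FALSE)

X <- max_amplitude_features(ep1, sw$best_window)
sel <- sequential_forward_selection(X, attr(X, "labels"), dc$n_select,
                                    dc$sfs_classifier, seed = 1,
                                    hyper = list(k = dc$knn_k))
cat("Sequential forward selection picked:", paste(sel, collapse = ", "), "\n")
jsonlite::write_json(list(best_window_ms = sw$best_window,
                          selected_channels = as.character(sel),
                          selection_scores = round(attr(sel, "scores"), 3)),
                     "results/selected_channels.json", auto_unbox = TRUE,
                     digits = NA)
cat("Wrote results/sweep.csv and results/selected_channels.json\n")
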