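#!/usr/bin/env Rscript
# Held-out classification of the three stimulation conditions: the 60
# two-second trials are split into 120 one-second segments, max-amplitude
# features are extracted in the best sweep window, PCA keeps two
# components (fitted on the stratified 80% training split only), SVM
# hyperparameters are grid-searched under 10-fold cross-validation, and the
# model is scored once on the untouched 20%.
# Writes results/final_test.json and results/confusion.csv.

library(painmark)

ses <- read_session("results/session")
fs <- ses$sampling_rate
sig <- notch(bandpass(ses$signal, fs), fs)
ep <- epoch_signal(sig, fs, ses$events, t_start = -500, t_end = 2000)
ep <- baseline_correct(ep)
ep <- reject_artifacts(ep, 150)

dc <- decode_config(seed = 1)
sw <- sweep_windows(crop_epochs(ep, 0, 1000), dc)
aug <- augment_split(crop_epochs(ep, 0, 2000))
ft <- final_test(aug, sw$best_window, dc)

cat(sprintf("Best window [%d, %d) ms; SVM %s kernel, cost %g\n",
            sw$best_window[1], sw$best_window[2], ft$hyper$kernel,
            ft$hyper$cost))
cat(sprintf("Validation bACC %.3f +/- %.3f, held-out test bACC %.3f (chance 0.333)\n",
            ft$validation_bacc, ft$validation_sd, ft$test_bacc))
cat("Confusion matrix (rows = true condition):\n")
print(ft$confusion)

jsonlite::write_json(list(best_window_ms = sw$best_window,
                          validation_bacc = ft$validation_bacc,
                          test_bacc = ft$test_bacc,
                          svm = ft$hyper),
                     "results/final_test.json", auto_unbox = TRUE, digits = NA)
utils::write.csv(as.data.frame.matrix(ft$confusion), "results/confusion.csv")
cat("Wrote results/final_test.json and results/confusion.csv\n")
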