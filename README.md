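# painmark

Spatio-temporal EEG biomarkers of phantom-limb stimulation intensity.

When transcutaneous electrical nerve stimulation (TENS) of an amputee's
residual limb evokes phantom-hand sensations, the cortical response carries a
signature of how intense the percept is: innocuous touch (INNO), moderately
intense touch (MOD) and noxious stimulation (NOX) differ in where and when
the evoked EEG peaks. `painmark` implements the full analysis chain for
identifying that signature and decoding the three conditions from 64-channel
EEG — together with a synthetic evoked-EEG generator that emulates the
experiment (3 conditions x 4 blocks x 5 pulse trains = 60 trials, 2 s trains
with 4 s +/- 25 % jittered delays, 500 Hz, extended 10-20 montage), so every
stage is testable without access to patient recordings.

The package is aimed at neural-engineering and ERP researchers prototyping
stimulation-intensity decoders or benchmarking sliding-window EEG analyses.

## What it computes

* **Preprocessing** — zero-phase fourth-order Butterworth band-pass
  (0.5–70 Hz) and 60 Hz notch, epoching to [-500, 2000) ms, baseline
  correction to the pre-stimulus mean, peak-to-peak artifact rejection
  (default 150 µV), condition averaging, and 2 s → 2 × 1 s epoch-split
  augmentation (60 → 120 trials).
* **Features** — per-trial, per-channel maximum signed amplitude over 100 ms
  windows: 64 features per trial.
* **Window-sweep decoding** — for each window between 50 and 950 ms and five
  classifiers (KNN, SVM, Gaussian Naive Bayes, linear and quadratic
  discriminants), stratified 10-fold cross-validated **balanced accuracy**

      bACC = (1/K) Σ_k  recall_k ,      chance = 1/3 for three classes,

  then a held-out test: PCA to 2 components and a grid-searched SVM on a
  stratified 80/20 split of the augmented trials.
* **Channel selection** — greedy sequential forward selection of 5 channels
  by leave-one-out balanced accuracy.
* **ERP statistics** — global field power

      GFP(t) = sqrt( (1/N) Σ_i ( u_i(t) − ū(t) )² ),

  the spatial standard deviation over the N = 64 electrodes; spatio-temporal
  peak detection (channel, latency, amplitude); per-channel topographic
  values; Kolmogorov–Smirnov normality screening, Mann–Whitney U,
  Kruskal–Wallis with a Tukey-HSD-on-ranks post hoc.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_decode_sweep.R
Rscript analysis/04_final_test.R
Rscript analysis/05_erp_stats.R
```

simulates one session, conditions it, and reproduces the analyses. The
decoding steps print, for the default seed:

```
Mean validation bACC by window (across classifiers):
 start end mean_bacc
    50 150     0.343
   150 250     0.533
   ...
   650 750     0.847
   ...
Best window: [650, 750) ms

Best window [650, 750) ms; SVM linear kernel, cost 1
Validation bACC 0.969 +/- 0.050, held-out test bACC 1.000 (chance 0.333)
Confusion matrix (rows = true condition):
      predicted
true   INNO MOD NOX
  INNO    8   0   0
  MOD     0   8   0
  NOX     0   0   8
```

The sweep localises the discriminative interval to [650, 750) ms — the
window containing the planted noxious central (Cz/C4/C6) component — where
the three conditions separate far above the 33.3 % chance level; the early
windows, which contain only the condition-unspecific 54 ms parietal
response, sit at chance. The ERP step prints the matching biomarkers:

```
NOX peak in [650, 750) ms: Cz at 694 ms, 2.73 uV
Kruskal-Wallis across conditions + background at Cz: H = 48.2, p = 2e-10
```

The same composition is available in one call as
`run_pipeline(pipeline_config(seed = 1))`, which returns a report bundle and
can write it to disk.

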