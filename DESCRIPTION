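Package: painmark
Title: Spatio-Temporal EEG Biomarkers of Phantom-Limb Stimulation Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for identifying spatio-temporal EEG biomarkers
    of innocuous, moderately intense and noxious transcutaneous stimulation of
    a phantom limb, and for classifying the three conditions from evoked
    responses. Provides a synthetic 64-channel evoked-EEG generator with the
    experiment's stimulation schedule and planted condition-specific
    components, ERP preprocessing (Butterworth band-pass and 60 Hz notch
    filtering, epoching, baseline correction, peak-to-peak artifact
    rejection, condition averaging, epoch-split augmentation), max-amplitude
    feature extraction over 100 ms windows, a window-sweep decoding study
    with five classifiers under stratified cross-validation and balanced
    accuracy, sequential forward channel selection, global field power,
    spatio-temporal peak detection and the accompanying nonparametric
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    class,
    stats,
    jsonlite,
    tools,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
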