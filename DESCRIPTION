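Package: painmonitor
Title: Continuous Pain-Intensity Monitoring from Electrodermal and Facial Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for continuous pain-intensity estimation from
    multimodal physiological and behavioural time series: simulation of
    stimulus-locked pain sessions (phasic and tonic heat/electrical stimuli,
    skin-conductance responses, facial-activity channels) with known ground
    truth; per-second temporal-integration descriptors (min, max, mean,
    standard deviation of each channel and its first two derivatives) with
    person-specific standardization, label shifting and 10-s sliding windows;
    construction of stimulus-filtered datasets with an imbalance-reducing
    no-pain retention rule; random-forest baselines and small recurrent
    (LSTM) classifiers and regressors with a facial-response sample-weighting
    augmentation; decision-level mean-score fusion of the two modalities; and
    agreement-based evaluation via micro-averaged F1, mean squared error and
    the intraclass correlation coefficient ICC(3,1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
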