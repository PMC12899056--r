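Package: eegdann
Title: Cross-Subject Neonatal EEG Seizure Detection with Domain-Adversarial Spatiotemporal Networks
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cross-subject neonatal electroencephalogram (EEG) seizure
    detection. Implements multi-annotator consensus labeling with the annotation
    disagreement rate (ADR), a bipolar-montage and short-time Fourier transform
    (STFT) spectrogram preprocessing pipeline, and a domain-adversarial
    spatiotemporal network: a channel-independent convolutional encoder, a
    spatial bidirectional LSTM over the electrode sequence, attention pooling,
    and a gradient reversal layer feeding a subject-identity (domain)
    classifier. Includes a synthetic multi-subject EEG cohort generator with
    controlled inter-subject domain shift and simulated annotators, subject-wise
    stratified cross-validation, data-scaling and ablation experiments, and a
    minimal European Data Format (EDF) reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
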