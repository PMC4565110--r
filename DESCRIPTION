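Package: ecthrv
Title: Post-Operative Holter ECG and Heart Rate Variability Analysis for
    Electrochemotherapy Safety Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing cardiac safety of intra-abdominal
    electrochemotherapy from 24-hour ambulatory (Holter) electrocardiograms.
    Provides a ground-truthed synthetic ECG and electroporation-pulse waveform
    generator, QRS/Q/T peak detection with normal/abnormal beat classification
    and ST-segment deviation flagging, night-window extraction with
    escalating-threshold selection of twelve 5-minute subsegments,
    peak-to-peak QT intervals with rate correction, the standard set of
    time-domain, Poincare and spectral (Welch and autoregressive Burg) heart
    rate variability measures with cubic-spline ectopic editing and 4 Hz
    resampling, electroporation pulse dose quantification (median-of-medians
    voltage and current, energy by power integration), and paired exact
    Wilcoxon signed-rank comparison of before/after treatment sessions with
    dose-response regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
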