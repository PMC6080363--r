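Package: pcgseg
Title: Automatic Segmentation of Heart Sounds in Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments single-channel phonocardiogram (PCG) recordings into the
    first to fourth heart sounds (S1-S4) and the named intervals between them.
    Murmurs are attenuated with an automatic-cutoff low-pass filter whose cutoff
    is read from the smoothed FFT-magnitude envelope; component onsets and
    offsets are located on a mathematical-morphology envelope with adaptive
    amplitude and energy thresholds; the average cardiac cycle is estimated by
    unbiased autocorrelation with side-peak suppression; and components are
    labelled S1/S2/S3/S4 from Stockwell-transform instantaneous frequency and
    inter-component timing rules. Includes a ground-truthed synthetic PCG
    generator, event-detection evaluation metrics (sensitivity, positive
    predictive value, accuracy, signal-murmur ratio), WAV and annotation file
    I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
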