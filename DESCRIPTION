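Package: wheezr
Title: Automatic Wheeze Recognition in Pediatric Lung-Sound Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects wheezes in short two-microphone (chest / ambient)
    pediatric lung-sound recordings. Implements a five-step pipeline:
    band-pass preprocessing and resampling to 11.025 kHz, Hamming-windowed
    short-time Fourier analysis, extraction of above-threshold spectral
    local maxima, linking of maxima across frames into candidate tracks
    under the CORSA continuity rule (dominant frequency > 100 Hz, duration
    > 100 ms), and rule- or tree-based rejection of heartbeat, voice and
    crying noise using both channels, yielding a file-level wheeze /
    no-wheeze verdict with monophonic/polyphonic typing. Includes a seeded
    synthetic lung-sound scene generator with ground-truth annotations and
    evaluation utilities (confusion-matrix metrics, Jonckheere-Terpstra
    trend test, corpus summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
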