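# wheezr

Automatic wheeze recognition in short two-microphone pediatric lung-sound
recordings.

Wheezes — continuous adventitious lung sounds with dominant frequency
> 100 Hz lasting > 100 ms (CORSA definition) — are the key exacerbation
sign in childhood asthma and bronchiolitis, but auscultation is subjective
and small children tolerate only ~30 s of recording, usually in a noisy
consultation room. `wheezr` is for researchers and device developers who
need an objective, reproducible file-level wheeze/no-wheeze verdict from a
chest ("lung") microphone paired with an ambient ("environment")
microphone used as a noise reference.

## The algorithm

For a recording resampled to 11.025 kHz, the pipeline computes
Hamming-windowed short-time spectra `S(t, f)` (window 4096 points ≈ 372 ms,
hop 128 points) and, per frame `t`, a relative threshold

    T(t) = mean{ S(t, f) : 90 Hz ≤ f ≤ 5000 Hz } + Δ        (Δ = 20 dB)

Spectral local maxima above `T(t)` inside 100–5000 Hz are linked across
frames (±3 bins/frame drift, ≤ 2-frame gaps) into candidate tracks; a track
survives only if its span exceeds 100 ms. Each track is then labelled by
ordered rejection rules computed from both channels — duration ≤ 100 ms →
heartbeat; environment ≥ lung level → ambient voice; unstable pitch
(CV > 0.15), intermittency (gap fraction > 0.3) or non-tonal spectrum
(−6 dB peak width > 14 bins) → crying; frequency outside (100, 5000) Hz →
other noise; else wheeze — or by a trained CART tree (`fit_tree()`). A file
is a *wheeze file* iff at least one wheeze track remains; simultaneous
wheeze tracks at distinct frequencies make it *polyphonic*.

Evaluation utilities provide sensitivity = TP/(TP+FN), specificity =
TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN), the Jonckheere–Terpstra
ordered-trend test (exact for small samples, tie-corrected normal
approximation otherwise), and corpus summaries of simultaneous
local-maximum counts per wheeze sound. A seeded synthetic scene generator
(`scene_spec()`, `render_scene()`, `sample_corpus()`) emulates wheezes
within the clinically observed parameter ranges plus heartbeat, crying,
voice and breath-noise interference, with exact ground-truth annotations.

## Worked example

```r
library(wheezr)

spec <- scene_spec(10, events = list(
  scene_event("wheeze", onset_s = 2, duration_ms = 600, freq_hz = 420, snr_db = 18),
  scene_event("voice",  onset_s = 5, duration_ms = 600, freq_hz = 220),
  scene_event("heartbeat", onset_s = 7.5)), seed = 8)
sc  <- render_scene(spec)
det <- wheeze_detect(sc$recording)
summary(det)
```

```
Wheeze recognition: verdict WHEEZE (monophonic, 1 wheeze track(s))
10.0 s analysed, 5 candidate track(s)

Candidate tracks:
 track start_s duration_ms mean_freq_hz mean_level_db         label
     1   1.788       661.8        420.0        -36.82        wheeze
     2   4.818       603.7        220.7        -40.43 ambient_voice
     3   4.830       580.5        439.2        -43.48 ambient_voice
     4   4.865       510.8        659.5        -46.19 ambient_voice
     5   4.899       429.6        880.2        -48.72 ambient_voice
```

The 420 Hz synthetic wheeze is recovered as one stable track (the 372 ms
analysis window dilates its apparent duration); the voice burst appears as
four harmonic tracks, each rejected because it is louder on the
environment microphone; the 80 ms heartbeat never forms a track at all.
Verdict: wheeze, monophonic.

Confusion-matrix metrics print as percentages with their fractions:

```r
metrics(confusion_counts(tp = 65, fp = 7, fn = 0, tn = 142))
```

```
Sensitivity 100.0% (65/65)
Specificity 95.3% (142/149)
PPV         90.3% (65/72)
NPV         100.0% (142/142)
```

A thin command-line front end ships in `inst/cli/wheezr`
(`detect` / `synth` / `eval` subcommands; `detect` exits 0 for wheeze,
1 for no-wheeze, ≥ 2 on error).

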