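---
title: "Wheeze recognition in two-microphone pediatric lung sounds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wheeze recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the signal model

A wheeze is a continuous adventitious lung sound superimposed on breath
sounds. Under the Computerized Respiratory Sound Analysis (CORSA)
definitions it is a narrowband tone with dominant frequency above 100 Hz
lasting longer than 100 ms, typically confined to 100–5000 Hz. In a
pediatric consultation room the recording also contains heartbeats, the
patient's crying, and voices — and the examination must be short (about
30 s), because infants will not tolerate more.

`wheezr` implements a five-step recognition pipeline for recordings made
with two microphones: a chest-contact *lung* microphone and an *environment*
microphone that serves as an ambient-noise reference.

1. **Preprocessing.** Both channels are band-limited (Butterworth high/low
   pass, applied zero-phase) and resampled to 11.025 kHz at 16-bit
   amplitude resolution.
2. **Short-time spectra.** A Hamming window of 4096 points (371.5 ms,
   conventionally quoted as 372 ms) is advanced 128 points (11.6 ms) per
   frame; one-sided periodograms are expressed in dB, with 0 dB defined as
   the peak bin of a full-scale bin-centred sine.
3. **Local maxima.** In each frame, bins that exceed both frequency
   neighbours and a relative threshold — the mean dB level over 90–5000 Hz
   plus an offset — are candidate wheeze points, restricted to 100–5000 Hz.
4. **Track linking.** Maxima are associated across frames (nearest
   frequency within ±3 bins per frame of separation, gaps up to 2 frames
   bridged). A track is kept if its inclusive frame span exceeds 100 ms and
   does not exceed a 3 s cap; over-long runs are split at their
   weakest-margin point and re-tested.
5. **Noise rejection and verdict.** Per-track features computed on *both*
   channels feed an ordered rule list (or optionally a trained CART tree)
   that labels each track wheeze / heartbeat / ambient voice / crying /
   other noise. A file is a *wheeze file* if at least one track survives as
   a wheeze; simultaneous wheeze tracks more than one bin apart make it
   *polyphonic*, otherwise *monophonic*.

## Tunable parameters and why their defaults are what they are

| parameter | default | unit | rationale |
|---|---|---|---|
| `target_rate` | 11 025 | Hz | analysis standard; Nyquist 5 512.5 Hz covers the wheeze band |
| `highpass_hz` / `lowpass_hz` | 50 / 5 500 | Hz | just outside the 90–5000 Hz thresholding band so the filters do not shape its edges |
| `window_points` / `hop_points` | 4096 / 128 | samples | 372 ms frequency resolution (2.69 Hz/bin) with 11.6 ms hop; the hop is the temporal resolution of "continued" |
| `threshold_offset_db` | 20 | dB | see below |
| `min_duration_ms` | 100 | ms | the CORSA continuity rule, exclusive bound ("> 100 ms"): 9 frames (104.5 ms) pass, 8 frames (92.9 ms) do not |
| `max_duration_ms` | 3 000 | ms | proxy for "within one expiration"; the longest clinically reported wheeze is 1 616 ms |
| `max_bin_drift_per_frame` | 3 | bins | allows ±8 Hz/ms pitch drift while keeping crossing sounds separable |
| `max_gap_frames` | 2 | frames | bridges momentary dropouts (23 ms) without merging separate events |
| `max_freq_cv` | 0.15 | – | pitch-stability bound; wheeze tracks measure ≲ 0.01 |
| `max_gap_fraction` | 0.3 | – | intermittency bound |
| `max_peak_width_bins` | 14 | bins | tonality bound; see below |

**The threshold offset.** The per-frame threshold is the 90–5000 Hz band
mean of the dB spectrum plus an offset. Because the window overlaps 97%
between hops, a chance periodogram excursion of the noise floor persists
for ~30 frames (≈350 ms) — long enough to satisfy the duration rule — so
the offset must place the threshold above essentially all noise-floor
bins. For a white floor the periodogram is exponentially distributed: an
offset of +10 dB over the dB-mean leaves ~0.4% of bins above threshold and
floods the tracker with hundreds of stable pseudo-tracks per file, while
+14 dB already silences the floor completely in our simulations. A pure
tone, by contrast, concentrates its energy into a single bin and gains
~33 dB over the same floor, so even the weakest clinically reported wheeze
(3 dB above the breath noise in the time domain) still clears a +20 dB
threshold with ≈6 dB of margin. The default of **20 dB** sits midway
between the noise transition and the weakest wheeze; it is configurable.

**The tonality feature (`peak_width_bins`).** Duration, channel contrast,
pitch stability and band membership alone cannot reject crying under a
372 ms window: a pitch glide of a few hundred Hz/s smears into a broad
spectral plateau whose internal ripples fragment into locally stable,
lung-dominant tracks longer than 100 ms — indistinguishable from wheezes
by those four criteria. What does distinguish them is spectral width: a
wheeze is a tone, and even a 100 ms wheeze (whose own mainlobe is widened
to ~19 Hz ≈ 7 bins by its short duration) stays within a handful of bins,
while glide plateaus measure tens of bins. `peak_width_bins` is the mean
contiguous width around each track point within 6 dB of the peak; in our
simulations wheeze tracks measure ≤ 8 bins and crying plateaus ≥ 19
(median 46), so the cutoff of **14 bins** sits in the gap. A fixed-flank
"sharpness" (level minus the mean 3–6 bins away) was considered and
rejected: it misclassifies the shortest wheezes, whose own mainlobe
reaches those flanks.

**Classification rules, in order.** (1) span ≤ 100 ms → heartbeat;
(2) environment level at the track's cells ≥ lung level → ambient voice;
(3) frequency CV > 0.15, gap fraction > 0.3 or peak width > 14 bins →
crying; (4) mean frequency outside (100, 5000) Hz → other noise;
(5) otherwise → wheeze. Every label carries the ordered rule path that
produced it. `fit_tree()` can replace the rules with a depth-limited CART
tree over the same features; its predictions expose their root-to-leaf
path the same way.

## What the synthetic generator emulates — and what it does not

No audio corpus accompanies the clinical validation, so the package ships
a seeded scene generator whose defaults emulate the study conditions:
30 s two-channel recordings; wheezes as amplitude-enveloped sinusoids
(one partner tone when polyphonic, drawn for ~63% of events) with
frequency and duration drawn from normal distributions truncated to the
clinically observed ranges (422 ± 233 Hz on [100, 1380]; 388 ± 245 ms on
[100, 1616]) and intensity uniform over [3, 44] dB above the breath-noise
floor; heartbeats as sub-90 Hz thumps shorter than 100 ms; crying as
chest-dominant harmonic pitch glides (fundamental 300–450 Hz sweeping
threefold over 0.8–1.5 s — infant cry expirations sweep hundreds of Hz
per second); voices as environment-dominant harmonic bursts. Events leak
into the opposite channel attenuated by 12 dB, a fixture constant, not a
measured device property.

Deliberate simplifications, and hence limits on what passing tests show
about real data:

* **Breath noise is white within the analysis band.** Real breath sounds
  tilt downward with frequency. With the tilted floor, a single global
  band-mean threshold would sit below the low-frequency floor and above
  the high-frequency floor; handling that would require a frequency-
  dependent threshold the pipeline deliberately does not have.
* **Wheezes are pure tones.** Real wheezes carry slight pitch drift and
  amplitude modulation; the drift allowance and gap bridging exist for
  them but are exercised only mildly by the generator.
* No room reverberation, no microphone coloration, no nasal-congestion
  sounds (no described acoustic signature), and cry vibrato is not
  modelled: strong frequency modulation concentrates energy at its
  turning points into tonal ridges, which would require a more elaborate
  cry model to render faithfully.

Synthetic-corpus results (file-level sensitivity 1.0, specificity
≥ 0.95 at wheeze SNR ≥ 10 dB) therefore demonstrate the internal
consistency of the pipeline under the stated acoustic model, not clinical
performance.

## Numerical choices

* **Filter order of operations.** Anti-alias low-pass before resampling,
  high-pass after, both zero-phase (`filtfilt`) so event onsets feeding
  the 100 ms rule are not delayed. When the low-pass corner lies at or
  above 98% of the current Nyquist it is skipped: an order-4 IIR there is
  numerically unstable and removes nothing; the resampler's own kernel
  provides the anti-aliasing.
* **Resampling** uses a windowed-sinc kernel (half-width 16 output
  samples, scaled by the decimation factor; Hann-windowed, locally
  DC-normalized). Passband flat to < 0.01 dB below 3 kHz, alias rejection
  ≈ 70 dB; output length is `round(n · rate_out / rate_in)`.
* **Quantization** rounds to the nearest of 2^16 uniform levels on
  [−1, 1), keeping a float processing path.
* **Spectral normalization** divides by the window's coherent gain
  (Σw/2), so a full-scale bin-centred sine reads 0 dB. All thresholds are
  relative (band mean + offset), so the reference cancels; track skeletons
  are exactly invariant to global gain.
* **Linking tie-breaks.** Peak–track pairs are assigned greedily by
  smallest frequency distance, then track seniority, then bin order —
  deterministic throughout. Duration is the inclusive frame span times the
  hop.
* **Degenerate inputs.** Silence yields no tracks; an all-tied
  Jonckheere–Terpstra sample yields p = 1 by convention (this is exactly
  the "every wheeze file detected in every age group" case); a metric with
  a zero denominator is reported as undefined rather than 0 or an error.
  Displayed percentages round half-up to one decimal.
* **Jonckheere–Terpstra.** The statistic sums pairwise Mann–Whitney
  counts (ties = ½) over ordered group pairs. For total n ≤ 12 the p-value
  is exact — by convolution of Mann–Whitney null distributions when the
  data are untied, by complete enumeration of group assignments when tied —
  otherwise a normal approximation with tie-corrected variance and
  continuity correction is used. Two-sided by default.

## Open design points resolved here

* The classifier operates **per candidate track**, with the file verdict
  an OR over track labels; nothing in the flow requires file-level
  features, and per-track labels give an auditable trail.
* Polyphonic typing: two wheeze tracks overlapping in time with mean
  frequencies more than one bin (2.69 Hz) apart.
* The 30 s protocol length is advisory: shorter inputs process normally
  (the command-line tool warns).
* Simulated corpora in the test suite and the acceptance script use 10 s
  scenes, 65 wheeze + 149 noise files: with events an order of magnitude
  shorter than a scene, a 10 s scene exercises the same per-event physics
  as a 30 s one at a third of the cost, and the file counts match the
  validation study's class balance.

## Known limitations

The default rule constants (offset 20 dB, width 14 bins, CV 0.15) were
calibrated on the synthetic acoustic model above; real recordings with
tilted breath-noise spectra or reverberant voices will likely need the
trained-tree path (`fit_tree()`) on labelled data. The pipeline has no
respiratory-phase segmentation, so "within the expiratory duration" is
approximated by a fixed cap, and no wheeze-rate (Tw/Ttot) output is
provided.
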