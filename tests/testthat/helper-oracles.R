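# Independent oracles and fixture builders shared across tests.

# Naive O(N^2) DFT periodogram in dB, normalized like the implementation
# (full-scale bin-centred sine -> 0 dB). Computed by direct summation in
# chunks of bins; no FFT anywhere.
naive_dft_power_db <- function(x, db_floor = -120) {
  n <- length(x)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * win
  coh <- sum(win) / 2
  n_bins <- n %/% 2 + 1
  p <- numeric(n_bins)
  t <- 0:(n - 1)
  for (k0 in seq(0, n_bins - 1, by = 256)) {
    ks <- k0:min(k0 + 255, n_bins - 1)
    W <- exp(-2i * pi * outer(t, ks) / n)
    p[ks + 1] <- (Mod(crossprod(W, xw)) / coh)^2
  }
  10 * log10(pmax(p, 10^(db_floor / 10)))
}

# Association oracle for clean fixtures (well-separated stable tones): peaks
# are grouped by frequency proximity (split where sorted unique bins jump by
# more than the drift allowance), then each group's frame run is one track
# if its inclusive span exceeds the duration rule. Valid only when tones are
# separated by much more than the drift window and do not cross.
oracle_track_count <- function(peaks, hop_s, cfg) {
  if (nrow(peaks) == 0) return(list(n_tracks = 0L, n_points = 0L))
  ub <- sort(unique(peaks$bin))
  grp_id <- cumsum(c(1, diff(ub) > cfg$max_bin_drift_per_frame *
                                     (cfg$max_gap_frames + 1)))
  grp <- grp_id[match(peaks$bin, ub)]
  n_tracks <- 0L; n_points <- 0L
  for (g in unique(grp)) {
    fr <- sort(unique(peaks$frame[grp == g]))
    # split the frame run at unbridgeable gaps
    runs <- split(fr, cumsum(c(1, diff(fr) > cfg$max_gap_frames + 1)))
    for (r in runs) {
      dur <- (max(r) - min(r) + 1) * hop_s * 1000
      if (dur > cfg$min_duration_ms && dur <= cfg$max_duration_ms) {
        n_tracks <- n_tracks + 1L
        # one peak per frame per track: transition frames can carry a
        # duplicate maximum that no association may use twice
        n_points <- n_points + length(r)
      }
    }
  }
  list(n_tracks = n_tracks, n_points = n_points)
}

# a flat spectral series with optional injected constant-frequency events:
# events = list(list(frames =, bin =, level =))
flat_series <- function(n_frames, n_bins = 257, floor_db = -80,
                        sample_rate = 11025, events = list()) {
  w <- (n_bins - 1) * 2
  cfg <- spectral_config(window_points = w, hop_points = min(128L, w))
  P <- matrix(floor_db, n_frames, n_bins)
  for (e in events) P[cbind(e$frames, rep(e$bin, length(e$frames)))] <- e$level
  spectral_series(P, sample_rate, cfg)
}

# hand-built candidate_tracks object for classifier-level tests
fake_tracks <- function(rows, bin_hz = 11025 / 4096, hop_s = 128 / 11025) {
  summ <- cbind(track = seq_len(nrow(rows)), rows)
  pts <- lapply(seq_len(nrow(rows)), function(i)
    data.frame(frame = 1L, bin = 100L, freq_hz = rows$mean_freq_hz[i],
               level_db = -30, margin_db = 10))
  structure(list(summary = summ, points = pts, hop_s = hop_s,
                 bin_hz = bin_hz), class = "candidate_tracks")
}

feature_row <- function(duration_ms = 300, mean_freq_hz = 400,
                        freq_cv = 0.02, mean_margin_db = 12,
                        env_minus_lung_db = -12, gap_fraction = 0,
                        level_sd_db = 1, peak_width_bins = 3) {
  data.frame(duration_ms = duration_ms, mean_freq_hz = mean_freq_hz,
             freq_cv = freq_cv, mean_margin_db = mean_margin_db,
             env_minus_lung_db = env_minus_lung_db,
             gap_fraction = gap_fraction, level_sd_db = level_sd_db,
             peak_width_bins = peak_width_bins)
}

tone <- function(freq, dur_s, rate, amp = 1) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * rate) - 1)) / rate)
}
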