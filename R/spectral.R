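#' Short-time spectral analysis configuration
#'
#' Frame length, hop and window for the spectrogram on which wheeze
#' candidates are detected. The defaults give a 4096-point (371.5 ms,
#' conventionally quoted as 372 ms) Hamming window advanced 128 points
#' (11.6 ms) per frame at the 11.025 kHz analysis rate.
#'
#' @param window_points Window length in samples; must be a power of two.
#' @param hop_points Frame advance in samples.
#' @param window_kind Window function; only `"hamming"` is supported.
#' @param db_floor Lower clamp for spectral levels in dB.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(window_points = 4096L, hop_points = 128L,
                            window_kind = "hamming", db_floor = -120) {
  window_points <- as.integer(window_points)
  hop_points <- as.integer(hop_points)
  if (hop_points <= 0 || hop_points > window_points)
    stop("config error: need 0 < hop_points <= window_points")
  if (bitwAnd(window_points, window_points - 1L) != 0L)
    stop("config error: window_points must be a power of two")
  window_kind <- match.arg(window_kind, "hamming")
  structure(list(window_points = window_points, hop_points = hop_points,
                 window_kind = window_kind, db_floor = db_floor),
            class = "spectral_config")
}

#' Window duration in milliseconds
#'
#' @param cfg A [spectral_config()].
#' @param sample_rate Sampling rate in Hz.
#' @param digits Rounding for the returned value (0 reproduces the
#'   conventional "372 ms" figure for the defaults).
#' @return Window duration in ms.
#' @export
window_duration_ms <- function(cfg = spectral_config(), sample_rate = 11025,
                               digits = 0) {
  round(cfg$window_points / sample_rate * 1000, digits)
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Construct a spectral series from a precomputed dB matrix
#'
#' Low-level constructor, used mostly by tests and by
#' [compute_spectral_series()]. Levels are in dB relative to a full-scale
#' sine (a full-scale bin-centred tone peaks at 0 dB).
#'
#' @param power_db Numeric matrix, frames in rows, frequency bins in columns.
#' @param sample_rate Sampling rate in Hz.
#' @param cfg The [spectral_config()] the matrix was computed with.
#' @return A `spectral_series` object with fields `power_db`,
#'   `frame_times_s`, `bin_freqs_hz`, `sample_rate` and `config`.
#' @export
spectral_series <- function(power_db, sample_rate, cfg = spectral_config()) {
  power_db <- as.matrix(power_db)
  structure(list(
    power_db = power_db,
    frame_times_s = (seq_len(nrow(power_db)) - 1) * cfg$hop_points / sample_rate,
    bin_freqs_hz = (seq_len(ncol(power_db)) - 1) * sample_rate / cfg$window_points,
    sample_rate = sample_rate,
    config = cfg), class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf(
    "<spectral_series> %d frames x %d bins, %g Hz, hop %.1f ms, window %.1f ms\n",
    nrow(x$power_db), ncol(x$power_db), x$sample_rate,
    x$config$hop_points / x$sample_rate * 1000,
    x$config$window_points / x$sample_rate * 1000))
  invisible(x)
}

#' Compute the dB spectrogram of one channel (pipeline step 2)
#'
#' Hamming-windowed one-sided periodograms at each hop. Power is normalized
#' by the window's coherent gain so that a full-scale sine locked to a bin
#' centre reads 0 dB; levels are clamped below at `cfg$db_floor`.
#'
#' @param channel Numeric sample vector.
#' @param sample_rate Sampling rate in Hz.
#' @param cfg A [spectral_config()].
#' @return A [spectral_series()].
#' @export
compute_spectral_series <- function(channel, sample_rate,
                                    cfg = spectral_config()) {
  n <- length(channel)
  W <- cfg$window_points
  if (n < W) stop("input too short: need at least one full analysis window")
  hop <- cfg$hop_points
  n_frames <- (n - W) %/% hop + 1L
  win <- hamming_window(W)
  coh_gain <- sum(win) / 2                 # full-scale sine -> 0 dB
  n_bins <- W %/% 2L + 1L
  out <- matrix(cfg$db_floor, nrow = n_frames, ncol = n_bins)

  block <- 256L                            # frames per FFT batch
  for (b0 in seq.int(1L, n_frames, by = block)) {
    b1 <- min(b0 + block - 1L, n_frames)
    idx <- outer(seq_len(W), (seq.int(b0, b1) - 1L) * hop, "+")
    fr <- matrix(channel[idx], nrow = W) * win
    sp <- stats::mvfft(fr)[seq_len(n_bins), , drop = FALSE]
    p <- (Mod(sp) / coh_gain)^2
    out[b0:b1, ] <- t(10 * log10(pmax(p, 10^(cfg$db_floor / 10))))
  }
  spectral_series(out, sample_rate, cfg)
}

band_bins <- function(series, band_lo, band_hi) {
  which(series$bin_freqs_hz >= band_lo & series$bin_freqs_hz <= band_hi)
}

#' Mean spectral level over a frequency band at one frame
#'
#' @param series A [spectral_series()].
#' @param frame Frame index (1-based).
#' @param band_lo,band_hi Band edges in Hz; the band must contain at least
#'   one bin and lie within \[0, Nyquist\].
#' @return Mean of `power_db` over the band's bins, in dB.
#' @export
band_mean_level <- function(series, frame, band_lo, band_hi) {
  if (band_lo >= band_hi) stop("config error: band_lo must be < band_hi")
  if (band_hi > series$sample_rate / 2)
    stop("config error: band exceeds the Nyquist frequency (",
         series$sample_rate / 2, " Hz)")
  bins <- band_bins(series, band_lo, band_hi)
  if (length(bins) == 0) stop("config error: band contains no bins")
  mean(series$power_db[frame, bins])
}

#' Export a spectrogram as a long-format data frame
#'
#' One row per (frame, bin) cell: `frame_time_s`, `freq_hz`, `power_db`.
#' Suitable for plotting or writing as a columnar text file.
#'
#' @param series A [spectral_series()].
#' @return A data frame.
#' @export
spectrogram_frame <- function(series) {
  data.frame(
    frame_time_s = rep(series$frame_times_s, times = length(series$bin_freqs_hz)),
    freq_hz = rep(series$bin_freqs_hz, each = nrow(series$power_db)),
    power_db = as.vector(series$power_db))
}
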