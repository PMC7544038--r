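#' Two-channel lung-sound recording
#'
#' Container for a chest-microphone ("lung") channel and an ambient
#' ("environment") channel sampled at a common rate. Samples are full-scale
#' floats in \[-1, 1\].
#'
#' @param lung Numeric vector, lung-microphone samples.
#' @param environment Numeric vector, environment-microphone samples. Must
#'   have the same length as `lung`.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `lung_recording` with fields `lung`,
#'   `environment`, `sample_rate` and `duration_s`.
#' @export
lung_recording <- function(lung, environment, sample_rate) {
  lung <- as.numeric(lung)
  environment <- as.numeric(environment)
  if (length(lung) != length(environment))
    stop("lung and environment channels must have the same length")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a positive number")
  if (anyNA(lung) || anyNA(environment) ||
      !all(is.finite(lung)) || !all(is.finite(environment)))
    stop("all samples must be finite")
  structure(
    list(lung = lung, environment = environment,
         sample_rate = sample_rate,
         duration_s = length(lung) / sample_rate),
    class = "lung_recording")
}

#' @export
print.lung_recording <- function(x, ...) {
  cat(sprintf("<lung_recording> %d samples/channel @ %g Hz (%.2f s)\n",
              length(x$lung), x$sample_rate, x$duration_s))
  invisible(x)
}

# ---- minimal RIFF/WAVE PCM reader & writer -------------------------------
# Supports uncompressed PCM (format 1: 8/16/24/32-bit integer) and IEEE
# float (format 3: 32-bit). Written against the RIFF spec; no streaming.

read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      u16 <- function(i) sum(as.integer(body[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(body[i:(i + 3)]) * 256^(0:3))
      fmt <- list(format = u16(1), channels = u16(3),
                  sample_rate = u32(5), bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)  # skip unknown chunk
    }
    if (sz %% 2 == 1) readBin(con, "raw", 1)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV (missing fmt or data chunk): ", path)
  if (!fmt$format %in% c(1L, 3L))
    stop("unsupported WAV encoding (only integer PCM and float32): ", path)

  bytes <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% bytes
  if (fmt$format == 3L) {
    if (fmt$bits != 32) stop("float WAV must be 32-bit")
    x <- readBin(data_raw, "double", n_total, size = 4, endian = "little")
  } else if (fmt$bits == 8) {
    # 8-bit PCM is unsigned
    x <- (as.integer(data_raw) - 128) / 128
  } else if (fmt$bits == 16) {
    x <- readBin(data_raw, "integer", n_total, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$bits == 24) {
    b <- matrix(as.integer(data_raw[seq_len(n_total * 3)]), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else if (fmt$bits == 32) {
    x <- readBin(data_raw, "integer", n_total, size = 4, endian = "little") / 2^31
  } else stop("unsupported bit depth: ", fmt$bits)

  n_frames <- n_total %/% fmt$channels
  x <- matrix(x[seq_len(n_frames * fmt$channels)], nrow = fmt$channels)
  list(samples = x, sample_rate = fmt$sample_rate,
       channels = fmt$channels, bits = fmt$bits)
}

write_wav <- function(samples, sample_rate, path) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  n_ch <- nrow(samples)
  x <- as.vector(samples)               # column-major = interleaved frames
  x <- pmin(pmax(x, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  data_sz <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, size = 4,
           endian = "little")                             # byte rate
  writeBin(n_ch * 2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a two-channel recording from a WAV file
#'
#' Channel 0 is conventionally the lung-sound microphone and channel 1 the
#' environment microphone. A mono file can serve both roles only when both
#' indices are explicitly set to 0.
#'
#' @param path Path to a PCM or float32 WAV file.
#' @param lung_channel_index Zero-based channel index of the lung microphone.
#' @param env_channel_index Zero-based channel index of the environment
#'   microphone.
#' @return A [lung_recording()].
#' @export
read_recording <- function(path, lung_channel_index = 0L,
                           env_channel_index = 1L) {
  w <- read_wav(path)
  need <- max(lung_channel_index, env_channel_index) + 1L
  if (w$channels < need)
    stop(sprintf("WAV has %d channel(s); channel index %d requested",
                 w$channels, need - 1L))
  lung_recording(w$samples[lung_channel_index + 1L, ],
                 w$samples[env_channel_index + 1L, ],
                 w$sample_rate)
}

#' Write a recording to a 16-bit stereo WAV file
#'
#' @param rec A [lung_recording()]. Channel 0 receives the lung channel,
#'   channel 1 the environment channel.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "lung_recording"))
  write_wav(rbind(rec$lung, rec$environment), rec$sample_rate, path)
}

#' Preprocessing configuration
#'
#' Settings for the first pipeline step: band-limit both channels and
#' resample to the analysis standard of 11.025 kHz / 16 bit.
#'
#' @param target_rate Output sampling rate in Hz.
#' @param quantization_bits Output amplitude resolution in bits.
#' @param highpass_hz High-pass corner (Hz); removes contact rumble and
#'   mains-frequency interference below the analysis band.
#' @param lowpass_hz Low-pass (anti-alias) corner in Hz; must lie below the
#'   target Nyquist frequency.
#' @param filter_order Butterworth order of each filter (applied forward and
#'   backward, so the effective roll-off is doubled and the phase is zero).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_rate = 11025, quantization_bits = 16L,
                              highpass_hz = 50, lowpass_hz = 5500,
                              filter_order = 4L) {
  if (!(highpass_hz > 0 && highpass_hz < lowpass_hz &&
        lowpass_hz < target_rate / 2))
    stop("config error: need 0 < highpass_hz < lowpass_hz < target_rate/2")
  if (quantization_bits < 2 || quantization_bits > 32)
    stop("config error: quantization_bits out of range")
  structure(list(target_rate = target_rate,
                 quantization_bits = as.integer(quantization_bits),
                 highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

# zero-phase Butterworth; skipped when the corner sits essentially at Nyquist
# (an order-4 IIR there is numerically unstable and removes nothing).
zp_butter <- function(x, corner_hz, rate, order, type) {
  w <- corner_hz / (rate / 2)
  if (type == "low" && w >= 0.98) return(x)
  bf <- signal::butter(order, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

# windowed-sinc resampler (arbitrary rational ratio, zero phase, flat
# passband); the kernel half-width scales with the decimation factor so the
# anti-alias cutoff keeps ~80 dB of stopband rejection
resample_to <- function(x, from_rate, to_rate, half_width = 16L) {
  if (from_rate == to_rate) return(x)
  r <- to_rate / from_rate
  n_in <- length(x)
  n_out <- round(n_in * r)
  cutoff <- 0.97 * min(1, r)              # fraction of the input Nyquist
  L <- ceiling(half_width / min(1, r))    # kernel half-width, input samples
  t_in <- (seq_len(n_out) - 1) / r        # fractional input positions
  k0 <- floor(t_in)
  frac <- t_in - k0
  acc <- numeric(n_out)
  wsum <- numeric(n_out)
  for (j in (-L + 1L):L) {
    d <- j - frac
    w <- cutoff * sinc(cutoff * d) * (0.5 + 0.5 * cos(pi * d / L))
    k <- k0 + j
    ok <- k >= 0 & k < n_in
    acc[ok] <- acc[ok] + x[k[ok] + 1L] * w[ok]
    wsum <- wsum + w
  }
  # normalize by the kernel's local DC gain (removes residual ripple)
  acc / wsum
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

quantize <- function(x, bits) {
  full <- 2^(bits - 1)
  pmin(pmax(round(x * full), -full), full - 1) / full
}

#' Preprocess a recording (pipeline step 1)
#'
#' Low-pass filters each channel for anti-aliasing, resamples to the target
#' rate, high-pass filters to remove sub-band rumble, and quantizes to the
#' configured bit depth. Both filters are zero-phase so that event onsets
#' (which feed the downstream 100 ms duration rule) are not shifted.
#'
#' @param rec A [lung_recording()].
#' @param cfg A [preprocess_config()].
#' @return A new [lung_recording()] at `cfg$target_rate`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "lung_recording"))
  if (!inherits(cfg, "preprocess_config")) stop("config error: cfg invalid")
  one <- function(x) {
    x <- zp_butter(x, cfg$lowpass_hz, rec$sample_rate, cfg$filter_order, "low")
    x <- resample_to(x, rec$sample_rate, cfg$target_rate)
    x <- zp_butter(x, cfg$highpass_hz, cfg$target_rate, cfg$filter_order, "high")
    quantize(x, cfg$quantization_bits)
  }
  lung_recording(one(rec$lung), one(rec$environment), cfg$target_rate)
}
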