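#' Candidate-detection configuration (steps 3 and 4)
#'
#' The per-frame threshold is the mean spectral level over
#' `threshold_band_lo`..`threshold_band_hi` plus `threshold_offset_db`.
#' Local maxima above it, inside the candidate band, are linked across
#' frames into tracks; a track is kept only if it lasts longer than
#' `min_duration_ms` (the CORSA "> 100 ms" continuity rule) and no longer
#' than `max_duration_ms` (a proxy for "within one expiration").
#'
#' @param threshold_band_lo,threshold_band_hi Band (Hz) whose mean level
#'   sets the per-frame threshold.
#' @param threshold_offset_db Offset (dB) added to the band mean.
#' @param candidate_band_lo,candidate_band_hi Band (Hz) in which local
#'   maxima count as wheeze candidates.
#' @param min_duration_ms Minimum track duration (exclusive bound), ms.
#' @param max_duration_ms Maximum track duration, ms; longer tracks are
#'   split at their weakest point and re-tested.
#' @param max_bin_drift_per_frame Maximum frequency drift between linked
#'   points, in bins per frame of separation.
#' @param max_gap_frames Maximum number of consecutive frames a track may
#'   bridge without a point.
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold_band_lo = 90, threshold_band_hi = 5000,
                             threshold_offset_db = 20,
                             candidate_band_lo = 100, candidate_band_hi = 5000,
                             min_duration_ms = 100, max_duration_ms = 3000,
                             max_bin_drift_per_frame = 3L,
                             max_gap_frames = 2L) {
  if (min_duration_ms >= max_duration_ms)
    stop("config error: min_duration_ms must be < max_duration_ms")
  if (max_bin_drift_per_frame < 0 || max_gap_frames < 0)
    stop("config error: drift and gap must be >= 0")
  structure(list(threshold_band_lo = threshold_band_lo,
                 threshold_band_hi = threshold_band_hi,
                 threshold_offset_db = threshold_offset_db,
                 candidate_band_lo = candidate_band_lo,
                 candidate_band_hi = candidate_band_hi,
                 min_duration_ms = min_duration_ms,
                 max_duration_ms = max_duration_ms,
                 max_bin_drift_per_frame = as.integer(max_bin_drift_per_frame),
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "detection_config")
}

#' Per-frame detection threshold (step 3)
#'
#' @param series A [spectral_series()].
#' @param frame Frame index (1-based).
#' @param cfg A [detection_config()].
#' @return Threshold in dB: band mean plus the configured offset.
#' @export
frame_threshold <- function(series, frame, cfg = detection_config()) {
  band_mean_level(series, frame, cfg$threshold_band_lo, cfg$threshold_band_hi) +
    cfg$threshold_offset_db
}

all_frame_thresholds <- function(series, cfg) {
  bins <- band_bins(series, cfg$threshold_band_lo, cfg$threshold_band_hi)
  if (length(bins) == 0) stop("config error: threshold band contains no bins")
  rowMeans(series$power_db[, bins, drop = FALSE]) + cfg$threshold_offset_db
}

#' Extract above-threshold spectral local maxima (step 3)
#'
#' A peak is a bin strictly greater than both frequency neighbours, inside
#' the candidate band, with level at or above that frame's threshold.
#'
#' @param series A [spectral_series()].
#' @param cfg A [detection_config()].
#' @return Data frame with columns `frame`, `bin` (both 1-based), `freq_hz`,
#'   `level_db`, `margin_db` (level above the frame threshold), sorted by
#'   (frame, bin).
#' @export
extract_local_maxima <- function(series, cfg = detection_config()) {
  P <- series$power_db
  thr <- all_frame_thresholds(series, cfg)
  nb <- ncol(P)
  cand <- band_bins(series, cfg$candidate_band_lo, cfg$candidate_band_hi)
  cand <- cand[cand > 1 & cand < nb]      # edge bins lack a neighbour
  if (length(cand) == 0)
    return(data.frame(frame = integer(), bin = integer(), freq_hz = numeric(),
                      level_db = numeric(), margin_db = numeric()))
  sub <- P[, cand, drop = FALSE]
  is_peak <- sub > P[, cand - 1L, drop = FALSE] &
             sub > P[, cand + 1L, drop = FALSE] &
             sub >= thr
  w <- which(is_peak, arr.ind = TRUE)
  fr <- w[, 1L]; bn <- cand[w[, 2L]]
  o <- order(fr, bn)
  data.frame(frame = fr[o], bin = bn[o],
             freq_hz = series$bin_freqs_hz[bn[o]],
             level_db = P[cbind(fr[o], bn[o])],
             margin_db = P[cbind(fr[o], bn[o])] - thr[fr[o]])
}

# duration convention: inclusive frame span times the hop
span_duration_ms <- function(first_frame, last_frame, hop_s) {
  (last_frame - first_frame + 1) * hop_s * 1000
}

track_summary_row <- function(pts, hop_s, frame_times) {
  span <- pts$frame[nrow(pts)] - pts$frame[1] + 1L
  data.frame(
    start_s = frame_times[pts$frame[1]],
    end_s = frame_times[pts$frame[1]] + span * hop_s,
    duration_ms = span * hop_s * 1000,
    n_points = nrow(pts),
    mean_freq_hz = mean(pts$freq_hz),
    freq_sd_hz = if (nrow(pts) > 1) stats::sd(pts$freq_hz) else 0,
    mean_level_db = mean(pts$level_db),
    mean_margin_db = mean(pts$margin_db),
    n_gap_frames = span - nrow(pts))
}

# drop the weakest-margin interior point of an over-long run and re-test
# both remaining halves against the duration window
split_overlong <- function(pts, cfg, hop_s) {
  dur <- span_duration_ms(pts$frame[1], pts$frame[nrow(pts)], hop_s)
  if (dur <= cfg$max_duration_ms) {
    if (dur > cfg$min_duration_ms) return(list(pts)) else return(list())
  }
  if (nrow(pts) < 3) return(list())
  k <- which.min(pts$margin_db[2:(nrow(pts) - 1)]) + 1L
  c(split_overlong(pts[seq_len(k - 1L), , drop = FALSE], cfg, hop_s),
    split_overlong(pts[seq.int(k + 1L, nrow(pts)), , drop = FALSE], cfg, hop_s))
}

#' Link local maxima across frames into candidate tracks (step 4)
#'
#' Greedy frame-order association: each open track is extended to the
#' nearest-frequency peak of the current frame within
#' `max_bin_drift_per_frame` bins per frame of separation; gaps up to
#' `max_gap_frames` frames are bridged; every peak joins at most one track.
#' Tracks are kept when their inclusive frame span exceeds
#' `min_duration_ms`; spans over `max_duration_ms` are split at their
#' weakest-margin point and re-tested.
#'
#' @param peaks Data frame as returned by [extract_local_maxima()].
#' @param series The [spectral_series()] the peaks came from (supplies the
#'   hop and frame clock).
#' @param cfg A [detection_config()].
#' @return A `candidate_tracks` object: `summary` (one row per retained
#'   track), `points` (list of per-track peak data frames), plus `hop_s` and
#'   `bin_hz`.
#' @export
link_tracks <- function(peaks, series, cfg = detection_config()) {
  hop_s <- series$config$hop_points / series$sample_rate
  bin_hz <- series$sample_rate / series$config$window_points

  # tracks are held as integer index vectors into `peaks`
  open_idx <- list(); open_last_frame <- integer(); open_last_bin <- integer()
  done <- list()

  if (nrow(peaks) > 0) {
    pk_frame <- peaks$frame; pk_bin <- peaks$bin
    rows_by_frame <- split(seq_along(pk_frame), pk_frame)
    for (fi in seq_along(rows_by_frame)) {
      rows <- rows_by_frame[[fi]]
      f <- pk_frame[rows[1]]
      if (length(open_idx)) {
        # retire tracks that can no longer be extended
        expired <- f - open_last_frame > cfg$max_gap_frames + 1L
        if (any(expired)) {
          done <- c(done, open_idx[expired])
          open_idx <- open_idx[!expired]
          open_last_frame <- open_last_frame[!expired]
          open_last_bin <- open_last_bin[!expired]
        }
      }
      taken <- rep(FALSE, length(rows))
      n_open <- length(open_idx)
      if (n_open) {
        # all admissible (track, peak) pairs, nearest-frequency first
        gap <- f - open_last_frame
        d <- abs(outer(open_last_bin, pk_bin[rows], "-"))
        adm <- which(d <= cfg$max_bin_drift_per_frame * gap, arr.ind = TRUE)
        if (nrow(adm)) {
          ord <- order(d[adm], adm[, 1L], adm[, 2L])
          used_t <- rep(FALSE, n_open)
          for (i in ord) {
            ti <- adm[i, 1L]; pi <- adm[i, 2L]
            if (used_t[ti] || taken[pi]) next
            used_t[ti] <- TRUE; taken[pi] <- TRUE
            open_idx[[ti]] <- c(open_idx[[ti]], rows[pi])
            open_last_frame[ti] <- f
            open_last_bin[ti] <- pk_bin[rows[pi]]
          }
        }
      }
      new_p <- which(!taken)
      if (length(new_p)) {
        open_idx <- c(open_idx, as.list(rows[new_p]))
        open_last_frame <- c(open_last_frame, rep(f, length(new_p)))
        open_last_bin <- c(open_last_bin, pk_bin[rows[new_p]])
      }
    }
  }
  done <- c(done, open_idx)

  kept <- list()
  for (idx in done)
    kept <- c(kept, split_overlong(peaks[idx, , drop = FALSE], cfg, hop_s))
  if (length(kept)) {
    ord <- order(vapply(kept, function(p) p$frame[1], numeric(1)),
                 vapply(kept, function(p) p$bin[1], numeric(1)))
    kept <- kept[ord]
    summ <- do.call(rbind, lapply(kept, track_summary_row,
                                  hop_s = hop_s,
                                  frame_times = series$frame_times_s))
    summ <- cbind(track = seq_along(kept), summ)
    rownames(summ) <- NULL
  } else {
    summ <- data.frame(track = integer(), start_s = numeric(),
                       end_s = numeric(), duration_ms = numeric(),
                       n_points = integer(), mean_freq_hz = numeric(),
                       freq_sd_hz = numeric(), mean_level_db = numeric(),
                       mean_margin_db = numeric(), n_gap_frames = integer())
  }
  structure(list(summary = summ, points = kept,
                 hop_s = hop_s, bin_hz = bin_hz),
            class = "candidate_tracks")
}

#' @export
print.candidate_tracks <- function(x, ...) {
  cat(sprintf("<candidate_tracks> %d track(s)\n", length(x$points)))
  if (nrow(x$summary))
    print(x$summary[, c("track", "start_s", "duration_ms", "mean_freq_hz",
                        "mean_level_db")], digits = 4)
  invisible(x)
}

#' Detect candidate tracks on one channel
#'
#' Convenience wrapper: threshold, peak extraction and linking in one call.
#'
#' @param series A [spectral_series()].
#' @param cfg A [detection_config()].
#' @return A `candidate_tracks` object (see [link_tracks()]).
#' @export
detect_tracks <- function(series, cfg = detection_config()) {
  link_tracks(extract_local_maxima(series, cfg), series, cfg)
}
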