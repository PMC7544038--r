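#' Per-track classification features (step 5)
#'
#' Features feeding the noise-rejection classifier. `env_minus_lung_db` is
#' the mean environment-channel level at the track's (frame, bin) cells
#' minus the lung-channel level at the same cells: ambient sounds (voices)
#' are louder on the environment microphone, wheezes on the chest
#' microphone. `freq_cv` (frequency coefficient of variation) separates the
#' gliding pitch of crying from the stable pitch of a wheeze.
#' `peak_width_bins` measures tonality: the mean width (in bins) of the
#' contiguous region around each track point whose level stays within 6 dB
#' of the peak. A wheeze, even a brief one whose mainlobe is widened by its
#' own short duration, stays within a handful of bins; the broad spectral
#' plateaus produced by fast pitch glides (crying) or broadband transients
#' spread over tens of bins.
#'
#' @param track One element of a `candidate_tracks` object's `points` list
#'   (a peak data frame), or a `candidate_tracks` object with a single
#'   track.
#' @param lung [spectral_series()] of the lung channel (the one the track
#'   was detected on).
#' @param env [spectral_series()] of the environment channel; must share
#'   the lung series' spectral configuration and frame count.
#' @param hop_s Hop duration in seconds (taken from `lung` by default).
#'
#' @return A one-row data frame: `duration_ms`, `mean_freq_hz`, `freq_cv`,
#'   `mean_margin_db`, `env_minus_lung_db`, `gap_fraction`, `level_sd_db`,
#'   `peak_width_bins`.
#' @export
compute_features <- function(track, lung, env,
                             hop_s = lung$config$hop_points / lung$sample_rate) {
  if (!identical(dim(lung$power_db), dim(env$power_db)))
    stop("alignment error: lung and environment spectra differ in shape")
  pts <- if (inherits(track, "candidate_tracks")) track$points[[1]] else track
  cells <- cbind(pts$frame, pts$bin)
  span <- pts$frame[nrow(pts)] - pts$frame[1] + 1L
  mf <- mean(pts$freq_hz)
  data.frame(
    duration_ms = span * hop_s * 1000,
    mean_freq_hz = mf,
    freq_cv = if (nrow(pts) > 1) stats::sd(pts$freq_hz) / mf else 0,
    mean_margin_db = mean(pts$margin_db),
    env_minus_lung_db = mean(env$power_db[cells] - lung$power_db[cells]),
    gap_fraction = (span - nrow(pts)) / span,
    level_sd_db = if (nrow(pts) > 1) stats::sd(pts$level_db) else 0,
    peak_width_bins = mean(vapply(seq_len(nrow(pts)), function(i)
      peak_width(lung$power_db, pts$frame[i], pts$bin[i]), numeric(1))))
}

# contiguous -drop_db width (bins) around a spectral peak; the search is
# capped because any width past the tonality cutoff reads the same
peak_width <- function(P, frame, bin, drop_db = 6, max_half = 60L) {
  lv <- P[frame, ]
  ref <- lv[bin] - drop_db
  lo <- bin
  while (lo > 1L && bin - lo < max_half && lv[lo - 1L] >= ref) lo <- lo - 1L
  hi <- bin
  nb <- length(lv)
  while (hi < nb && hi - bin < max_half && lv[hi + 1L] >= ref) hi <- hi + 1L
  hi - lo + 1L
}

#' Default interpretable noise-rejection rules
#'
#' An ordered rule list distilled from the qualitative acoustic contrasts
#' between wheezes and the main noise sources: heartbeats are brief
#' (< 100 ms), ambient voices are louder on the environment microphone,
#' crying glides in pitch and is intermittent, and wheezes sit between
#' 100 Hz and 5 kHz. A track that survives every rejection rule is a
#' wheeze.
#'
#' @param max_heartbeat_ms Duration at or below which a track is a
#'   heartbeat.
#' @param max_freq_cv Frequency coefficient of variation above which a
#'   track is crying.
#' @param max_gap_fraction Missing-frame fraction above which a track is
#'   crying.
#' @param max_peak_width_bins Spectral peak width (see
#'   [compute_features()]) above which a track is a non-tonal
#'   glide/transient, i.e. crying.
#' @param band Admissible wheeze frequency band (Hz, open interval).
#' @return An object of class `wheeze_rules`.
#' @export
default_rule_tree <- function(max_heartbeat_ms = 100, max_freq_cv = 0.15,
                              max_gap_fraction = 0.3,
                              max_peak_width_bins = 14, band = c(100, 5000)) {
  structure(list(max_heartbeat_ms = max_heartbeat_ms,
                 max_freq_cv = max_freq_cv,
                 max_gap_fraction = max_gap_fraction,
                 max_peak_width_bins = max_peak_width_bins, band = band),
            class = "wheeze_rules")
}

#' @export
print.wheeze_rules <- function(x, ...) {
  cat("<wheeze_rules> ordered rejection rules:\n",
      sprintf(" 1. duration_ms <= %g        -> heartbeat\n", x$max_heartbeat_ms),
      " 2. env_minus_lung_db >= 0   -> ambient_voice\n",
      sprintf(" 3. freq_cv > %g, gap_fraction > %g or peak_width_bins > %g -> crying\n",
              x$max_freq_cv, x$max_gap_fraction, x$max_peak_width_bins),
      sprintf(" 4. mean_freq_hz outside (%g, %g) -> other_noise\n",
              x$band[1], x$band[2]),
      " 5. otherwise                -> wheeze\n", sep = "")
  invisible(x)
}

#' Classify one candidate track (step 5)
#'
#' @param features One-row data frame from [compute_features()].
#' @param model A `wheeze_rules` object (default) or a fitted
#'   `wheeze_tree` from [fit_tree()].
#' @return A list with `label` (one of `wheeze`, `heartbeat`,
#'   `ambient_voice`, `crying`, `other_noise`) and `rule_path`, the ordered
#'   rule identifiers that produced it.
#' @export
classify_track <- function(features, model = default_rule_tree()) {
  UseMethod("classify_track", model)
}

#' @export
classify_track.wheeze_rules <- function(features, model = default_rule_tree()) {
  path <- character()
  fin <- function(label, rule) list(label = label,
                                    rule_path = c(path, rule))
  if (features$duration_ms <= model$max_heartbeat_ms)
    return(fin("heartbeat", "duration<=100ms"))
  path <- c(path, "duration>100ms")
  if (features$env_minus_lung_db >= 0)
    return(fin("ambient_voice", "env>=lung"))
  path <- c(path, "lung-dominant")
  if (features$freq_cv > model$max_freq_cv ||
      features$gap_fraction > model$max_gap_fraction ||
      (!is.null(features$peak_width_bins) &&
       features$peak_width_bins > model$max_peak_width_bins))
    return(fin("crying", "unstable-or-untonal"))
  path <- c(path, "stable-tonal-pitch")
  if (features$mean_freq_hz <= model$band[1] ||
      features$mean_freq_hz >= model$band[2])
    return(fin("other_noise", "outside-wheeze-band"))
  fin("wheeze", "in-band")
}

#' @export
classify_track.wheeze_tree <- function(features, model) {
  fit <- model$fit
  lab <- as.character(stats::predict(fit, features, type = "class"))
  node <- rpart_leaf_node(fit, features)
  pr <- rpart::path.rpart(fit, nodes = node, print.it = FALSE)[[1]]
  list(label = lab, rule_path = as.character(pr[-1]))  # drop "root"
}

# descend the fitted tree for one new row and return its leaf node number
# (rpart predicts classes for new data but does not report the leaf)
rpart_leaf_node <- function(fit, newdata) {
  node <- 1L
  frame <- fit$frame
  repeat {
    row <- match(node, as.integer(rownames(frame)))
    if (frame$var[row] == "<leaf>") return(node)
    prev <- seq_len(row - 1L)
    idx <- sum(frame$ncompete[prev] + frame$nsurrogate[prev] +
               (frame$var[prev] != "<leaf>")) + 1L
    cut <- fit$splits[idx, "index"]
    goes_left <- if (fit$splits[idx, "ncat"] < 0)
      newdata[[as.character(frame$var[row])]][1] < cut
    else
      newdata[[as.character(frame$var[row])]][1] >= cut
    node <- if (goes_left) 2L * node else 2L * node + 1L
  }
}

#' Train a decision tree on labelled track features
#'
#' Fits a depth-limited CART tree (via `rpart`) as a drop-in replacement
#' for the default rules; predictions expose their rule path for audit.
#'
#' @param features Data frame of [compute_features()] rows.
#' @param truth Character vector of labels, one per row.
#' @param seed Integer seed (cross-validation surrogates are disabled, so
#'   the fit is deterministic; the seed is still honoured for
#'   reproducibility of any future stochastic options).
#' @param maxdepth Maximum tree depth.
#' @return A `wheeze_tree` object wrapping the `rpart` fit.
#' @export
fit_tree <- function(features, truth, seed = 1L, maxdepth = 4L) {
  truth <- as.character(truth)
  if (length(unique(truth)) < 2)
    stop("training error: need at least two classes")
  df <- cbind(features, .label = factor(truth))
  with_seed(as.integer(seed), {
    fit <- rpart::rpart(.label ~ duration_ms + mean_freq_hz + freq_cv +
                          mean_margin_db + env_minus_lung_db + gap_fraction +
                          level_sd_db + peak_width_bins,
                        data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, xval = 0, cp = 0.01,
                          minsplit = 4, minbucket = 2))
  })
  structure(list(fit = fit), class = "wheeze_tree")
}

#' @export
print.wheeze_tree <- function(x, ...) {
  cat("<wheeze_tree> CART noise-rejection tree:\n")
  print(x$fit)
  invisible(x)
}

#' Aggregate track labels into the file-level verdict (step 5)
#'
#' A file is a wheeze file if at least one track is labelled wheeze. The
#' wheeze is polyphonic when two wheeze tracks overlap in time at distinct
#' frequencies (more than one bin apart), monophonic otherwise.
#'
#' @param labels List of [classify_track()] results, one per track.
#' @param tracks The `candidate_tracks` object the labels refer to.
#' @return A `file_decision` list: `verdict` (`"wheeze"`/`"no_wheeze"`),
#'   `wheeze_type` (`"monophonic"`/`"polyphonic"`/`"none"`) and
#'   `wheeze_tracks` (summary rows of the wheeze-labelled tracks).
#' @export
decide_file <- function(labels, tracks) {
  lab <- vapply(labels, function(l) l$label, character(1))
  if (length(lab) != length(tracks$points))
    stop("labels and tracks are not aligned")
  wz <- which(lab == "wheeze")
  if (length(wz) == 0)
    return(structure(list(verdict = "no_wheeze", wheeze_type = "none",
                          wheeze_tracks = tracks$summary[0, ]),
                     class = "file_decision"))
  s <- tracks$summary[wz, , drop = FALSE]
  poly <- FALSE
  if (nrow(s) > 1) {
    for (i in seq_len(nrow(s) - 1)) for (j in seq.int(i + 1, nrow(s))) {
      overlap <- s$start_s[i] < s$end_s[j] && s$start_s[j] < s$end_s[i]
      distinct <- abs(s$mean_freq_hz[i] - s$mean_freq_hz[j]) > tracks$bin_hz
      if (overlap && distinct) { poly <- TRUE; break }
    }
  }
  structure(list(verdict = "wheeze",
                 wheeze_type = if (poly) "polyphonic" else "monophonic",
                 wheeze_tracks = s),
            class = "file_decision")
}

#' @export
print.file_decision <- function(x, ...) {
  cat(sprintf("<file_decision> verdict: %s (type: %s, %d wheeze track(s))\n",
              x$verdict, x$wheeze_type, nrow(x$wheeze_tracks)))
  invisible(x)
}
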