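#' Full wheeze-recognition pipeline configuration
#'
#' Bundles the per-step configurations. Can be read from YAML with
#' [pipeline_config_from_yaml()].
#'
#' @param preprocess A [preprocess_config()].
#' @param spectral A [spectral_config()].
#' @param detection A [detection_config()].
#' @param classifier A `wheeze_rules` or `wheeze_tree` model.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            spectral = spectral_config(),
                            detection = detection_config(),
                            classifier = default_rule_tree()) {
  structure(list(preprocess = preprocess, spectral = spectral,
                 detection = detection, classifier = classifier),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys `preprocess`, `spectral`, `detection` and `classifier`
#' each hold the arguments of the corresponding constructor; missing keys
#' keep their defaults. `classifier` accepts only `"default-rules"` (or the
#' rule-tree tuning arguments).
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.list(x)) stop("config error: malformed pipeline YAML")
  cls <- x$classifier
  classifier <- if (is.null(cls) || identical(cls, "default-rules"))
    default_rule_tree()
  else if (is.list(cls)) do.call(default_rule_tree, cls)
  else stop("config error: unsupported classifier spec")
  pipeline_config(
    preprocess = do.call(preprocess_config, x$preprocess %||% list()),
    spectral = do.call(spectral_config, x$spectral %||% list()),
    detection = do.call(detection_config, x$detection %||% list()),
    classifier = classifier)
}

#' Detect wheezes in a two-channel lung-sound recording
#'
#' Runs the five-step recognition pipeline: (1) band-pass preprocessing and
#' resampling to 11.025 kHz / 16 bit; (2) Hamming-windowed short-time
#' spectra of both channels; (3) extraction of spectral local maxima above
#' a relative per-frame threshold; (4) linking of maxima across frames into
#' candidate tracks persisting more than 100 ms; (5) per-track feature
#' computation over both channels and rule- or tree-based rejection of
#' heartbeat, voice and crying noise. The verdict is "wheeze" if at least
#' one track survives as a wheeze.
#'
#' @param x A WAV file path or a [lung_recording()].
#' @param config A [pipeline_config()].
#' @param keep_series Keep the two spectral series in the result (large).
#' @param ... Passed to [read_recording()] when `x` is a path
#'   (`lung_channel_index`, `env_channel_index`).
#' @return A `wheeze_detection` object: `verdict`, `wheeze_type`, `tracks`
#'   (a `candidate_tracks`), `labels`, `rule_paths`, `features`, `decision`
#'   and the configuration used.
#' @export
wheeze_detect <- function(x, config = pipeline_config(),
                          keep_series = FALSE, ...) {
  rec <- if (inherits(x, "lung_recording")) x else read_recording(x, ...)
  rec <- preprocess(rec, config$preprocess)
  lung <- compute_spectral_series(rec$lung, rec$sample_rate, config$spectral)
  env <- compute_spectral_series(rec$environment, rec$sample_rate,
                                 config$spectral)
  tracks <- detect_tracks(lung, config$detection)
  feats <- lapply(tracks$points, compute_features, lung = lung, env = env)
  labels <- lapply(feats, classify_track, model = config$classifier)
  decision <- decide_file(labels, tracks)
  structure(list(
    verdict = decision$verdict,
    wheeze_type = decision$wheeze_type,
    decision = decision,
    tracks = tracks,
    labels = vapply(labels, function(l) l$label, character(1)),
    rule_paths = lapply(labels, function(l) l$rule_path),
    features = if (length(feats)) do.call(rbind, feats) else NULL,
    duration_s = rec$duration_s,
    config = config,
    series = if (keep_series) list(lung = lung, env = env) else NULL),
    class = "wheeze_detection")
}

#' @export
print.wheeze_detection <- function(x, ...) {
  cat(sprintf("Wheeze recognition: verdict %s", toupper(x$verdict)))
  if (x$verdict == "wheeze")
    cat(sprintf(" (%s, %d wheeze track(s))", x$wheeze_type,
                sum(x$labels == "wheeze")))
  cat(sprintf("\n%.1f s analysed, %d candidate track(s)\n",
              x$duration_s, length(x$labels)))
  invisible(x)
}

#' @export
summary.wheeze_detection <- function(object, ...) {
  print(object)
  if (length(object$labels)) {
    cat("\nCandidate tracks:\n")
    df <- cbind(object$tracks$summary[, c("track", "start_s", "duration_ms",
                                          "mean_freq_hz", "mean_level_db")],
                label = object$labels)
    print(df, digits = 4, row.names = FALSE)
    cat("\nLabel counts:\n")
    print(table(object$labels))
  }
  invisible(object)
}

#' Plot a detection result
#'
#' Spectrogram of the lung channel (needs `keep_series = TRUE` in
#' [wheeze_detect()]) with candidate-track points overlaid; wheeze-labelled
#' tracks in red, rejected tracks in grey.
#'
#' @param x A `wheeze_detection` object.
#' @param max_freq_hz Upper frequency limit of the display.
#' @param ... Unused.
#' @export
plot.wheeze_detection <- function(x, max_freq_hz = 3000, ...) {
  if (is.null(x$series))
    stop("re-run wheeze_detect() with keep_series = TRUE to plot")
  s <- x$series$lung
  keep <- s$bin_freqs_hz <= max_freq_hz
  graphics::image(s$frame_times_s, s$bin_freqs_hz[keep],
                  s$power_db[, keep, drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = sprintf("verdict: %s", x$verdict))
  for (i in seq_along(x$tracks$points)) {
    p <- x$tracks$points[[i]]
    graphics::points(s$frame_times_s[p$frame], p$freq_hz, pch = 16,
                     cex = 0.4,
                     col = if (x$labels[i] == "wheeze") "red" else "grey30")
  }
  invisible(x)
}

#' Serialize a detection result to JSON
#'
#' @param x A `wheeze_detection` object.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
detection_to_json <- function(x, path = NULL) {
  out <- list(verdict = x$verdict, wheeze_type = x$wheeze_type,
              tracks = x$tracks$summary, labels = x$labels,
              rule_paths = x$rule_paths)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Run the pipeline over a corpus of scene specifications
#'
#' Renders each scene, runs [wheeze_detect()], and tabulates verdicts
#' against the scenes' ground truth.
#'
#' @param specs List of [scene_spec()]s (e.g. from [sample_corpus()]).
#' @param config A [pipeline_config()].
#' @return A list: `results` data frame (file, truth, prediction),
#'   `confusion` ([confusion_counts()]), `metrics` ([metrics()]) and
#'   `per_file` (tracks and labels per file, for [summarize_tracks()]).
#' @export
run_corpus <- function(specs, config = pipeline_config()) {
  n <- length(specs)
  truth <- logical(n); pred <- logical(n)
  per_file <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- render_scene(specs[[i]])
    det <- wheeze_detect(sc$recording, config)
    truth[i] <- scene_has_wheeze(specs[[i]])
    pred[i] <- det$verdict == "wheeze"
    per_file[[i]] <- list(tracks = det$tracks,
                          labels = lapply(seq_along(det$labels), function(k)
                            list(label = det$labels[k],
                                 rule_path = det$rule_paths[[k]])))
  }
  cc <- tally_confusion(truth, pred)
  list(results = data.frame(file = seq_len(n), truth = truth,
                            prediction = pred),
       confusion = cc, metrics = metrics(cc), per_file = per_file)
}
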