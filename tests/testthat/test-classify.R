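mk_series_pair <- function(lung_level = -20, env_level = -60,
                           n_frames = 30, bin = 50) {
  lung <- flat_series(n_frames, n_bins = 257, floor_db = -80,
                      events = list(list(frames = 1:n_frames, bin = bin,
                                         level = lung_level)))
  env <- flat_series(n_frames, n_bins = 257, floor_db = -80,
                     events = list(list(frames = 1:n_frames, bin = bin,
                                        level = env_level)))
  list(lung = lung, env = env)
}

test_that("env_minus_lung_db is the cross-channel level difference at track cells", {
  p <- mk_series_pair(lung_level = -20, env_level = -60)
  tr <- detect_tracks(p$lung, detection_config())
  f <- compute_features(tr$points[[1]], p$lung, p$env)
  expect_equal(f$env_minus_lung_db, -40)

  f_same <- compute_features(tr$points[[1]], p$lung, p$lung)
  expect_equal(f_same$env_minus_lung_db, 0)
  expect_equal(f_same$gap_fraction, 0)
  expect_error(compute_features(tr$points[[1]], p$lung,
                                flat_series(5, n_bins = 257)),
               "alignment")
})

test_that("a pitch glide scores a larger freq_cv than a steady tone", {
  p <- mk_series_pair()
  glide <- data.frame(frame = 1:20, bin = 50 + round(seq(0, 45, length.out = 20)))
  glide$freq_hz <- p$lung$bin_freqs_hz[glide$bin]
  glide$level_db <- -20; glide$margin_db <- 20
  steady <- data.frame(frame = 1:20, bin = 50)
  steady$freq_hz <- p$lung$bin_freqs_hz[steady$bin]
  steady$level_db <- -20; steady$margin_db <- 20
  cv_glide <- compute_features(glide, p$lung, p$env)$freq_cv
  cv_steady <- compute_features(steady, p$lung, p$env)$freq_cv
  expect_gt(cv_glide, cv_steady)
  expect_gt(cv_glide, 0.15)
})

test_that("the default rules label tracks by their ordered rejection criteria", {
  rules <- default_rule_tree()
  expect_equal(classify_track(feature_row(), rules)$label, "wheeze")
  expect_equal(classify_track(feature_row(duration_ms = 80), rules)$label,
               "heartbeat")
  expect_equal(classify_track(feature_row(duration_ms = 250,
                                          env_minus_lung_db = 6), rules)$label,
               "ambient_voice")
  expect_equal(classify_track(feature_row(freq_cv = 0.3), rules)$label,
               "crying")
  expect_equal(classify_track(feature_row(gap_fraction = 0.5), rules)$label,
               "crying")
  expect_equal(classify_track(feature_row(peak_width_bins = 40), rules)$label,
               "crying")
  expect_equal(classify_track(feature_row(mean_freq_hz = 6000), rules)$label,
               "other_noise")
})

test_that("every classification carries an auditable rule path", {
  res <- classify_track(feature_row(), default_rule_tree())
  expect_true(length(res$rule_path) >= 1)
  expect_equal(res$rule_path[length(res$rule_path)], "in-band")
  res2 <- classify_track(feature_row(duration_ms = 50), default_rule_tree())
  expect_equal(res2$rule_path, "duration<=100ms")
})

test_that("rule classification is unaffected by a global gain shift", {
  # all features are relative (dB differences) or temporal, so adding a
  # constant to both channels' levels must not change any label
  f <- feature_row()
  expect_equal(classify_track(f)$label, classify_track(f)$label)
  p <- mk_series_pair()
  tr <- detect_tracks(p$lung, detection_config())
  f1 <- compute_features(tr$points[[1]], p$lung, p$env)
  p$lung$power_db <- p$lung$power_db - 6
  p$env$power_db <- p$env$power_db - 6
  tr2 <- detect_tracks(p$lung, detection_config())
  f2 <- compute_features(tr2$points[[1]], p$lung, p$env)
  expect_equal(classify_track(f1)$label, classify_track(f2)$label)
})

test_that("a trained tree splits first on a perfectly separating feature", {
  set.seed(4)
  n <- 40
  wheeze <- do.call(rbind, replicate(n, feature_row(
    env_minus_lung_db = rnorm(1, -12, 2)), simplify = FALSE))
  voice <- do.call(rbind, replicate(n, feature_row(
    env_minus_lung_db = rnorm(1, 8, 2)), simplify = FALSE))
  fit <- fit_tree(rbind(wheeze, voice),
                  c(rep("wheeze", n), rep("ambient_voice", n)), seed = 1)
  expect_equal(as.character(fit$fit$frame$var[1]), "env_minus_lung_db")
  pred <- classify_track(feature_row(env_minus_lung_db = -10), fit)
  expect_equal(pred$label, "wheeze")
  expect_true(length(pred$rule_path) >= 1)
  expect_match(pred$rule_path[1], "env_minus_lung_db")
})

test_that("conflicting identical feature vectors give the majority label", {
  f <- do.call(rbind, replicate(9, feature_row(), simplify = FALSE))
  fit <- fit_tree(f, c(rep("wheeze", 6), rep("crying", 3)), seed = 1)
  expect_equal(classify_track(feature_row(), fit)$label, "wheeze")
})

test_that("single-class training input is rejected", {
  f <- do.call(rbind, replicate(5, feature_row(), simplify = FALSE))
  expect_error(fit_tree(f, rep("wheeze", 5)), "training error")
})

test_that("file verdicts follow the any-wheeze rule with mono/poly typing", {
  rows <- data.frame(start_s = c(1, 1.2, 3), end_s = c(2, 2.2, 4),
                     duration_ms = 1000, n_points = 10,
                     mean_freq_hz = c(400, 800, 410), freq_sd_hz = 1,
                     mean_level_db = -30, mean_margin_db = 10,
                     n_gap_frames = 0)
  tracks <- fake_tracks(rows)
  lab <- function(l) list(label = l, rule_path = "x")

  none <- decide_file(list(lab("crying"), lab("ambient_voice"),
                           lab("heartbeat")), tracks)
  expect_equal(none$verdict, "no_wheeze")
  expect_equal(none$wheeze_type, "none")

  poly <- decide_file(list(lab("wheeze"), lab("wheeze"), lab("crying")), tracks)
  expect_equal(poly$verdict, "wheeze")
  expect_equal(poly$wheeze_type, "polyphonic")  # overlap at 400 vs 800 Hz

  mono <- decide_file(list(lab("wheeze"), lab("crying"), lab("wheeze")), tracks)
  expect_equal(mono$wheeze_type, "monophonic")  # no temporal overlap

  expect_error(decide_file(list(lab("wheeze")), tracks), "aligned")
})

test_that("adding a wheeze-labelled track never flips a wheeze verdict", {
  rows <- data.frame(start_s = c(1, 5), end_s = c(2, 6), duration_ms = 1000,
                     n_points = 10, mean_freq_hz = c(400, 900),
                     freq_sd_hz = 1, mean_level_db = -30,
                     mean_margin_db = 10, n_gap_frames = 0)
  tracks <- fake_tracks(rows)
  lab <- function(l) list(label = l, rule_path = "x")
  base <- decide_file(list(lab("wheeze"), lab("crying")), tracks)
  more <- decide_file(list(lab("wheeze"), lab("wheeze")), tracks)
  expect_equal(base$verdict, "wheeze")
  expect_equal(more$verdict, "wheeze")
  expect_gte(nrow(more$wheeze_tracks), nrow(base$wheeze_tracks))
})
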