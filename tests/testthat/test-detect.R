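test_that("the frame threshold is the band mean plus the offset", {
  s <- flat_series(2, n_bins = 2049, floor_db = -40)
  expect_equal(frame_threshold(s, 1, detection_config(threshold_offset_db = 10)),
               -30)
  expect_equal(frame_threshold(s, 1, detection_config(threshold_offset_db = 0)),
               band_mean_level(s, 1, 90, 5000))
})

test_that("on white noise the threshold clears at least half the band bins", {
  set.seed(11)
  s <- compute_spectral_series(rnorm(11025, sd = 0.01), 11025)
  cfg <- detection_config()
  thr <- frame_threshold(s, 10, cfg)
  bb <- wheezr:::band_bins(s, cfg$threshold_band_lo, cfg$threshold_band_hi)
  expect_gte(mean(thr > s$power_db[10, bb]), 0.5)
})

test_that("strict local maxima above threshold are extracted, flat frames give none", {
  s <- flat_series(3, n_bins = 257, floor_db = -80,
                   events = list(list(frames = 1:3, bin = 50, level = -20)))
  pk <- extract_local_maxima(s, detection_config())
  expect_equal(unique(pk$bin), 50)
  expect_equal(nrow(pk), 3)
  expect_true(all(pk$margin_db >= 0))

  flat <- flat_series(3, n_bins = 257, floor_db = -40)
  expect_equal(nrow(extract_local_maxima(flat, detection_config())), 0)
})

test_that("a tone in noise yields one peak per frame within a bin of its frequency", {
  set.seed(5)
  # noise floor high enough to bury the Hamming sidelobes of the tone
  x <- rnorm(11025 * 2, sd = 0.05) + tone(400, 2, 11025, 1)
  s <- compute_spectral_series(x, 11025)
  pk <- extract_local_maxima(s, detection_config())
  per_frame <- table(factor(pk$frame, levels = seq_len(nrow(s$power_db))))
  expect_gte(mean(per_frame == 1), 0.95)
  expect_true(all(abs(pk$freq_hz - 400) <= 11025 / 4096 + 1e-9))
})

test_that("the >100 ms continuity rule keeps 9-frame runs and drops 8-frame runs", {
  cfg <- detection_config()
  mk <- function(n_frames) flat_series(
    12, n_bins = 257, floor_db = -80,
    events = list(list(frames = seq_len(n_frames), bin = 50, level = -20)))
  s9 <- mk(9)
  tr9 <- detect_tracks(s9, cfg)
  expect_equal(nrow(tr9$summary), 1)
  expect_equal(tr9$summary$duration_ms, 9 * 128 / 11025 * 1000)  # 104.49 ms
  expect_gt(tr9$summary$duration_ms, 100)

  tr8 <- detect_tracks(mk(8), cfg)
  expect_equal(nrow(tr8$summary), 0)   # 92.9 ms fails the "> 100 ms" rule
})

test_that("two simultaneous stable tones produce exactly two tracks", {
  sp <- scene_spec(2, list(
    scene_event("wheeze", onset_s = 0.5, duration_ms = 500, freq_hz = 400,
                snr_db = 30, polyphonic_partner_hz = 800)),
    breath_noise_db = -60, seed = 21)
  sc <- render_scene(sp)
  s <- compute_spectral_series(sc$recording$lung, 11025)
  tr <- detect_tracks(s, detection_config())
  expect_equal(nrow(tr$summary), 2)
  expect_equal(sort(round(tr$summary$mean_freq_hz, -2)), c(400, 800))
})

test_that("track skeletons are invariant to a global gain change", {
  sp <- scene_spec(2, list(
    scene_event("wheeze", onset_s = 0.4, duration_ms = 600, freq_hz = 500,
                snr_db = 15)), seed = 33)
  x <- render_scene(sp)$recording$lung
  cfg <- detection_config()
  skel <- function(g) {
    tr <- detect_tracks(compute_spectral_series(g * x, 11025), cfg)
    do.call(rbind, lapply(tr$points, function(p) p[, c("frame", "bin")]))
  }
  expect_identical(skel(1), skel(0.5))
})

test_that("silence produces zero tracks", {
  s <- compute_spectral_series(numeric(11025), 11025)
  expect_equal(nrow(detect_tracks(s, detection_config())$summary), 0)
})

test_that("greedy linking matches the association oracle on clean fixtures", {
  cfg <- detection_config()
  for (seed in 1:4) {
    sp <- scene_spec(2, list(
      scene_event("wheeze", onset_s = 0.3, duration_ms = 700, freq_hz = 350,
                  snr_db = 30),
      scene_event("wheeze", onset_s = 0.8, duration_ms = 500, freq_hz = 1100,
                  snr_db = 30)),
      breath_noise_db = -70, seed = seed)
    s <- compute_spectral_series(render_scene(sp)$recording$lung, 11025)
    pk <- extract_local_maxima(s, cfg)
    tr <- link_tracks(pk, s, cfg)
    ora <- oracle_track_count(pk, tr$hop_s, cfg)
    expect_equal(nrow(tr$summary), ora$n_tracks)
    expect_equal(sum(tr$summary$n_points), ora$n_points)
  }
})

test_that("retained tracks always respect band and duration bounds", {
  cfg <- detection_config()
  for (seed in 1:3) {
    specs <- sample_corpus(1, 1, seed = seed, duration_s = 5,
                           snr_db_range = c(10, 44))
    for (sp in specs) {
      s <- compute_spectral_series(render_scene(sp)$recording$lung, 11025)
      tr <- detect_tracks(s, cfg)
      if (nrow(tr$summary) == 0) next
      expect_true(all(tr$summary$duration_ms > cfg$min_duration_ms))
      expect_true(all(tr$summary$duration_ms <= cfg$max_duration_ms))
      for (p in tr$points)
        expect_true(all(p$freq_hz >= cfg$candidate_band_lo &
                        p$freq_hz <= cfg$candidate_band_hi))
    }
  }
})

test_that("over-long runs are split at weak points and re-tested", {
  cfg <- detection_config(max_duration_ms = 1000)
  s <- flat_series(400, n_bins = 257, floor_db = -80,
                   events = list(list(frames = 1:400, bin = 50, level = -20)))
  # carve a weak point so the splitter has a natural breakpoint
  s$power_db[200, 50] <- -45
  tr <- detect_tracks(s, cfg)
  expect_gt(nrow(tr$summary), 1)
  expect_true(all(tr$summary$duration_ms <= 1000))
  expect_true(all(tr$summary$duration_ms > cfg$min_duration_ms))
})
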