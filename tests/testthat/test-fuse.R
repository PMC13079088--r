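mk_tracks <- function(t_mid_s, conf, frame_rate = 450) {
  # build a track table whose mid-transit times equal t_mid_s
  f <- round(t_mid_s * frame_rate)
  data.frame(track_id = seq_along(t_mid_s), n = 3L,
             first_frame = f - 1, last_frame = f + 1,
             confidence = conf, mean_y = 50, mean_x = 100)
}

mk_if_events <- function(t, psma = TRUE, epcam = FALSE) {
  data.frame(t_center_s = t, psma_pos = psma, epcam_pos = epcam,
             psma_amplitude = ifelse(psma, 1, 0),
             epcam_amplitude = ifelse(epcam, 1, 0))
}

test_that("event fusion matches tracks to IF pulses on the shared clock", {
  # disjoint time supports: all tracks marker-negative
  tr <- mk_tracks(c(1, 2), c(0.9, 0.8))
  ev <- mk_if_events(c(10, 20))
  fused <- align_events(tr, ev, 450, time_tolerance = 0.5)
  expect_false(any(fused$psma_pos))
  expect_equal(nrow(attr(fused, "orphan_if_events")), 2)
  # two tracks, one IF event within tolerance of the nearer only
  tr2 <- mk_tracks(c(1.0, 3.0), c(0.9, 0.8))
  ev2 <- mk_if_events(1.1)
  fused2 <- align_events(tr2, ev2, 450, time_tolerance = 0.3)
  expect_equal(fused2$psma_pos, c(TRUE, FALSE))
  expect_equal(nrow(attr(fused2, "orphan_if_events")), 0)
  # matching is one-to-one even with several nearby candidates
  tr3 <- mk_tracks(c(1.0, 1.05), c(0.9, 0.8))
  ev3 <- mk_if_events(c(1.0, 1.06))
  fused3 <- align_events(tr3, ev3, 450, time_tolerance = 0.2)
  expect_equal(sum(fused3$psma_pos), 2)
})

test_that("fusion recovers marker truth on a simulated run", {
  run <- tiny_run()
  # perfect holographic tracks from ground truth
  step_px <- run$config$flow_speed_um_s / run$config$optical$frame_rate_hz /
    run$config$optical$object_pixel_um
  det <- data.frame(frame = run$tracks$frame, x = run$tracks$x_px,
                    y = run$tracks$y_px,
                    confidence = ifelse(
                      run$truth$class_label[run$tracks$event_id] == "ctc_like",
                      0.95, 0.3))
  lk <- link_tracks(det, step_px, gate = 10)
  pk <- trace_peaks(run$traces, run$config$transit_s)
  ev <- match_channels(pk$psma, pk$epcam,
                       time_tolerance = 0.5 * run$config$transit_s)
  fused <- align_events(track_table(lk), ev,
                        run$config$optical$frame_rate_hz,
                        time_tolerance = run$config$transit_s)
  expect_equal(sum(fused$psma_pos), sum(run$truth$psma_expressed))
  expect_equal(sum(fused$epcam_pos), sum(run$truth$epcam_expressed))
})

test_that("the CTC gate requires confidence and PSMA but never EpCAM", {
  expect_true(classify_ctc(0.6, TRUE))
  expect_false(classify_ctc(0.6, FALSE))
  expect_false(classify_ctc(0.4999, TRUE))
  expect_true(classify_ctc(0.5, TRUE))            # inclusive by default
  expect_false(classify_ctc(0.5, TRUE, strict_greater = TRUE))
  expect_true(classify_ctc(0.6, FALSE, require_psma = FALSE))
  # gating is monotone in the threshold and in the PSMA requirement
  set.seed(71)
  conf <- runif(50); psma <- runif(50) < 0.5
  for (th in c(0.2, 0.5, 0.8)) {
    n_lo <- sum(classify_ctc(conf, psma, threshold = th))
    n_hi <- sum(classify_ctc(conf, psma, threshold = th + 0.1))
    expect_gte(n_lo, n_hi)
    n_nopsma <- sum(classify_ctc(conf, psma, threshold = th,
                                 require_psma = FALSE))
    expect_gte(n_nopsma, n_lo)
  }
})

test_that("per-mL enumeration follows the printed arithmetic", {
  none <- data.frame(track_id = integer(), confidence = numeric(),
                     t_mid_s = numeric(), n_frames = integer(),
                     psma_pos = logical(), epcam_pos = logical())
  expect_equal(enumerate_per_ml(none, 7.5)$ctc_per_ml, 0)
  expect_error(enumerate_per_ml(none, 0), "positive")
  # 5 false events over 55 mL: fewer than 0.1 per mL
  five <- data.frame(track_id = 1:5, confidence = 0.9, t_mid_s = 1:5,
                     n_frames = 3, psma_pos = TRUE, epcam_pos = FALSE)
  rep5 <- enumerate_per_ml(five, 55)
  expect_equal(rep5$ctc_per_ml, 5 / 55)
  expect_lt(rep5$ctc_per_ml, 0.1)
  # 25 CTCs in 2 mL: 12.5 per mL
  e25 <- data.frame(track_id = 1:25, confidence = 0.9, t_mid_s = 1:25,
                    n_frames = 3, psma_pos = TRUE,
                    epcam_pos = rep(c(TRUE, FALSE), c(10, 15)))
  rep25 <- enumerate_per_ml(e25, 2)
  expect_equal(rep25$ctc_per_ml, 12.5)
  expect_equal(rep25$frac_epcam_pos_among_psma_pos, 0.4)
})

test_that("PPV follows its defining formula and monotonicities", {
  expect_equal(ppv(0.5, 10, 0), 1)
  expect_error(ppv(0, 10, 0), "undefined")
  expect_equal(ppv(0.60, 10, 5 / 55), 6 / (6 + 5 / 55), tolerance = 1e-12)
  # monotone: decreasing in FPR, increasing in TPR and abundance
  grid <- expand.grid(tpr = c(0.3, 0.6, 0.9), c = c(1, 10),
                      fpr = c(0.05, 0.5, 2))
  v <- with(grid, mapply(ppv, tpr, c, fpr))
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$tpr[i] >= grid$tpr[j] && grid$c[i] >= grid$c[j] &&
        grid$fpr[i] <= grid$fpr[j])
      expect_gte(v[i], v[j])
  }
})

test_that("depletion and enrichment arithmetic multiplies across stages", {
  st <- data.frame(stage = "microfluidic",
                   population = c("ctc", "wbc"),
                   count_in = c(100, 1e6),
                   count_out = c(95, 4000))
  out <- depletion_stats(st)
  expect_equal(out$per_stage$depletion[2], 0.996)
  expect_equal(out$per_stage$retention[1], 0.95)
  # retention 0.95 over 99.6% WBC depletion: 237.5-fold, above 100
  expect_equal(out$enrichment$fold_enrichment, 0.95 / 0.004)
  expect_gt(out$enrichment$fold_enrichment, 100)
  # no-op stage: zero depletion, fold equals retention
  same <- depletion_stats(data.frame(stage = "s", population = c("ctc", "wbc"),
                                     count_in = c(10, 10),
                                     count_out = c(9, 10)))
  expect_equal(same$per_stage$depletion[2], 0)
  expect_equal(same$enrichment$fold_enrichment, 0.9)
  # two 10x background stages at full retention: cumulative fold 100
  two <- depletion_stats(data.frame(
    stage = rep(c("a", "b"), each = 2), population = rep(c("ctc", "wbc"), 2),
    count_in = c(10, 1000, 10, 100), count_out = c(10, 100, 10, 10)))
  expect_equal(two$enrichment$fold_enrichment, 100)
  expect_error(depletion_stats(data.frame(stage = "s", population = "ctc",
                                          count_in = 10, count_out = 11)),
               "negative depletion")
})

test_that("cohort summaries use the even-n sample median", {
  rep1 <- structure(list(sample_id = "a", volume_ml = 1, n_ctc = 3,
                         ctc_per_ml = 3, frac_epcam_pos_among_psma_pos = NA,
                         threshold = 0.5), class = "enumeration_report")
  one <- cohort_summary(list(rep1), "patient")
  expect_equal(one$summary$median_per_ml, 3)
  mk <- function(v) structure(list(sample_id = "x", volume_ml = 1,
                                   n_ctc = v, ctc_per_ml = v,
                                   frac_epcam_pos_among_psma_pos = NA,
                                   threshold = 0.5),
                              class = "enumeration_report")
  reps <- lapply(c(1, 2, 3, 100, 0, 3), mk)
  cs <- cohort_summary(reps, c(rep("patient", 4), rep("healthy", 2)))
  med <- cs$summary$median_per_ml
  names(med) <- cs$summary$cohort
  expect_equal(unname(med["patient"]), 2.5)   # mean of middle two
  expect_equal(unname(med["healthy"]), 1.5)
  expect_equal(sort(cs$distributions$patient), c(1, 2, 3, 100))
})
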