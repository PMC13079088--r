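test_that("heatmap peak extraction matches the brute-force oracle", {
  expect_equal(nrow(heatmap_peaks(matrix(0.4, 20, 20), 0.5, 5)), 0)
  # single rendered Gaussian: exactly one detection at the blob centre
  hm <- 0.9 * render_targets(data.frame(x = 14, y = 9), c(24, 30), 8.12 / 2)
  pk <- heatmap_peaks(hm, 0.5, 8)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x, pk$y), c(14, 9))
  expect_equal(pk$confidence, 0.9)
  # two equal peaks 3 px apart under a 10 px radius: one survivor
  hm2 <- pmax(0.8 * render_targets(data.frame(x = 10, y = 10), c(24, 30), 1.5),
              0.8 * render_targets(data.frame(x = 13, y = 10), c(24, 30), 1.5))
  pk2 <- heatmap_peaks(hm2, 0.5, 10)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2, oracle_peaks(hm2, 0.5, 10))
  # randomized agreement with the all-pixel oracle
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    hm3 <- matrix(0, 28, 36)
    for (k in 1:n)
      hm3 <- pmax(hm3, runif(1, 0.3, 1) *
                    render_targets(data.frame(x = runif(1, 2, 33),
                                              y = runif(1, 2, 25)),
                                   c(28, 36), runif(1, 1.2, 3)))
    got <- heatmap_peaks(hm3, 0.35, 4)
    want <- oracle_peaks(hm3, 0.35, 4)
    expect_equal(got, want)
  }
})

test_that("peak extraction is invariant to threshold-preserving monotone rescaling", {
  set.seed(32)
  hm <- pmax(0.7 * render_targets(data.frame(x = 8, y = 8), c(24, 24), 2),
             0.9 * render_targets(data.frame(x = 18, y = 14), c(24, 24), 2))
  theta <- 0.5
  # strictly monotone map fixing the threshold crossing: x^2 scaled
  resc <- hm^2
  theta2 <- theta^2
  a <- heatmap_peaks(hm, theta, 5)
  b <- heatmap_peaks(resc, theta2, 5)
  expect_equal(a[, c("x", "y")], b[, c("x", "y")])
})

test_that("track linking groups repeated captures and conserves detections", {
  expect_error(link_tracks(data.frame(frame = 1, x = 1, y = 1,
                                      confidence = 1), 5, -1), "gate")
  one <- link_tracks(data.frame(frame = 3, x = 10, y = 5, confidence = 0.7),
                     5, 10)
  expect_equal(nrow(track_table(one)), 1)
  expect_equal(track_table(one)$n, 1)
  # one cell visible over 5 consecutive frames
  det <- data.frame(frame = 1:5, x = 10 + 20 * (0:4), y = 30,
                    confidence = c(0.6, 0.9, 0.8, 0.7, 0.5))
  lk <- link_tracks(det, 20, 8)
  tt <- track_table(lk)
  expect_equal(nrow(tt), 1)
  expect_equal(tt$n, 5)
  expect_equal(tt$confidence, 0.9)   # representative = max member
  # two co-transiting cells at transverse separation beyond the gate
  det2 <- rbind(det, transform(det, y = 60, confidence = confidence - 0.1))
  lk2 <- link_tracks(det2, 20, 8)
  expect_equal(nrow(track_table(lk2)), 2)
  expect_equal(nrow(lk2), nrow(det2))          # all detections kept
  expect_true(all(table(lk2$track_id) == 5))   # one per frame per track
})

test_that("track linking recovers planted cells from the simulator", {
  run <- tiny_run()
  step_px <- run$config$flow_speed_um_s / run$config$optical$frame_rate_hz /
    run$config$optical$object_pixel_um
  # feed ground-truth centroids as perfect detections
  det <- data.frame(frame = run$tracks$frame, x = run$tracks$x_px,
                    y = run$tracks$y_px, confidence = 1)
  lk <- link_tracks(det, step_px, gate = 10)
  expect_equal(nrow(track_table(lk)), length(unique(run$tracks$event_id)))
})

test_that("greedy reference matching satisfies its contracts and hand cases", {
  ref <- data.frame(x = c(10, 40), y = c(10, 10))
  # identical sets: all matched
  m <- match_to_reference(cbind(ref, confidence = c(0.9, 0.8)), ref, 5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 0, 0))
  # 3 predictions, 2 references, one prediction far from both
  pred <- data.frame(x = c(10.5, 39, 200), y = c(10, 10, 10),
                     confidence = c(0.9, 0.7, 0.95))
  m2 <- match_to_reference(pred, ref, 5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(2, 1, 0))
  expect_equal(m2$tp + m2$fn, nrow(ref))
  expect_equal(m2$tp + m2$fp, nrow(pred))
  # injectivity both ways
  expect_false(any(duplicated(m2$pairs$pred)))
  expect_false(any(duplicated(m2$pairs$ref)))
  # infinite radius with equal counts: perfect matching
  m3 <- match_to_reference(data.frame(x = c(0, 1), y = c(0, 0),
                                      confidence = c(1, 1)),
                           data.frame(x = c(500, 900), y = c(0, 0)), 1e9)
  expect_equal(c(m3$fp, m3$fn), c(0, 0))
})

test_that("greedy matching equals the optimal assignment on small instances", {
  set.seed(41)
  radius <- 15 / 0.345
  for (i in 1:200) {
    np <- sample(0:6, 1); nr <- sample(0:6, 1)
    pred <- data.frame(x = runif(np, 0, 1439), y = runif(np, 0, 255),
                       confidence = runif(np))
    ref <- data.frame(x = runif(nr, 0, 1439), y = runif(nr, 0, 255))
    expect_equal(match_to_reference(pred, ref, radius)$tp,
                 oracle_max_match(pred, ref, radius))
  }
})

test_that("recovery curves are correctly normalized and non-increasing", {
  expect_error(recovery_curve(data.frame(confidence = numeric()), 0.5),
               "zero truth")
  # all truths matched at confidence 1: TPR = 1 everywhere
  all1 <- data.frame(event_id = 1:4, confidence = 1)
  expect_equal(recovery_curve(all1, c(0.2, 0.9, 1))$tpr, rep(1, 3))
  # unmatched truths contribute 0 at every threshold
  mix <- data.frame(event_id = 1:4, confidence = c(0.9, 0.4, NA, NA))
  rc <- recovery_curve(mix, c(0.2, 0.5, 0.8))
  expect_equal(rc$tpr, c(0.5, 0.25, 0.25))
  set.seed(51)
  for (i in 1:20) {
    conf <- ifelse(runif(10) < 0.3, NA, runif(10))
    rc <- recovery_curve(data.frame(event_id = 1:10, confidence = conf),
                         seq(0.2, 0.9, by = 0.1))
    expect_true(all(diff(rc$tpr) <= 0))
  }
})
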