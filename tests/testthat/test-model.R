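small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_model(model_spec(channels = 3),
                                              seed = 42)
    cache
  }
})

test_that("detector obeys its shape, range and determinism contracts", {
  m <- small_model()
  x <- matrix(rnorm(64 * 96), 64, 96)
  p <- model_forward(m, x)
  expect_equal(dim(p), c(32, 48))           # exactly input / downsample
  expect_true(all(p >= 0 & p <= 1))
  # all-zero input: finite output in [0, 1]
  p0 <- model_forward(m, matrix(0, 64, 96))
  expect_true(all(is.finite(p0)) && all(p0 >= 0 & p0 <= 1))
  # same seed, same weights; different seed, different weights
  m2 <- build_model(model_spec(channels = 3), seed = 42)
  expect_identical(m$weights, m2$weights)
  m3 <- build_model(model_spec(channels = 3), seed = 43)
  expect_false(identical(m$weights, m3$weights))
  expect_error(model_forward(m, matrix(0, 63, 96)), "divisible")
})

test_that("measured receptive field respects the construction bound", {
  m <- small_model()
  rf <- m$receptive_field_px
  expect_true(is.integer(rf) && rf > 0)
  expect_lte(rf, m$spec$receptive_field_bound)
  # a tight bound is rejected at construction
  expect_error(build_model(model_spec(channels = 3,
                                      receptive_field_bound = 16), seed = 1),
               "receptive field")
})

test_that("network backward pass matches finite-difference gradients", {
  m <- small_model()
  set.seed(7)
  x <- matrix(rnorm(24 * 32), 24, 32)
  y <- render_targets(data.frame(x = 8, y = 6), c(12, 16), 2)
  cfg <- loss_config()
  fw <- model_forward(m, x, cache = TRUE)
  eps <- 1e-7
  pc <- pmin(pmax(fw$p, eps), 1 - eps)
  a <- holoflow:::loss_weights(y, TRUE, cfg)
  gz <- a * (pc - y) / length(pc)
  bk <- holoflow:::model_backward(m, fw$cache, gz)
  lossf <- function(mm) asymmetric_bce(model_forward(mm, x), y, TRUE, cfg)
  for (nm in c("stem", "d2", "b3", "f2", "h1", "h2")) {
    i <- sample(length(m$weights[[nm]]$w), 1)
    h <- 1e-5
    mp <- m; mp$weights[[nm]]$w[i] <- mp$weights[[nm]]$w[i] + h
    mn <- m; mn$weights[[nm]]$w[i] <- mn$weights[[nm]]$w[i] - h
    num <- (lossf(mp) - lossf(mn)) / (2 * h)
    expect_equal(bk$grads[[nm]]$gw[i], num, tolerance = 1e-4)
  }
})

test_that("learning-rate schedule decays exponentially from 0.01", {
  cfg <- train_config()
  expect_equal(lr_schedule(cfg, 0:2), c(0.01, 0.0085, 0.007225))
})

test_that("hard-sample mining weights are normalized, monotone and equivariant", {
  expect_equal(mine_hard_sessions(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(mine_hard_sessions(c(0, 0)), c(0.5, 0.5))
  expect_equal(mine_hard_sessions(c(1, 3), delta = 0), c(0.25, 0.75))
  set.seed(13)
  for (i in 1:20) {
    l <- runif(6, 0, 5)
    w <- mine_hard_sessions(l)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    expect_true(all(diff(w[order(l)]) >= -1e-12))   # monotone in loss
    perm <- sample(6)
    expect_equal(mine_hard_sessions(l[perm]), w[perm])   # equivariance
    expect_equal(mine_hard_sessions(10 * l), w)          # scale invariance
  }
})

test_that("session split is leakage-free and frame-balanced", {
  rec <- data.frame(session_id = sprintf("s%02d", 1:10), n_frames = 50)
  sp <- split_by_session(rec, 0.8, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), rec$session_id)
  expect_identical(split_by_session(rec, 0.8, seed = 3), sp)
  # uneven sessions: realized ratio as close to 0.8 as sizes allow
  rec2 <- data.frame(session_id = c("a", "b", "c"),
                     n_frames = c(700, 200, 100))
  sp2 <- split_by_session(rec2, 0.8, seed = 1)
  got <- sum(rec2$n_frames[rec2$session_id %in% sp2$train]) / 1000
  best <- min(abs(c(0.7, 0.8, 0.9, 0.3) - 0.8))
  expect_lte(abs(got - 0.8), best + 1e-12)
  expect_error(split_by_session(rec[1, ], 0.8), "2 sessions")
})

test_that("pseudo-labeling enforces the buffer-only protocol", {
  m <- small_model()
  frames <- array(rnorm(64 * 96 * 2, sd = 0.1), c(64, 96, 2))
  expect_error(pseudo_label(frames, m, session = list(medium = "blood")),
               "protocol violation")
  # untrained detector on blank buffer frames: no labels
  lab <- pseudo_label(frames, m, confidence_threshold = 0.9,
                      session = list(medium = "buffer"))
  expect_equal(nrow(lab), 0)
  expect_true(all(lab$source == "pseudo"))
})

test_that("zero-epoch training returns the initialization unchanged", {
  sess <- list(
    list(frames = array(rnorm(16 * 24 * 2), c(16, 24, 2)),
         labels = data.frame(frame = 1, x = 12, y = 8),
         positive = TRUE, medium = "buffer", cohort = "cell_line",
         session_id = "p1"),
    list(frames = array(rnorm(16 * 24 * 2), c(16, 24, 2)),
         labels = data.frame(frame = integer(), x = numeric(),
                             y = numeric()),
         positive = FALSE, medium = "blood", cohort = "healthy",
         session_id = "n1"))
  cfg <- train_config(epochs = 0, seed = 11)
  fit <- train_detector(sess, cfg, spec = model_spec(channels = 3))
  init <- build_model(model_spec(channels = 3), seed = 11)
  expect_identical(fit$model$weights, init$weights)
  expect_equal(nrow(fit$metrics), 0)
  expect_error(train_detector(sess[1], cfg, spec = model_spec(channels = 3)),
               "positive and negative")
})

test_that("a short training run reduces the loss on toy data", {
  sess <- simulate_session_set(n_pos = 2, n_neg = 2, frames_per_session = 12,
                               optical = optical_config(roi = c(128L, 64L)),
                               flow_speed_um_s = 5000, rate_per_s = 30,
                               seed = 71)
  cfg <- train_config(epochs = 3, batch_size = 4, steps_per_epoch = 8,
                      seed = 2)
  fit <- train_detector(sess, cfg, spec = model_spec(channels = 4))
  expect_equal(nrow(fit$metrics), 3)
  first <- fit$metrics$pos_loss[1] + fit$metrics$neg_loss[1]
  last <- fit$metrics$pos_loss[3] + fit$metrics$neg_loss[3]
  expect_lt(last, first)
  expect_equal(fit$metrics$lr, lr_schedule(cfg, 0:2))
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- small_model()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$weights, m$weights)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 42)
  expect_equal(side$n_parameters, n_parameters(m))
  unlink(c(path, paste0(path, ".json")))
})
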