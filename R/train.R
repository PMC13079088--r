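#' Training configuration
#'
#' Adam with learning rate 0.01 and exponential decay by a factor of 0.85
#' each epoch. At epoch `e` (0-based) the learning rate is
#' `learning_rate * lr_decay_per_epoch^e`.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay_per_epoch Multiplicative decay per epoch, in (0, 1).
#' @param epochs Number of training epochs.
#' @param batch_size Frames per optimizer step.
#' @param steps_per_epoch Optimizer steps per epoch; defaults to covering
#'   the training set once.
#' @param seed Seed for weight init, sampling and augmentation.
#' @param augment List of switches: `flip` (horizontal flip along the flow
#'   axis, off by default -- defocused fringes have a chirality) and
#'   `intensity_jitter` (multiplicative gain jitter, on by default).
#' @export
train_config <- function(learning_rate = 0.01, lr_decay_per_epoch = 0.85,
                         epochs = 10L, batch_size = 8L,
                         steps_per_epoch = NULL, seed = 1L,
                         augment = list(flip = FALSE, intensity_jitter = TRUE)) {
  stopifnot(learning_rate > 0, lr_decay_per_epoch > 0, lr_decay_per_epoch < 1,
            epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 lr_decay_per_epoch = lr_decay_per_epoch,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = steps_per_epoch,
                 seed = as.integer(seed), augment = augment),
            class = "train_config")
}

#' Learning-rate schedule
#' @param cfg A [train_config()].
#' @param epoch 0-based epoch index (vectorized).
#' @return `learning_rate * decay^epoch`.
#' @export
lr_schedule <- function(cfg, epoch) {
  cfg$learning_rate * cfg$lr_decay_per_epoch^epoch
}

#' Hard-sample mining weights
#'
#' Healthy-control imaging sessions are resampled each epoch in proportion
#' to their previous-epoch mean loss, so the sessions the detector currently
#' finds hardest are seen more often. A floor `delta` (default 1% of the max
#' loss) keeps every session's probability positive; if all losses are zero
#' the weights are uniform.
#'
#' @param losses Nonnegative numeric vector of per-session mean losses.
#' @param delta Additive floor; defaults to `0.01 * max(losses)`.
#' @return Weights proportional to `losses + delta`, summing to 1.
#' @export
mine_hard_sessions <- function(losses, delta = NULL) {
  stopifnot(is.numeric(losses), all(losses >= 0), length(losses) >= 1)
  if (all(losses == 0)) return(rep(1 / length(losses), length(losses)))
  if (is.null(delta)) delta <- 0.01 * max(losses)
  w <- losses + delta
  w / sum(w)
}

#' Leakage-free session-level train/validation split
#'
#' All frames of an acquisition session go to the same partition, so
#' repeated captures of one cell can never appear on both sides. Among
#' session-respecting partitions, the realized frame-count ratio is pushed
#' as close to `ratio` as the session sizes allow.
#'
#' @param records Data frame with columns `session_id` and `n_frames`.
#' @param ratio Target training fraction of frames (default 0.8).
#' @param seed Seed for the session shuffle.
#' @return List with `train` and `val` character vectors of session ids.
#' @export
split_by_session <- function(records, ratio = 0.8, seed = 1L) {
  stopifnot(is.data.frame(records),
            all(c("session_id", "n_frames") %in% names(records)))
  n <- nrow(records)
  if (n < 2) stop("need at least 2 sessions to split")
  ord <- with_seed(as.integer(seed), sample.int(n))
  rec <- records[ord, ]
  total <- sum(rec$n_frames)
  if (n <= 16) {
    # exact: enumerate all session subsets, keep the frame ratio closest to
    # target (ties resolved by the seeded session order)
    masks <- seq_len(2^n - 2)     # exclude empty and full partitions
    bits <- matrix(as.integer(intToBits(masks)[seq_len(n) + rep((masks - 1) * 32,
                                                                each = n)]),
                   nrow = n)
    sums <- as.numeric(rec$n_frames %*% bits)
    best <- which.min(abs(sums / total - ratio))
    train_ids <- rec$session_id[bits[, best] == 1L]
  } else {
    train_ids <- character(0)
    train_n <- 0
    for (i in seq_len(n)) {
      cand <- train_n + rec$n_frames[i]
      if (abs(cand / total - ratio) <= abs(train_n / total - ratio)) {
        train_ids <- c(train_ids, rec$session_id[i])
        train_n <- cand
      }
    }
    if (length(train_ids) == n) train_ids <- train_ids[-length(train_ids)]
    if (length(train_ids) == 0) train_ids <- rec$session_id[1]
  }
  list(train = train_ids,
       val = setdiff(records$session_id, train_ids))
}

#' Pseudo-label a buffer session with a companion detector
#'
#' Runs a trained labeler over the frames of a cell-line-in-buffer session
#' and labels every detected nucleated object. This is a pure detection
#' task: in buffer runs every nucleated object is a cell-line cell, so no
#' healthy/cancer discrimination is required. As a protocol invariant the
#' pseudo-labeler must never be applied to blood-medium sessions, where
#' unlabeled true cells would poison the negative supervision; such calls
#' are a hard error.
#'
#' @param frames Normalized frame array (`H x W x n`).
#' @param labeler A trained `keypoint_model`.
#' @param confidence_threshold Peak acceptance threshold.
#' @param session List or one-row data frame with at least `medium`
#'   (`"buffer"` or `"blood"`).
#' @param nms_radius Non-maximum-suppression radius (input px).
#' @return Data frame `frame`, `x`, `y`, `confidence`, `source = "pseudo"`.
#' @export
pseudo_label <- function(frames, labeler, confidence_threshold = 0.5,
                         session = list(medium = "buffer"),
                         nms_radius = 16) {
  medium <- if (is.data.frame(session)) session$medium[1] else session$medium
  if (!identical(medium, "buffer"))
    stop("protocol violation: pseudo-labeler applied to a blood-medium session")
  stopifnot(length(dim(frames)) == 3)
  out <- list()
  for (f in seq_len(dim(frames)[3])) {
    hm <- upsample_bilinear(model_forward(labeler, frames[, , f]),
                            labeler$spec$downsample)
    pk <- heatmap_peaks(hm, threshold = confidence_threshold,
                        nms_radius = nms_radius)
    if (nrow(pk)) out[[length(out) + 1L]] <-
        data.frame(frame = f, x = pk$x, y = pk$y, confidence = pk$confidence)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               confidence = numeric())
  res$source <- rep("pseudo", nrow(res))
  res
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(weights) {
  lapply(weights, function(wb)
    list(mw = 0 * wb$w, vw = 0 * wb$w, mb = 0 * wb$b, vb = 0 * wb$b))
}

adam_step <- function(weights, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mw <- beta1 * st$mw + (1 - beta1) * g$gw
    st$vw <- beta2 * st$vw + (1 - beta2) * g$gw^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$gb
    st$vb <- beta2 * st$vb + (1 - beta2) * g$gb^2
    weights[[nm]]$w <- weights[[nm]]$w -
      lr * (st$mw / bc1) / (sqrt(st$vw / bc2) + eps)
    weights[[nm]]$b <- weights[[nm]]$b -
      lr * as.numeric(st$mb / bc1) / (sqrt(as.numeric(st$vb / bc2)) + eps)
    state[[nm]] <- st
  }
  list(weights = weights, state = state)
}

# loss + d(loss)/d(logits) for one frame, at the output grid
frame_loss_grad <- function(model, frame, target, positive, loss_cfg) {
  fw <- model_forward(model, frame, cache = TRUE)
  p <- fw$p
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  a <- loss_weights(target, positive, loss_cfg)
  n <- length(p)
  loss <- -sum(a * (target * log(pc) + (1 - target) * log(1 - pc))) / n
  gz <- a * (pc - target) / n        # combined sigmoid + BCE gradient
  list(loss = loss, gz = gz, cache = fw$cache)
}

#' Train the keypoint detector
#'
#' Trains on a list of sessions, each a list with elements `frames`
#' (normalized array `H x W x n`), `labels` (data frame `frame`, `x`, `y` in
#' input-pixel coordinates; zero rows for negative sessions), `positive`
#' (logical: cell-line-in-buffer stream), `medium`, `cohort` and
#' `session_id`. Every batch draws half its frames from positive sessions
#' (uniformly) and half from negative sessions, the latter weighted by
#' [mine_hard_sessions()] on the previous epoch's per-session mean loss.
#' Targets are rendered on the fly at the output grid (coordinates and sigma
#' divided by the model's downsample factor) and the asymmetric
#' cross-entropy of [loss_config()] is minimized with Adam under the
#' [lr_schedule()].
#'
#' @param sessions Training sessions (see above); must contain at least one
#'   positive and one negative session.
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param spec A [model_spec()] (ignored when `model` is given).
#' @param tspec A [target_spec()] giving the keypoint sigma in input pixels.
#' @param model Optionally a pre-built `keypoint_model` to continue training.
#' @param val_sessions Optional held-out sessions for per-epoch validation
#'   loss.
#' @return List: `model`, `metrics` (one row per epoch), `mining` (final
#'   weights), `cfg`.
#' @export
train_detector <- function(sessions, cfg = train_config(),
                           loss_cfg = loss_config(), spec = model_spec(),
                           tspec = target_spec(), model = NULL,
                           val_sessions = NULL) {
  pos_idx <- which(vapply(sessions, function(s) isTRUE(s$positive), TRUE))
  neg_idx <- which(vapply(sessions, function(s) !isTRUE(s$positive), TRUE))
  if (length(pos_idx) == 0 || length(neg_idx) == 0)
    stop("training requires both positive and negative sessions")
  if (is.null(model)) model <- build_model(spec, seed = cfg$seed)
  ds <- model$spec$downsample
  sigma_out <- tspec$sigma_px / ds
  n_total <- sum(vapply(sessions, function(s) dim(s$frames)[3], 0))
  steps <- cfg$steps_per_epoch %||% ceiling(n_total / cfg$batch_size)

  target_for <- function(s, f, flipped = FALSE) {
    lab <- s$labels[s$labels$frame == f, , drop = FALSE]
    shp <- c(dim(s$frames)[1] %/% ds, dim(s$frames)[2] %/% ds)
    if (nrow(lab) == 0) return(matrix(0, shp[1], shp[2]))
    x <- if (flipped) (dim(s$frames)[2] - 1) - lab$x else lab$x
    render_targets(data.frame(x = pmin(x / ds, shp[2] - 1),
                              y = pmin(lab$y / ds, shp[1] - 1)),
                   shp, sigma_out)
  }

  opt_state <- adam_init(model$weights)
  t_step <- 0L
  mine_w <- rep(1 / length(neg_idx), length(neg_idx))
  metrics <- list()
  set.seed(cfg$seed + 7L)
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_schedule(cfg, epoch)
    neg_loss_sum <- numeric(length(neg_idx))
    neg_loss_n <- numeric(length(neg_idx))
    pos_losses <- c()
    for (step in seq_len(steps)) {
      n_pos <- ceiling(cfg$batch_size / 2)
      n_neg <- cfg$batch_size - n_pos
      picks <- list()
      for (i in seq_len(n_pos)) {
        si <- pos_idx[sample.int(length(pos_idx), 1)]
        picks[[length(picks) + 1L]] <-
          c(si, sample.int(dim(sessions[[si]]$frames)[3], 1))
      }
      for (i in seq_len(n_neg)) {
        ni <- sample.int(length(neg_idx), 1, prob = mine_w)
        si <- neg_idx[ni]
        picks[[length(picks) + 1L]] <-
          c(si, sample.int(dim(sessions[[si]]$frames)[3], 1))
      }
      acc <- NULL
      for (pk in picks) {
        s <- sessions[[pk[1]]]
        fr <- s$frames[, , pk[2]]
        if (isTRUE(cfg$augment$intensity_jitter))
          fr <- fr * stats::runif(1, 0.9, 1.1)
        flipped <- isTRUE(cfg$augment$flip) && stats::runif(1) < 0.5
        if (flipped) fr <- fr[, rev(seq_len(ncol(fr)))]
        y <- target_for(s, pk[2], flipped)
        lg <- frame_loss_grad(model, fr, y, isTRUE(s$positive), loss_cfg)
        bk <- model_backward(model, lg$cache, lg$gz)
        if (is.null(acc)) acc <- bk$grads
        else for (nm in names(acc)) {
          acc[[nm]]$gw <- acc[[nm]]$gw + bk$grads[[nm]]$gw
          acc[[nm]]$gb <- acc[[nm]]$gb + bk$grads[[nm]]$gb
        }
        if (isTRUE(s$positive)) pos_losses <- c(pos_losses, lg$loss)
        else {
          ni <- match(pk[1], neg_idx)
          neg_loss_sum[ni] <- neg_loss_sum[ni] + lg$loss
          neg_loss_n[ni] <- neg_loss_n[ni] + 1
        }
      }
      for (nm in names(acc)) {
        acc[[nm]]$gw <- acc[[nm]]$gw / length(picks)
        acc[[nm]]$gb <- acc[[nm]]$gb / length(picks)
      }
      t_step <- t_step + 1L
      upd <- adam_step(model$weights, acc, opt_state, lr, t_step)
      model$weights <- upd$weights
      opt_state <- upd$state
    }
    sess_mean <- ifelse(neg_loss_n > 0, neg_loss_sum / pmax(neg_loss_n, 1), 0)
    mine_w <- mine_hard_sessions(sess_mean)
    val_loss <- NA_real_
    if (!is.null(val_sessions))
      val_loss <- mean(vapply(val_sessions, function(s) {
        ls <- vapply(seq_len(dim(s$frames)[3]), function(f) {
          p <- model_forward(model, s$frames[, , f])
          asymmetric_bce(p, target_for(s, f), isTRUE(s$positive), loss_cfg)
        }, 0)
        mean(ls)
      }, 0))
    metrics[[length(metrics) + 1L]] <- data.frame(
      epoch = epoch, lr = lr,
      pos_loss = if (length(pos_losses)) mean(pos_losses) else NA_real_,
      neg_loss = if (any(neg_loss_n > 0))
        sum(neg_loss_sum) / sum(neg_loss_n) else NA_real_,
      val_loss = val_loss)
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else
    data.frame(epoch = integer(), lr = numeric(), pos_loss = numeric(),
               neg_loss = numeric(), val_loss = numeric())
  list(model = model, metrics = metrics, mining = mine_w, cfg = cfg)
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is one serialized file plus a JSON sidecar recording the
#' architecture spec, the init seed and a content hash, so a run can verify
#' exactly which detector produced it.
#'
#' @param model A `keypoint_model`.
#' @param path Checkpoint file path (sidecar written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec), seed = model$seed,
                  n_parameters = n_parameters(model),
                  receptive_field_px = model$receptive_field_px,
                  sha = unname(tools::md5sum(path)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "keypoint_model"))
  model
}
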