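#' Streaming exponential-moving-average background
#'
#' Raw in-line holograms carry a strong static background (the undiffracted
#' reference wave plus fixed-pattern structure) that drifts slowly over a
#' session. It is tracked causally with an exponential moving average of
#' preceding frames: `bg <- (1 - alpha) * bg + alpha * frame`. The update is
#' strictly causal -- a frame is always referenced against the background
#' accumulated from frames before it.
#'
#' @param alpha EMA decay factor in (0, 1]; small values track slow drift
#'   without absorbing transiting cells.
#' @param warmup Number of frames used only to seed the background before
#'   normalized output is considered valid.
#' @return Object of class `background_state`.
#' @export
background_state <- function(alpha = 0.02, warmup = 10L) {
  stopifnot(alpha > 0, alpha <= 1, warmup >= 1)
  structure(list(bg = NULL, alpha = alpha, warmup = as.integer(warmup),
                 frames_seen = 0L),
            class = "background_state")
}

#' Fold one frame into the running background
#'
#' The first frame initializes the background; subsequent frames update it as
#' `bg <- (1 - alpha) * bg + alpha * frame`.
#'
#' @param state A [background_state()].
#' @param frame Numeric matrix.
#' @return Updated state.
#' @export
update_background <- function(state, frame) {
  stopifnot(inherits(state, "background_state"), is.matrix(frame))
  if (is.null(state$bg)) {
    state$bg <- frame
  } else {
    if (!all(dim(frame) == dim(state$bg)))
      stop("frame shape does not match background")
    state$bg <- (1 - state$alpha) * state$bg + state$alpha * frame
  }
  state$frames_seen <- state$frames_seen + 1L
  state
}

#' Fixed-mean / fixed-sd normalization spec
#'
#' After background subtraction every frame is scaled with one fixed mean and
#' standard deviation so intensity statistics are comparable across sessions
#' and stations (rather than per-frame statistics, which would erase contrast
#' differences that carry signal).
#'
#' @param mean Fixed mean subtracted after background referencing.
#' @param sd Fixed scale (> 0).
#' @export
normalization_spec <- function(mean = 0, sd = 1) {
  if (sd <= 0) stop("sd must be positive")
  structure(list(mean = mean, sd = sd), class = "normalization_spec")
}

#' Background-subtract and normalize a frame
#'
#' `((frame - background) - mean) / sd`, using the background accumulated
#' from *preceding* frames only. Errors if the background has seen fewer than
#' `warmup` frames.
#'
#' @param frame Numeric matrix.
#' @param state A [background_state()] that has seen at least `warmup` frames.
#' @param spec A [normalization_spec()].
#' @return Numeric matrix, same shape.
#' @export
subtract_and_normalize <- function(frame, state, spec = normalization_spec()) {
  stopifnot(inherits(state, "background_state"),
            inherits(spec, "normalization_spec"))
  if (is.null(state$bg) || state$frames_seen < state$warmup)
    stop("background not initialized: fewer than warmup frames seen")
  if (!all(dim(frame) == dim(state$bg)))
    stop("frame shape does not match background")
  ((frame - state$bg) - spec$mean) / spec$sd
}

#' Preprocess a frame stack
#'
#' Streams a stack through the EMA background and fixed normalization. The
#' first `warmup` frames only seed the background and yield no output.
#'
#' @param frames Numeric array `height x width x n`.
#' @inheritParams subtract_and_normalize
#' @param alpha EMA decay factor.
#' @param warmup Seed-only frame count.
#' @return List: `frames` (normalized array, `n - warmup` slices), `index`
#'   (original frame indices of the output slices), `state`.
#' @export
preprocess_stack <- function(frames, spec = normalization_spec(),
                             alpha = 0.02, warmup = 10L) {
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (n <= warmup) stop("stack shorter than warmup")
  st <- background_state(alpha = alpha, warmup = warmup)
  out <- array(0, dim = c(dim(frames)[1:2], n - warmup))
  idx <- integer(n - warmup)
  j <- 0L
  for (f in seq_len(n)) {
    fr <- frames[, , f]
    if (f > warmup) {
      j <- j + 1L
      out[, , j] <- subtract_and_normalize(fr, st, spec)
      idx[j] <- f
    }
    st <- update_background(st, fr)
  }
  list(frames = out, index = idx, state = st)
}

#' Fringe-sharpness focus score
#'
#' Ratio of gradient energy to centered signal energy,
#' `sum(|grad f|^2) / sum((f - mean(f))^2)`. The gradient removes any
#' additive offset and the centered denominator makes the score invariant to
#' affine intensity changes; in the frequency domain it is the signal-power-
#' weighted mean squared spatial frequency, so Gaussian blurring strictly
#' lowers it. Constant frames score 0.
#'
#' @param frame Numeric matrix (background-subtracted).
#' @return Nonnegative scalar; larger means sharper fringe content.
#' @export
focus_metric <- function(frame) {
  stopifnot(is.matrix(frame))
  denom <- sum((frame - mean(frame))^2)
  if (denom <= .Machine$double.eps * length(frame)) return(0)
  gx <- frame[, -1, drop = FALSE] - frame[, -ncol(frame), drop = FALSE]
  gy <- frame[-1, , drop = FALSE] - frame[-nrow(frame), , drop = FALSE]
  (sum(gx^2) + sum(gy^2)) / denom
}
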