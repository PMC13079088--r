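# Independent oracles and small fixture builders shared across tests.

# Maximum bipartite matching (Kuhn augmenting paths) on the within-radius
# graph: the exact optimum for true-positive counts, independent of the
# greedy matcher under test.
oracle_max_match <- function(pred, ref, radius) {
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) return(0L)
  adj <- lapply(seq_len(np), function(i)
    which((ref$x - pred$x[i])^2 + (ref$y - pred$y[i])^2 <= radius^2))
  env <- new.env()
  env$matchR <- rep(0L, nr)
  try_augment <- function(i) {
    for (j in adj[[i]]) if (!env$seen[j]) {
      env$seen[j] <- TRUE
      if (env$matchR[j] == 0L || try_augment(env$matchR[j])) {
        env$matchR[j] <- i
        return(TRUE)
      }
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_len(np)) {
    env$seen <- rep(FALSE, nr)
    if (try_augment(i)) cnt <- cnt + 1L
  }
  cnt
}

# Circular Gaussian blur via the FFT (keeps the grid, no edge cropping).
oracle_blur <- function(m, sigma) {
  h <- nrow(m); w <- ncol(m)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  tf <- exp(-2 * pi^2 * sigma^2 *
              (outer(fy^2, rep(1, w)) + outer(rep(1, h), fx^2)))
  Re(stats::fft(stats::fft(m) * tf, inverse = TRUE)) / (h * w)
}

# Brute-force peak oracle: enumerate all pixels, keep strict 8-neighbour
# maxima >= threshold, then keep each only if no kept higher-priority peak
# lies within the radius.
oracle_peaks <- function(hm, threshold, nms_radius) {
  h <- nrow(hm); w <- ncol(hm)
  cand <- list()
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    nb <- hm[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (hm[i, j] >= threshold && sum(hm[i, j] > nb) == 8)
      cand[[length(cand) + 1L]] <- c(x = j - 1, y = i - 1, conf = hm[i, j])
  }
  # border maxima (compare against in-grid neighbours only)
  for (i in 1:h) for (j in 1:w) {
    if (i > 1 && i < h && j > 1 && j < w) next
    nb <- hm[max(1, i - 1):min(h, i + 1), max(1, j - 1):min(w, j + 1)]
    if (hm[i, j] >= threshold && sum(hm[i, j] > nb) == length(nb) - 1)
      cand[[length(cand) + 1L]] <- c(x = j - 1, y = i - 1, conf = hm[i, j])
  }
  if (!length(cand)) return(data.frame(x = numeric(), y = numeric(),
                                       confidence = numeric()))
  d <- do.call(rbind, cand)
  d <- data.frame(x = d[, "x"], y = d[, "y"], confidence = d[, "conf"])
  d <- d[order(-d$confidence, d$y, d$x), ]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- d[keep, , drop = FALSE]
    keep[i] <- all((kept$x - d$x[i])^2 + (kept$y - d$y[i])^2 > nms_radius^2)
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A small simulation shared by several test files (memoized).
tiny_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      oc <- optical_config(roi = c(192L, 64L))
      sc <- sim_config(optical = oc, flow_speed_um_s = 3000,
                       cell_rate_per_s = c(ctc_like = 4, blood_like = 6),
                       duration_s = 0.5, seed = 307L)
      cache <<- simulate_run(sc)
    }
    cache
  }
})
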