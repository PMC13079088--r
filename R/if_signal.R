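#' Robust baseline and noise scale of a PMT trace
#'
#' Rolling-median baseline with a window much longer than the expected pulse
#' width, and a noise scale from the scaled median absolute deviation of the
#' residual (`1.4826 * MAD`, consistent for Gaussian noise). Both are robust
#' to contamination of up to roughly 10% of samples by pulses.
#'
#' @param values Numeric PMT series.
#' @param window Rolling window length in samples (>= 3); rounded up to odd.
#' @return List `baseline` (series) and `noise` (scalar sd estimate).
#' @export
estimate_baseline <- function(values, window) {
  if (window < 3) stop("baseline window must span at least 3 samples")
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(values) %% 2L == 0L) length(values) - 1L
           else length(values))
  baseline <- as.numeric(stats::runmed(values, k, endrule = "median"))
  resid <- values - baseline
  noise <- 1.4826 * stats::median(abs(resid))
  list(baseline = baseline, noise = noise)
}

#' Detect fluorescence pulses in a PMT trace
#'
#' A transiting fluorescent cell produces a broad unimodal pulse whose
#' duration equals the field-of-view transit time, which separates true
#' events from electronic spikes and baseline noise. Excursions of the
#' baseline residual are accepted when (a) their apex amplitude reaches
#' `k_sigma` times the noise scale and (b) their full width at half maximum
#' lies within `width_gate` times the expected transit width. Excursions
#' separated by less than `merge_gap` times the expected width are merged
#' first (one cell can dip briefly below threshold mid-transit).
#'
#' @param time_s Sample times (uniform).
#' @param values PMT series.
#' @param baseline,noise From [estimate_baseline()].
#' @param expected_width_s Expected pulse FWHM: field-of-view length divided
#'   by flow speed.
#' @param k_sigma Amplitude acceptance threshold in noise units (default 6).
#' @param width_gate Acceptable FWHM range as multiples of
#'   `expected_width_s`.
#' @param merge_gap Merge excursions closer than this fraction of
#'   `expected_width_s`.
#' @param channel Channel name recorded in the output.
#' @return Data frame `channel`, `t_center_s`, `amplitude`, `width_s`, `snr`.
#' @export
detect_pmt_peaks <- function(time_s, values, baseline, noise,
                             expected_width_s, k_sigma = 6,
                             width_gate = c(0.3, 3), merge_gap = 0.2,
                             channel = "pmt") {
  empty <- data.frame(channel = character(), t_center_s = numeric(),
                      amplitude = numeric(), width_s = numeric(),
                      snr = numeric())
  resid <- values - baseline
  if (noise <= 0) noise <- .Machine$double.eps
  dt <- stats::median(diff(time_s))
  above <- resid >= 0.5 * k_sigma * noise   # candidate support at half gate
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short gaps
  gap_n <- merge_gap * expected_width_s / dt
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1 < gap_n)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
    runs <- merged
  }
  out <- list()
  for (i in seq_len(nrow(runs))) {
    sl <- runs$start[i]:runs$end[i]
    amp <- max(resid[sl])
    if (amp < k_sigma * noise) next
    half <- sl[resid[sl] >= amp / 2]
    width <- (length(half)) * dt
    if (width < width_gate[1] * expected_width_s ||
        width > width_gate[2] * expected_width_s) next
    center <- sum(time_s[half] * resid[half]) / sum(resid[half])
    out[[length(out) + 1L]] <- data.frame(
      channel = channel, t_center_s = center, amplitude = amp,
      width_s = width, snr = amp / noise)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Detect pulses in both channels of a trace table
#'
#' Convenience wrapper running [estimate_baseline()] and
#' [detect_pmt_peaks()] on the `pmt1`/`pmt2` columns of a trace data frame.
#'
#' @param traces Data frame `time_s`, `pmt1`, `pmt2` (channel names taken
#'   from `attr(traces, "channels")`, default `c("pmt1", "pmt2")`).
#' @param expected_width_s Expected pulse FWHM (s).
#' @param k_sigma Amplitude threshold in noise units.
#' @param baseline_window_mult Baseline window as a multiple of the expected
#'   width (default 50).
#' @return List of two peak data frames, named by channel.
#' @export
trace_peaks <- function(traces, expected_width_s, k_sigma = 6,
                        baseline_window_mult = 50) {
  channels <- attr(traces, "channels") %||% c("pmt1", "pmt2")
  dt <- stats::median(diff(traces$time_s))
  win <- max(3, baseline_window_mult * expected_width_s / dt)
  win <- min(win, length(traces$time_s))
  out <- list()
  for (ci in 1:2) {
    v <- traces[[paste0("pmt", ci)]]
    bl <- estimate_baseline(v, win)
    out[[channels[ci]]] <- detect_pmt_peaks(
      traces$time_s, v, bl$baseline, bl$noise, expected_width_s,
      k_sigma = k_sigma, channel = channels[ci])
  }
  out
}

#' One-to-one matching of two sorted time sequences within a tolerance.
#' Points on a line always admit a non-crossing maximum matching, so a
#' dynamic program over the two sorted sequences (maximize matches, then
#' minimize total |dt|) yields the exact optimum.
#' @noRd
match_times <- function(t1, t2, tol) {
  n1 <- length(t1); n2 <- length(t2)
  if (n1 == 0 || n2 == 0)
    return(data.frame(i = integer(), j = integer()))
  o1 <- order(t1); o2 <- order(t2)
  s1 <- t1[o1]; s2 <- t2[o2]
  cnt <- matrix(0L, n1 + 1, n2 + 1)
  cost <- matrix(0, n1 + 1, n2 + 1)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    best_c <- cnt[i, j + 1]; best_d <- cost[i, j + 1]
    if (cnt[i + 1, j] > best_c ||
        (cnt[i + 1, j] == best_c && cost[i + 1, j] < best_d)) {
      best_c <- cnt[i + 1, j]; best_d <- cost[i + 1, j]
    }
    dd <- abs(s1[i] - s2[j])
    if (dd <= tol) {
      mc <- cnt[i, j] + 1L; md <- cost[i, j] + dd
      if (mc > best_c || (mc == best_c && md < best_d)) {
        best_c <- mc; best_d <- md
      }
    }
    cnt[i + 1, j + 1] <- best_c; cost[i + 1, j + 1] <- best_d
  }
  # traceback
  i <- n1; j <- n2
  pairs <- list()
  while (i > 0 && j > 0) {
    dd <- abs(s1[i] - s2[j])
    if (dd <= tol && cnt[i + 1, j + 1] == cnt[i, j] + 1L &&
        abs(cost[i + 1, j + 1] - (cost[i, j] + dd)) < 1e-12) {
      pairs[[length(pairs) + 1L]] <- c(o1[i], o2[j])
      i <- i - 1; j <- j - 1
    } else if (cnt[i + 1, j + 1] == cnt[i, j + 1] &&
               abs(cost[i + 1, j + 1] - cost[i, j + 1]) < 1e-12) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(i = m[, 1], j = m[, 2])
  } else data.frame(i = integer(), j = integer())
}

#' Match fluorescence pulses across the two PMT channels
#'
#' One-to-one matching by centre-time proximity: the exact maximum matching
#' of the two pulse-time sequences under the tolerance (computed by a
#' non-crossing dynamic program; ties resolved towards the smallest total
#' time offset). A matched pair becomes one event positive in both
#' markers; an unmatched pulse becomes a singleton event positive in its own
#' channel only, so `|events| = |peaks1| + |peaks2| - |matched pairs|`.
#'
#' @param peaks_ch1,peaks_ch2 Peak data frames from [detect_pmt_peaks()].
#' @param time_tolerance Maximum centre-time separation for a match (s), > 0.
#' @param channels Marker names of the two channels.
#' @return Data frame `t_center_s`, `<ch1>_pos`, `<ch2>_pos`,
#'   `<ch1>_amplitude`, `<ch2>_amplitude`.
#' @export
match_channels <- function(peaks_ch1, peaks_ch2, time_tolerance,
                           channels = c("psma", "epcam")) {
  stopifnot(time_tolerance > 0)
  n1 <- nrow(peaks_ch1); n2 <- nrow(peaks_ch2)
  pairs <- match_times(peaks_ch1$t_center_s, peaks_ch2$t_center_s,
                       time_tolerance)
  used1 <- logical(n1); used2 <- logical(n2)
  m <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    used1[i] <- TRUE; used2[j] <- TRUE
    m[[length(m) + 1L]] <- data.frame(
      t_center_s = (peaks_ch1$t_center_s[i] + peaks_ch2$t_center_s[j]) / 2,
      p1 = TRUE, p2 = TRUE,
      a1 = peaks_ch1$amplitude[i], a2 = peaks_ch2$amplitude[j])
  }
  s1 <- which(!used1); s2 <- which(!used2)
  for (i in s1) m[[length(m) + 1L]] <- data.frame(
    t_center_s = peaks_ch1$t_center_s[i], p1 = TRUE, p2 = FALSE,
    a1 = peaks_ch1$amplitude[i], a2 = 0)
  for (j in s2) m[[length(m) + 1L]] <- data.frame(
    t_center_s = peaks_ch2$t_center_s[j], p1 = FALSE, p2 = TRUE,
    a1 = 0, a2 = peaks_ch2$amplitude[j])
  out <- if (length(m)) do.call(rbind, m) else
    data.frame(t_center_s = numeric(), p1 = logical(), p2 = logical(),
               a1 = numeric(), a2 = numeric())
  out <- out[order(out$t_center_s), , drop = FALSE]
  names(out) <- c("t_center_s", paste0(channels, "_pos"),
                  paste0(channels, "_amplitude"))
  rownames(out) <- NULL
  out
}

#' Marker status from an accepted pulse (or its absence)
#'
#' A marker is scored positive for an event exactly when an accepted
#' fluorescence pulse exists for that channel at the event's time;
#' sub-threshold excursions were already rejected upstream and score
#' negative.
#'
#' @param peak One-row peak data frame, or `NULL` for absence.
#' @return `"positive"` or `"negative"`.
#' @export
score_marker <- function(peak = NULL) {
  if (is.null(peak) || (is.data.frame(peak) && nrow(peak) == 0))
    "negative" else "positive"
}
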