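#' Extract confidence-scored peaks from a heatmap
#'
#' Strict local maxima (8-neighbourhood) at or above the confidence
#' threshold, followed by greedy non-maximum suppression: within any
#' `nms_radius` neighbourhood only the highest peak survives, ties broken in
#' favour of the lowest `(y, x)`. Coordinates are 0-based pixel centres.
#'
#' @param heatmap Numeric matrix with values in `[0, 1]`.
#' @param threshold Confidence threshold in (0, 1).
#' @param nms_radius Suppression radius in pixels (Euclidean). The default
#'   is about twice the keypoint sigma at full resolution.
#' @return Data frame `x`, `y`, `confidence` (possibly zero rows), sorted by
#'   decreasing confidence.
#' @export
heatmap_peaks <- function(heatmap, threshold = 0.5, nms_radius = 16) {
  stopifnot(is.matrix(heatmap), threshold > 0, threshold < 1)
  h <- nrow(heatmap); w <- ncol(heatmap)
  empty <- data.frame(x = numeric(), y = numeric(), confidence = numeric())
  if (h < 3 || w < 3) return(empty)
  # pad with -Inf so border pixels can be maxima of their inside neighbours
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- heatmap
  core <- pad[2:(h + 1), 2:(w + 1)]
  is_max <- core >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
    is_max <- is_max & (core > nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  cand <- data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1,
                     confidence = heatmap[idx])
  cand <- cand[order(-cand$confidence, cand$y, cand$x), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    d2 <- (kept$x - cand$x[i])^2 + (kept$y - cand$y[i])^2
    keep[i] <- all(d2 > nms_radius^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the detector over a normalized frame stack
#'
#' Forward pass per frame, bilinear upsampling of the half-resolution
#' heatmap back to input resolution, then [heatmap_peaks()].
#'
#' @param model A trained `keypoint_model`.
#' @param frames Normalized array `H x W x n`.
#' @param threshold Peak extraction threshold.
#' @param nms_radius Suppression radius (input px).
#' @param frame_index Optional original frame indices (length n).
#' @return Data frame `frame`, `x`, `y`, `confidence`.
#' @export
detect_frames <- function(model, frames, threshold = 0.2, nms_radius = 16,
                          frame_index = NULL) {
  stopifnot(length(dim(frames)) == 3)
  n <- dim(frames)[3]
  if (is.null(frame_index)) frame_index <- seq_len(n)
  out <- list()
  for (f in seq_len(n)) {
    hm <- upsample_bilinear(model_forward(model, frames[, , f]),
                            model$spec$downsample)
    pk <- heatmap_peaks(hm, threshold = threshold, nms_radius = nms_radius)
    if (nrow(pk))
      out[[length(out) + 1L]] <- data.frame(frame = frame_index[f], pk)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               confidence = numeric())
}

#' Link per-frame detections into cell tracks
#'
#' A flowing cell is captured in several consecutive frames; to enumerate
#' each cell once, detections are greedily linked frame to frame using the
#' known along-flow displacement: a detection in frame `f` extends the track
#' whose predicted position (last position advanced by
#' `flow_displacement_per_frame` along x) is nearest, if within `gate`
#' pixels; otherwise it starts a new track. Every detection belongs to
#' exactly one track.
#'
#' @param detections Data frame `frame`, `x`, `y`, `confidence`.
#' @param flow_displacement_per_frame Expected along-flow displacement
#'   between consecutive frames (px).
#' @param gate Maximum distance between predicted and observed position (px).
#' @return Data frame of the input detections with a `track_id` column;
#'   per-track summary in `attr(, "tracks")` (`track_id`, `n`,
#'   `first_frame`, `last_frame`, `confidence` = max member confidence,
#'   `mean_y`).
#' @export
link_tracks <- function(detections, flow_displacement_per_frame, gate) {
  if (gate < 0) stop("gate must be nonnegative")
  det <- detections[order(detections$frame, -detections$confidence), ,
                    drop = FALSE]
  n <- nrow(det)
  det$track_id <- integer(n)
  last <- data.frame(track_id = integer(), frame = integer(), x = numeric(),
                     y = numeric())
  next_id <- 1L
  for (i in seq_len(n)) {
    f <- det$frame[i]
    active <- last[last$frame == f - 1L, , drop = FALSE]
    assigned <- FALSE
    if (nrow(active)) {
      px <- active$x + flow_displacement_per_frame
      d2 <- (px - det$x[i])^2 + (active$y - det$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= gate^2) {
        id <- active$track_id[j]
        det$track_id[i] <- id
        last[last$track_id == id, c("frame", "x", "y")] <-
          list(f, det$x[i], det$y[i])
        assigned <- TRUE
      }
    }
    if (!assigned) {
      det$track_id[i] <- next_id
      last <- rbind(last, data.frame(track_id = next_id, frame = f,
                                     x = det$x[i], y = det$y[i]))
      next_id <- next_id + 1L
    }
  }
  agg <- do.call(rbind, lapply(split(det, det$track_id), function(d)
    data.frame(track_id = d$track_id[1], n = nrow(d),
               first_frame = min(d$frame), last_frame = max(d$frame),
               confidence = max(d$confidence), mean_y = mean(d$y),
               mean_x = mean(d$x))))
  rownames(agg) <- NULL
  attr(det, "tracks") <- agg
  det
}

#' Track-level summary of linked detections
#' @param linked Output of [link_tracks()].
#' @export
track_table <- function(linked) attr(linked, "tracks")

#' Match predicted detections to reference keypoints
#'
#' One-to-one greedy matching: predictions are visited in order of
#' descending confidence and each takes the nearest still-unmatched
#' reference within `radius`. True positives are matched predictions, false
#' positives unmatched predictions, false negatives unmatched references, so
#' `TP + FN = |reference|` and `TP + FP = |predicted|`.
#'
#' @param predicted Data frame `x`, `y` and optionally `confidence`.
#' @param reference Data frame `x`, `y`.
#' @param radius Maximum matching distance (px), > 0.
#' @return List `tp`, `fp`, `fn`, `pairs` (data frame `pred`, `ref`,
#'   `distance` of 1-based row indices).
#' @export
match_to_reference <- function(predicted, reference, radius) {
  stopifnot(radius > 0)
  np <- nrow(predicted); nr <- nrow(reference)
  conf <- if ("confidence" %in% names(predicted)) predicted$confidence
  else rep(1, np)
  ord <- order(-conf)
  taken <- logical(nr)
  pairs <- list()
  for (i in ord) {
    if (nr == 0) break
    d2 <- (reference$x - predicted$x[i])^2 + (reference$y - predicted$y[i])^2
    d2[taken] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= radius^2) {
      taken[j] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        data.frame(pred = i, ref = j, distance = sqrt(d2[j]))
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pred = integer(), ref = integer(), distance = numeric())
  tp <- nrow(pairs)
  list(tp = tp, fp = np - tp, fn = nr - tp, pairs = pairs)
}

#' Match tracks to ground-truth events
#'
#' A track matches a truth event when at least one of its detections falls
#' within `radius` px of the event's true centroid in the same frame.
#' Matching is one-to-one, greedy by descending track confidence.
#'
#' @param linked Output of [link_tracks()].
#' @param truth_tracks Data frame `event_id`, `frame`, `x_px`, `y_px` of
#'   per-frame true centroids.
#' @param radius Matching radius (px).
#' @return Data frame `event_id`, `track_id`, `confidence` (NA track for
#'   unmatched events).
#' @export
match_tracks_to_truth <- function(linked, truth_tracks, radius) {
  tracks <- track_table(linked)
  ev_ids <- unique(truth_tracks$event_id)
  out <- data.frame(event_id = ev_ids, track_id = NA_integer_,
                    confidence = NA_real_)
  if (is.null(tracks) || nrow(tracks) == 0 || length(ev_ids) == 0) return(out)
  taken_ev <- character(0)
  for (ti in order(-tracks$confidence)) {
    id <- tracks$track_id[ti]
    dets <- linked[linked$track_id == id, , drop = FALSE]
    cand <- merge(dets, truth_tracks, by = "frame")
    if (nrow(cand) == 0) next
    cand$d2 <- (cand$x - cand$x_px)^2 + (cand$y - cand$y_px)^2
    cand <- cand[cand$d2 <= radius^2 & !(cand$event_id %in% taken_ev), ,
                 drop = FALSE]
    if (nrow(cand) == 0) next
    ev <- cand$event_id[which.min(cand$d2)]
    taken_ev <- c(taken_ev, ev)
    out$track_id[out$event_id == ev] <- id
    out$confidence[out$event_id == ev] <- tracks$confidence[ti]
  }
  out
}

#' Recovery (true-positive rate) versus confidence threshold
#'
#' `TPR(theta)` is the fraction of ground-truth events matched by a track
#' whose representative confidence is at least `theta`. Because the matched
#' set only shrinks as `theta` rises, the curve is non-increasing.
#'
#' @param matches Output of [match_tracks_to_truth()] (or any data frame
#'   with one row per truth event and a `confidence` column, NA when
#'   unmatched).
#' @param thresholds Ascending numeric vector of thresholds.
#' @return Data frame `threshold`, `tpr`.
#' @export
recovery_curve <- function(matches, thresholds) {
  if (nrow(matches) == 0) stop("recovery undefined for zero truth events")
  stopifnot(!is.unsorted(thresholds))
  tpr <- vapply(thresholds, function(th)
    sum(!is.na(matches$confidence) & matches$confidence >= th) /
      nrow(matches), 0)
  data.frame(threshold = thresholds, tpr = tpr)
}
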