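#' Fuse holographic tracks with immunofluorescence events
#'
#' Holography and the PMT channels share one clock, so a track (whose
#' detections span a transit interval of frames) and an IF event (a pulse
#' centre time) belong to the same cell when their times agree. Matching is
#' one-to-one and greedy on the smallest time difference within
#' `time_tolerance`. Tracks without an IF partner keep all-negative marker
#' status; IF events without a holographic track are returned separately
#' and are never enumerable as cells (holography is the cell-presence
#' channel).
#'
#' @param tracks Track summary (from [track_table()]).
#' @param if_events Cross-channel event table from [match_channels()].
#' @param frame_rate_hz Frame rate used to convert frame indices to seconds.
#' @param time_tolerance Maximum |track mid-time - pulse centre| (s).
#' @param channels Marker names.
#' @return Data frame of fused cell events: `track_id`, `confidence`,
#'   `t_mid_s`, `n_frames`, `<marker>_pos` flags; unmatched IF events in
#'   `attr(, "orphan_if_events")`.
#' @export
align_events <- function(tracks, if_events, frame_rate_hz,
                         time_tolerance, channels = c("psma", "epcam")) {
  stopifnot(time_tolerance > 0)
  nt <- if (is.null(tracks)) 0L else nrow(tracks)
  fused <- data.frame(track_id = integer(), confidence = numeric(),
                      t_mid_s = numeric(), n_frames = integer())
  for (ch in channels) fused[[paste0(ch, "_pos")]] <- logical()
  if (nt == 0) {
    attr(fused, "orphan_if_events") <- if_events
    return(fused)
  }
  t_mid <- (tracks$first_frame + tracks$last_frame) / 2 / frame_rate_hz
  fused <- data.frame(track_id = tracks$track_id,
                      confidence = tracks$confidence,
                      t_mid_s = t_mid, n_frames = tracks$n)
  for (ch in channels) fused[[paste0(ch, "_pos")]] <- FALSE
  ne <- nrow(if_events)
  matched_ev <- logical(ne)
  if (ne > 0) {
    pairs <- match_times(t_mid, if_events$t_center_s, time_tolerance)
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$i[k]; ei <- pairs$j[k]
      matched_ev[ei] <- TRUE
      for (ch in channels)
        fused[[paste0(ch, "_pos")]][ti] <- if_events[[paste0(ch, "_pos")]][ei]
    }
  }
  attr(fused, "orphan_if_events") <- if_events[!matched_ev, , drop = FALSE]
  fused
}

#' CTC gating rule
#'
#' A fused cell event is called a CTC only if its holographic confidence
#' reaches the model threshold (default 0.5) *and* it is PSMA-positive.
#' EpCAM is deliberately excluded from the gate -- EpCAM can be
#' downregulated during epithelial-to-mesenchymal transition, so gating on
#' it would discard a clinically important CTC subset; it is kept as a
#' phenotyping marker only. The threshold comparison is inclusive (`>=`) by
#' default; set `strict_greater = TRUE` for a strict comparison.
#'
#' @param confidence Holographic confidence in `[0, 1]` (vectorized).
#' @param psma_positive Logical PSMA status (vectorized).
#' @param threshold Holography model threshold (default 0.5).
#' @param require_psma Require PSMA positivity (default TRUE).
#' @param strict_greater Use `>` instead of `>=` for the threshold.
#' @return Logical vector: is the event a CTC?
#' @export
classify_ctc <- function(confidence, psma_positive, threshold = 0.5,
                         require_psma = TRUE, strict_greater = FALSE) {
  conf_ok <- if (strict_greater) confidence > threshold
  else confidence >= threshold
  if (require_psma) conf_ok & psma_positive else conf_ok
}

#' Enumerate CTCs per millilitre of whole blood
#'
#' Applies [classify_ctc()] to a fused event table and normalizes the count
#' to the whole-blood volume of the originating tube, so samples of
#' different collected volumes are comparable. The marker breakdown (the
#' fraction of PSMA-positive CTCs that are also EpCAM-positive) is computed
#' among the gated events.
#'
#' @param events Fused event table from [align_events()].
#' @param volume_ml Whole-blood volume the run represents (> 0).
#' @param threshold Holography threshold for the gate.
#' @param sample_id Identifier recorded in the report.
#' @param ... Passed to [classify_ctc()].
#' @return List of class `enumeration_report`: `sample_id`, `volume_ml`,
#'   `n_ctc`, `ctc_per_ml`, `frac_epcam_pos_among_psma_pos`, `threshold`.
#' @export
enumerate_per_ml <- function(events, volume_ml, threshold = 0.5,
                             sample_id = "sample", ...) {
  if (!is.numeric(volume_ml) || volume_ml <= 0)
    stop("volume_ml must be positive")
  is_ctc <- if (nrow(events)) classify_ctc(events$confidence,
                                           events$psma_pos,
                                           threshold = threshold, ...)
  else logical(0)
  n_ctc <- sum(is_ctc)
  frac <- if (n_ctc > 0 && "epcam_pos" %in% names(events))
    mean(events$epcam_pos[is_ctc]) else NA_real_
  structure(list(sample_id = sample_id, volume_ml = volume_ml,
                 n_ctc = n_ctc, ctc_per_ml = n_ctc / volume_ml,
                 frac_epcam_pos_among_psma_pos = frac,
                 threshold = threshold),
            class = "enumeration_report")
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat(sprintf("enumeration_report %s: %d CTC in %g mL -> %.3g CTC/mL (theta = %g)\n",
              x$sample_id, x$n_ctc, x$volume_ml, x$ctc_per_ml, x$threshold))
  if (!is.na(x$frac_epcam_pos_among_psma_pos))
    cat(sprintf("  EpCAM+ fraction among PSMA+ CTCs: %.2f\n",
                x$frac_epcam_pos_among_psma_pos))
  invisible(x)
}

#' Positive predictive value at an assumed abundance
#'
#' `PPV = TPR * c / (TPR * c + FPR)`: the probability that a called CTC is
#' real, given the recovery rate `TPR`, the false-positive rate `FPR`
#' (events per mL measured on negative samples) and an assumed true
#' abundance `c` (cells per mL).
#'
#' @param tpr True-positive rate (recovery) in `[0, 1]`.
#' @param abundance_per_ml Assumed CTC abundance `c` (cells/mL).
#' @param fpr_per_ml False positives per mL.
#' @return PPV in `[0, 1]`.
#' @export
ppv <- function(tpr, abundance_per_ml, fpr_per_ml) {
  stopifnot(tpr >= 0, tpr <= 1, abundance_per_ml >= 0, fpr_per_ml >= 0)
  denom <- tpr * abundance_per_ml + fpr_per_ml
  if (denom <= 0) stop("PPV undefined: TPR*c + FPR must be positive")
  tpr * abundance_per_ml / denom
}

#' Depletion and enrichment arithmetic across pipeline stages
#'
#' For each stage and population, depletion is `1 - out/in` (computed from
#' mean counts). The enrichment fold of the target population relative to a
#' background population in one stage is its retention divided by the
#' background's surviving fraction, and cumulative enrichment across stages
#' multiplies.
#'
#' @param stages Data frame with columns `stage`, `population`, `count_in`,
#'   `count_out` (counts per mL, means).
#' @param target Name of the target population (default `"ctc"`).
#' @return List: `per_stage` (data frame with `depletion` and `retention`
#'   per stage x population) and `enrichment` (data frame of cumulative
#'   fold enrichment of the target versus each background population).
#' @export
depletion_stats <- function(stages, target = "ctc") {
  stopifnot(all(c("stage", "population", "count_in", "count_out") %in%
                  names(stages)))
  if (any(stages$count_in <= 0)) stop("stage input counts must be positive")
  if (any(stages$count_out > stages$count_in))
    stop("negative depletion: output exceeds input")
  per <- stages
  per$retention <- per$count_out / per$count_in
  per$depletion <- 1 - per$retention
  pops <- unique(per$population)
  cum_ret <- vapply(pops, function(p)
    prod(per$retention[per$population == p]), 0)
  names(cum_ret) <- pops
  bg <- setdiff(pops, target)
  enr <- data.frame(background = bg,
                    fold_enrichment = cum_ret[[target]] / cum_ret[bg])
  rownames(enr) <- NULL
  list(per_stage = per, enrichment = enr,
       cumulative_retention = cum_ret)
}

#' Per-cohort summary of enumeration reports
#'
#' Median CTCs per mL within each cohort (even-sized cohorts take the mean
#' of the two middle values, the usual sample median), with the full
#' distribution retained.
#'
#' @param reports List of `enumeration_report`s.
#' @param cohorts Character vector of cohort labels, one per report.
#' @return List: `summary` (data frame `cohort`, `n`, `median_per_ml`) and
#'   `distributions` (named list of per-mL vectors).
#' @export
cohort_summary <- function(reports, cohorts) {
  stopifnot(length(reports) == length(cohorts), length(reports) >= 1)
  per_ml <- vapply(reports, function(r) r$ctc_per_ml, 0)
  split_vals <- split(per_ml, cohorts)
  if (any(vapply(split_vals, length, 0L) == 0)) stop("empty cohort")
  summary <- data.frame(
    cohort = names(split_vals),
    n = vapply(split_vals, length, 0L),
    median_per_ml = vapply(split_vals, stats::median, 0))
  rownames(summary) <- NULL
  list(summary = summary, distributions = split_vals)
}
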