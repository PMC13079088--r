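#' Simulate a labelled set of training sessions
#'
#' Builds the two training streams of the detector from the hologram
#' simulator, mirroring how the real system assembles its data: positive
#' sessions contain only CTC-like cells in buffer (every nucleated object is
#' a target, labels from the generator's ground truth standing in for
#' pseudo-labels), negative sessions contain only blood-like cells and are
#' supervised with blank heatmaps. Frames are background-referenced and
#' normalized with one fixed spec; the labels are remapped onto the
#' preprocessed frame index.
#'
#' @param n_pos,n_neg Number of positive / negative sessions.
#' @param frames_per_session Usable frames per session (after warmup).
#' @param optical An [optical_config()]; small ROIs keep training cheap.
#' @param flow_speed_um_s Flow speed (um/s).
#' @param rate_per_s Cell arrival rate per session stream (events/s).
#' @param seed Master seed; session i uses `seed + i`.
#' @param norm_sd Fixed normalization scale; defaults to the shot-noise
#'   scale `sqrt(photon_budget)`.
#' @param warmup Background warmup frames (excluded from the output).
#' @param photon_budget,read_noise_sd,background_drift Passed to
#'   [sim_config()].
#' @return List of session lists (`frames`, `labels`, `positive`, `medium`,
#'   `cohort`, `session_id`, `truth`, `truth_tracks`), suitable for
#'   [train_detector()].
#' @export
simulate_session_set <- function(n_pos, n_neg, frames_per_session = 100L,
                                 optical = optical_config(roi = c(256L, 128L)),
                                 flow_speed_um_s = 8000,
                                 rate_per_s = 40,
                                 seed = 1L,
                                 norm_sd = NULL,
                                 warmup = 10L,
                                 photon_budget = 2000,
                                 read_noise_sd = 5,
                                 background_drift = list(amplitude = 20,
                                                         timescale_s = 5)) {
  duration_s <- (frames_per_session + warmup) / optical$frame_rate_hz
  if (is.null(norm_sd)) norm_sd <- sqrt(photon_budget)
  norm <- normalization_spec(0, norm_sd)
  sessions <- list()
  kinds <- c(rep("pos", n_pos), rep("neg", n_neg))
  for (i in seq_along(kinds)) {
    pos <- kinds[i] == "pos"
    rates <- if (pos) c(ctc_like = rate_per_s, blood_like = 0)
    else c(ctc_like = 0, blood_like = rate_per_s)
    cfg <- sim_config(optical = optical, flow_speed_um_s = flow_speed_um_s,
                      cell_rate_per_s = rates,
                      photon_budget = photon_budget,
                      read_noise_sd = read_noise_sd,
                      background_drift = background_drift,
                      duration_s = duration_s, seed = seed + i)
    run <- simulate_run(cfg,
                        session_id = sprintf("%s-%03d", kinds[i], i),
                        sample_id = sprintf("sample-%03d", i),
                        cohort = if (pos) "cell_line" else "healthy")
    pre <- preprocess_stack(run$frames, norm, warmup = warmup)
    tr <- run$tracks[run$tracks$frame > warmup, , drop = FALSE]
    labels <- if (pos && nrow(tr)) {
      data.frame(frame = tr$frame - warmup, x = tr$x_px, y = tr$y_px)
    } else data.frame(frame = integer(), x = numeric(), y = numeric())
    # clip labels whose centre sits just outside the usable grid
    h <- dim(pre$frames)[1]; w <- dim(pre$frames)[2]
    labels <- labels[labels$x >= 0 & labels$x <= w - 1 &
                       labels$y >= 0 & labels$y <= h - 1, , drop = FALSE]
    truth_tracks <- tr
    truth_tracks$frame <- truth_tracks$frame - warmup
    sessions[[i]] <- list(frames = pre$frames, labels = labels,
                          positive = pos,
                          medium = if (pos) "buffer" else "blood",
                          cohort = if (pos) "cell_line" else "healthy",
                          session_id = sprintf("%s-%03d", kinds[i], i),
                          truth = run$truth, truth_tracks = truth_tracks,
                          config = cfg)
  }
  sessions
}
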