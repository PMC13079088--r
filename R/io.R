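#' Run manifest
#'
#' Sample provenance required for per-mL enumeration and leakage-free
#' splitting: sample and session ids, cohort, whole-blood volume, the
#' acquisition optics, the master seed, and (once files are written) an
#' inventory with content hashes.
#'
#' @param sample_id,session_id Identifiers.
#' @param cohort `"healthy"`, `"cell_line"` or `"patient"`.
#' @param volume_ml Whole-blood volume the run represents (> 0).
#' @param optical An [optical_config()].
#' @param seed Master seed of the run.
#' @param files Optional named list of file paths to inventory (hashed).
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(sample_id, cohort, session_id, volume_ml,
                         optical, seed, files = NULL) {
  stopifnot(volume_ml > 0, inherits(optical, "optical_config"))
  inv <- NULL
  if (!is.null(files))
    inv <- lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  structure(list(sample_id = sample_id, cohort = cohort,
                 session_id = session_id, volume_ml = volume_ml,
                 optical = unclass(optical), seed = as.integer(seed),
                 files = inv),
            class = "run_manifest")
}

#' Write / read a run manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @param verify Check recorded file hashes against the files on disk.
#' @export
read_manifest <- function(path, verify = TRUE) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$optical <- do.call(optical_config, m$optical[
    c("wavelength_um", "magnification", "numerical_aperture",
      "sensor_pixel_pitch_um", "frame_rate_hz", "roi", "focal_offset_um")])
  m$seed <- as.integer(m$seed)
  if (verify && !is.null(m$files) && length(m$files)) {
    for (f in m$files) {
      if (!file.exists(f$path)) next
      if (!identical(unname(tools::md5sum(f$path)), f$md5))
        stop(sprintf("manifest hash mismatch for %s", f$path))
    }
  }
  class(m) <- "run_manifest"
  m
}

#' Write / read a hologram frame stack as multi-page 16-bit TIFF
#'
#' Frames are stored as uint16 counts; values outside `[0, 65535]` are an
#' error rather than silently clipped. Round-trips are bit-identical.
#'
#' @param frames Numeric array `H x W x n` of sensor counts.
#' @param path TIFF file path.
#' @export
write_frames <- function(frames, path) {
  stopifnot(length(dim(frames)) == 3)
  if (any(frames < 0 | frames > 65535))
    stop("frame values outside uint16 range")
  pages <- lapply(seq_len(dim(frames)[3]), function(i)
    round(frames[, , i]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * 65535)
  arr
}

#' Write / read PMT traces as CSV
#'
#' Schema: `time_s`, `pmt1`, `pmt2`; channel names are kept in a header
#' comment and restored on read.
#'
#' @param traces Data frame from [simulate_run()].
#' @param path CSV path.
#' @export
write_traces <- function(traces, path) {
  need <- c("time_s", "pmt1", "pmt2")
  miss <- setdiff(need, names(traces))
  if (length(miss)) stop(sprintf("traces missing column: %s", miss[1]))
  ch <- attr(traces, "channels") %||% c("pmt1", "pmt2")
  con <- file(path, "w")
  writeLines(sprintf("# channels: %s", paste(ch, collapse = ",")), con)
  utils::write.csv(traces[, need], con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1)
  ch <- c("pmt1", "pmt2")
  skip <- 0L
  if (startsWith(first, "# channels:")) {
    ch <- trimws(strsplit(sub("# channels:", "", first), ",")[[1]])
    skip <- 1L
  }
  out <- utils::read.csv(path, skip = skip)
  miss <- setdiff(c("time_s", "pmt1", "pmt2"), names(out))
  if (length(miss)) stop(sprintf("traces missing column: %s", miss[1]))
  attr(out, "channels") <- ch
  out
}

#' Write / read detection or event tables as CSV
#'
#' The required schema is checked on both directions and violations name
#' the offending column.
#'
#' @param events Data frame.
#' @param path CSV path.
#' @param required Character vector of required columns.
#' @export
write_events <- function(events, path,
                         required = c("frame", "x", "y", "confidence")) {
  miss <- setdiff(required, names(events))
  if (length(miss)) stop(sprintf("events missing column: %s", miss[1]))
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, required = c("frame", "x", "y", "confidence")) {
  out <- utils::read.csv(path)
  miss <- setdiff(required, names(out))
  if (length(miss)) stop(sprintf("events missing column: %s", miss[1]))
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with defaults matching the
#' platform's stated operating point (holography threshold 0.5, keypoint
#' sigma 2.8 um, learning rate 0.01 with 0.85 decay, asymmetric weight 0.1).
#' Can be loaded from a YAML file; unknown keys are an error so typos never
#' pass silently.
#'
#' @param preprocess,target,loss,train,detect,if_signal,fusion Lists of
#'   stage parameters (see defaults in the function body).
#' @param output_dir Where [run_pipeline()] writes artifacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = list(), target = list(),
                            loss = list(), train = list(), detect = list(),
                            if_signal = list(), fusion = list(),
                            output_dir = tempfile("holoflow-run-")) {
  defaults <- list(
    preprocess = list(alpha = 0.02, warmup = 10L, norm_mean = 0,
                      norm_sd = 1),
    target = list(sigma_um = 2.8),
    loss = list(a_fp_on_positive = 0.1, a_otherwise = 1.0,
                labeled_threshold = 0.05),
    train = list(learning_rate = 0.01, lr_decay_per_epoch = 0.85,
                 epochs = 10L, batch_size = 8L, seed = 1L),
    detect = list(threshold = 0.5, extraction_threshold = 0.2,
                  nms_radius_px = 16, match_radius_um = 15, gate_px = 25),
    if_signal = list(k_sigma = 6, width_gate = c(0.3, 3),
                     merge_gap = 0.2, baseline_window_mult = 50,
                     time_tolerance_mult = 0.5),
    fusion = list(threshold = 0.5, require_psma = TRUE,
                  strict_greater = FALSE, time_tolerance_mult = 1.0))
  user <- list(preprocess = preprocess, target = target, loss = loss,
               train = train, detect = detect, if_signal = if_signal,
               fusion = fusion)
  for (sec in names(defaults)) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop(sprintf("unknown config key: %s.%s", sec, unknown[1]))
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  defaults$output_dir <- output_dir
  structure(defaults, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the configuration sections.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("preprocess", "target", "loss", "train", "detect", "if_signal",
             "fusion", "output_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop(sprintf("unknown config section: %s", unknown[1]))
  args <- y[intersect(names(y), known)]
  do.call(pipeline_config, args)
}

# Stable content hash of a configuration (or any R list).
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on one acquisition
#'
#' Preprocess (EMA background + fixed normalization), detect (keypoint
#' heatmaps, peaks, track linking), extract IF pulses in both PMT channels,
#' fuse by time, gate, and enumerate per mL. Writes `detections.csv`,
#' `if_events.csv`, `fused.csv`, `report.json` and a JSON-lines provenance
#' log into `config$output_dir` and returns the enumeration report.
#' Deterministic given inputs (no RNG is consumed).
#'
#' @param frames Raw frame array `H x W x n` (sensor counts).
#' @param traces PMT trace data frame.
#' @param manifest A [run_manifest()].
#' @param config A [pipeline_config()].
#' @param model A trained `keypoint_model` (checkpoint).
#' @param flow_speed_um_s Flow speed used for transit-time-derived gates.
#' @return The `enumeration_report`, with the fused event table in
#'   `attr(, "fused")` and the artifact directory in `attr(, "output_dir")`.
#' @export
run_pipeline <- function(frames, traces, manifest, config, model,
                         flow_speed_um_s) {
  stopifnot(inherits(manifest, "run_manifest"),
            inherits(config, "pipeline_config"),
            inherits(model, "keypoint_model"))
  t0 <- proc.time()[["elapsed"]]
  opt <- manifest$optical
  if (!inherits(opt, "optical_config")) opt <- do.call(optical_config, opt[
    c("wavelength_um", "magnification", "numerical_aperture",
      "sensor_pixel_pitch_um", "frame_rate_hz", "roi", "focal_offset_um")])
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "pipeline_log.jsonl")
  cfg_core <- unclass(config)
  cfg_core$output_dir <- NULL   # location never affects analysis identity
  chash <- config_hash(cfg_core)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage, config_hash = chash, seed = manifest$seed,
                  elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE)
  }

  pp <- config$preprocess
  norm <- normalization_spec(pp$norm_mean, pp$norm_sd)
  pre <- preprocess_stack(frames, norm, alpha = pp$alpha, warmup = pp$warmup)
  log_stage("preprocess", frames_in = dim(frames)[3],
            frames_out = dim(pre$frames)[3])

  dt <- config$detect
  det <- detect_frames(model, pre$frames,
                       threshold = dt$extraction_threshold,
                       nms_radius = dt$nms_radius_px,
                       frame_index = pre$index)
  flow_px <- flow_speed_um_s / opt$frame_rate_hz / opt$object_pixel_um
  linked <- link_tracks(det, flow_px, dt$gate_px)
  tracks <- track_table(linked)
  write_events(det, file.path(config$output_dir, "detections.csv"))
  log_stage("detect", detections = nrow(det),
            tracks = if (is.null(tracks)) 0L else nrow(tracks))

  fov_um <- opt$roi[1] * opt$object_pixel_um
  transit_s <- fov_um / flow_speed_um_s
  ifs <- config$if_signal
  pk <- trace_peaks(traces, transit_s, k_sigma = ifs$k_sigma,
                    baseline_window_mult = ifs$baseline_window_mult)
  channels <- attr(traces, "channels") %||% c("psma", "epcam")
  if_events <- match_channels(pk[[1]], pk[[2]],
                              time_tolerance = ifs$time_tolerance_mult * transit_s,
                              channels = channels)
  utils::write.csv(if_events, file.path(config$output_dir, "if_events.csv"),
                   row.names = FALSE)
  log_stage("if_signal", peaks_ch1 = nrow(pk[[1]]), peaks_ch2 = nrow(pk[[2]]),
            events = nrow(if_events))

  fu <- config$fusion
  fused <- align_events(tracks, if_events, opt$frame_rate_hz,
                        time_tolerance = fu$time_tolerance_mult * transit_s,
                        channels = channels)
  utils::write.csv(fused, file.path(config$output_dir, "fused.csv"),
                   row.names = FALSE)
  report <- enumerate_per_ml(fused, manifest$volume_ml,
                             threshold = fu$threshold,
                             sample_id = manifest$sample_id,
                             require_psma = fu$require_psma,
                             strict_greater = fu$strict_greater)
  jsonlite::write_json(c(unclass(report),
                         list(config_hash = chash, seed = manifest$seed)),
                       file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("enumerate", n_ctc = report$n_ctc,
            ctc_per_ml = report$ctc_per_ml)
  attr(report, "fused") <- fused
  attr(report, "output_dir") <- config$output_dir
  report
}
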