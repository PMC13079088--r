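#' Phase-object cell model
#'
#' Describes one population of flowing cells as seen by the holographic
#' station: a smooth phase bump of a given radius and peak optical thickness
#' (refractive-index excess times physical thickness), plus per-marker
#' fluorescence amplitude and expression probability for the PMT channels.
#' Two stock populations are provided: `"blood_like"` (small, optically
#' thin, marker-negative, emulating the residual nucleated blood background
#' after inertial enrichment) and `"ctc_like"` (larger, optically thicker,
#' predominantly PSMA-positive with partial EpCAM co-expression).
#'
#' @param class_label `"blood_like"` or `"ctc_like"`.
#' @param radius_um Cell radius in micrometres (> 0).
#' @param peak_optical_thickness_um Peak optical path excess in micrometres.
#' @param fluorescence_amplitude Named nonnegative vector, one entry per
#'   marker channel (default markers `psma`, `epcam`), in PMT signal units.
#' @param expression_probability Named vector of per-marker expression
#'   probabilities in `[0, 1]`.
#' @return Object of class `cell_model`.
#' @export
cell_model <- function(class_label = c("ctc_like", "blood_like"),
                       radius_um = NULL,
                       peak_optical_thickness_um = NULL,
                       fluorescence_amplitude = NULL,
                       expression_probability = NULL) {
  class_label <- match.arg(class_label)
  defaults <- switch(class_label,
    ctc_like = list(radius_um = 9, thickness = 0.15,
                    amp = c(psma = 1.2, epcam = 0.8),
                    expr = c(psma = 0.9, epcam = 0.37)),
    blood_like = list(radius_um = 3.5, thickness = 0.06,
                      amp = c(psma = 0, epcam = 0),
                      expr = c(psma = 0, epcam = 0)))
  radius_um <- radius_um %||% defaults$radius_um
  peak_optical_thickness_um <- peak_optical_thickness_um %||% defaults$thickness
  fluorescence_amplitude <- fluorescence_amplitude %||% defaults$amp
  expression_probability <- expression_probability %||% defaults$expr
  if (radius_um <= 0) stop("radius must be positive")
  if (any(expression_probability < 0 | expression_probability > 1))
    stop("expression probabilities must lie in [0, 1]")
  if (any(fluorescence_amplitude < 0))
    stop("fluorescence amplitudes must be nonnegative")
  structure(list(class_label = class_label,
                 radius_um = radius_um,
                 peak_optical_thickness_um = peak_optical_thickness_um,
                 fluorescence_amplitude = fluorescence_amplitude,
                 expression_probability = expression_probability),
            class = "cell_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Full description of one synthetic acquisition run: optics, flow, per-class
#' Poisson arrival rates, cell models, sensor noise, background drift, PMT
#' sampling, duration, the whole-blood volume the run is declared to
#' represent, and the master seed that fixes every random draw.
#'
#' @param optical An [optical_config()].
#' @param flow_speed_um_s Flow speed along the long ROI axis (um/s).
#' @param cell_rate_per_s Named numeric vector of mean arrival rates
#'   (events/s), one entry per element of `cell_models`.
#' @param cell_models List of [cell_model()]s, names matching
#'   `cell_rate_per_s`.
#' @param photon_budget Mean photons per pixel for unit intensity.
#' @param read_noise_sd Sensor read noise sd (counts).
#' @param background_drift List with `amplitude` (counts) and `timescale_s`;
#'   a smooth fixed pattern modulated on that timescale.
#' @param pmt_rate_hz PMT sampling rate (default 10 kHz).
#' @param pmt_noise_sd Gaussian noise sd of the PMT baseline (signal units).
#' @param pmt_baseline PMT baseline level (signal units).
#' @param duration_s Run duration in seconds.
#' @param volume_ml_equiv Whole-blood volume (mL) the run's event rates are
#'   declared to represent; used for per-mL enumeration.
#' @param seed Integer master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(optical = optical_config(),
                       flow_speed_um_s = 10000,
                       cell_rate_per_s = c(ctc_like = 2, blood_like = 10),
                       cell_models = list(ctc_like = cell_model("ctc_like"),
                                          blood_like = cell_model("blood_like")),
                       photon_budget = 2000,
                       read_noise_sd = 5,
                       background_drift = list(amplitude = 20, timescale_s = 5),
                       pmt_rate_hz = 10000,
                       pmt_noise_sd = 0.01,
                       pmt_baseline = 0.05,
                       duration_s = 1,
                       volume_ml_equiv = 1,
                       seed = 1L) {
  stopifnot(inherits(optical, "optical_config"),
            flow_speed_um_s > 0, duration_s > 0, volume_ml_equiv > 0,
            length(cell_rate_per_s) == length(cell_models),
            all(names(cell_models) == names(cell_rate_per_s)))
  fov_um <- optical$roi[1] * optical$object_pixel_um
  transit_s <- fov_um / flow_speed_um_s
  if (transit_s < 2 / optical$frame_rate_hz)
    stop("flow too fast: transit time shorter than 2 frame periods")
  structure(list(optical = optical, flow_speed_um_s = flow_speed_um_s,
                 cell_rate_per_s = cell_rate_per_s, cell_models = cell_models,
                 photon_budget = photon_budget, read_noise_sd = read_noise_sd,
                 background_drift = background_drift,
                 pmt_rate_hz = pmt_rate_hz, pmt_noise_sd = pmt_noise_sd,
                 pmt_baseline = pmt_baseline,
                 duration_s = duration_s, volume_ml_equiv = volume_ml_equiv,
                 seed = as.integer(seed),
                 fov_um = fov_um, transit_s = transit_s),
            class = "sim_config")
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Gives each simulation component its own
# reproducible sub-stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one holographic acquisition run
#'
#' Generates a stack of hologram frames, two synchronized PMT fluorescence
#' traces, the ground-truth event list, and a run manifest, all from one
#' seeded generator. Cells of each class arrive as independent Poisson
#' processes, transit the field of view along the long ROI axis at the flow
#' speed, and are rendered as defocused phase objects via angular-spectrum
#' propagation. Each expressed marker contributes a smooth unimodal pulse to
#' the corresponding PMT channel whose full width (FWHM) equals the
#' field-of-view transit time, centred at mid-transit. Frames and traces
#' share one clock starting at 0.
#'
#' @param config A [sim_config()].
#' @param session_id,sample_id,cohort Provenance recorded in the manifest.
#' @return List with elements `frames` (numeric array height x width x n,
#'   sensor counts), `traces` (data.frame `time_s`, `pmt1`, `pmt2`; channel
#'   names in `attr(,"channels")`), `truth` (data.frame of ground-truth
#'   events), `tracks` (per-frame true centroids, px), and `manifest`.
#' @export
simulate_run <- function(config, session_id = "sim-001",
                         sample_id = "sample-001",
                         cohort = c("cell_line", "healthy", "patient")) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- match.arg(cohort)
  opt <- config$optical
  if (config$duration_s < config$transit_s)
    stop("duration too short for any complete transit")
  n_frames <- max(1L, floor(config$duration_s * opt$frame_rate_hz))
  h <- opt$roi[2]; w <- opt$roi[1]
  dx <- opt$object_pixel_um
  seed <- config$seed

  # --- arrivals + marker expression (sub-streams 1 and 2) -------------------
  truth <- with_seed(seed + 1L, {
    rows <- list()
    for (ci in seq_along(config$cell_models)) {
      cls <- names(config$cell_models)[ci]
      n <- stats::rpois(1, config$cell_rate_per_s[[ci]] * config$duration_s)
      if (n == 0) next
      entry <- sort(stats::runif(n, 0, config$duration_s - config$transit_s))
      y_px <- stats::runif(n, 0.15 * h, 0.85 * h)
      rows[[cls]] <- data.frame(class_label = cls, entry_time_s = entry,
                                y_px = y_px, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(class_label = character(), entry_time_s = numeric(),
                 y_px = numeric())
  })
  markers <- names(config$cell_models[[1]]$fluorescence_amplitude)
  n_ev <- nrow(truth)
  expr <- with_seed(seed + 2L, {
    m <- matrix(FALSE, n_ev, length(markers), dimnames = list(NULL, markers))
    if (n_ev > 0) for (i in seq_len(n_ev)) {
      cm <- config$cell_models[[truth$class_label[i]]]
      m[i, ] <- stats::runif(length(markers)) < cm$expression_probability[markers]
    }
    m
  })
  if (n_ev > 0) {
    truth$event_id <- seq_len(n_ev)
    truth$pulse_center_s <- truth$entry_time_s + config$transit_s / 2
    truth$pulse_width_s <- config$transit_s
    for (m in markers) truth[[paste0(m, "_expressed")]] <- expr[, m]
  } else {
    truth$event_id <- integer(); truth$pulse_center_s <- numeric()
    truth$pulse_width_s <- numeric()
    for (m in markers) truth[[paste0(m, "_expressed")]] <- logical()
  }

  # --- per-frame true centroid tracks --------------------------------------
  track_rows <- vector("list", n_ev)
  if (n_ev > 0) for (i in seq_len(n_ev)) {
    t_fr <- (seq_len(n_frames) - 1L) / opt$frame_rate_hz
    x_px <- (t_fr - truth$entry_time_s[i]) * config$flow_speed_um_s / dx
    vis <- which(x_px >= 0 & x_px < w)
    if (length(vis))
      track_rows[[i]] <- data.frame(event_id = truth$event_id[i],
                                    frame = vis, x_px = x_px[vis],
                                    y_px = truth$y_px[i])
  }
  tracks <- if (n_ev > 0 && length(tr <- Filter(Negate(is.null), track_rows)))
    do.call(rbind, tr) else
    data.frame(event_id = integer(), frame = integer(),
               x_px = numeric(), y_px = numeric())

  # --- frames (sub-stream 3) -----------------------------------------------
  frames <- with_seed(seed + 3L, {
    bd <- config$background_drift
    # smooth fixed pattern: low-order 2-D cosine mixture, unit scale
    yy <- (seq_len(h) - 1) / h; xx <- (seq_len(w) - 1) / w
    pat <- outer(cos(2 * pi * yy + stats::runif(1, 0, 2 * pi)),
                 cos(2 * pi * xx + stats::runif(1, 0, 2 * pi)))
    ph0 <- stats::runif(1, 0, 2 * pi)
    arr <- array(0, dim = c(h, w, n_frames))
    by_frame <- split(tracks, factor(tracks$frame, levels = seq_len(n_frames)))
    for (f in seq_len(n_frames)) {
      tf <- (f - 1L) / opt$frame_rate_hz
      occ <- by_frame[[f]]
      if (!is.null(occ) && nrow(occ) > 0) {
        field <- matrix(complex(real = 1, imaginary = 0), h, w)
        for (r in seq_len(nrow(occ))) {
          cm <- config$cell_models[[
            truth$class_label[truth$event_id == occ$event_id[r]]]]
          field <- field * make_phase_object(cm, opt, shape = c(h, w),
                                             center_px = c(occ$x_px[r], occ$y_px[r]))
        }
        # band limiting at small grids is the intended behaviour here
        field <- withCallingHandlers(
          propagate_angular_spectrum(field, opt$focal_offset_um,
                                     opt$wavelength_um, dx),
          warning = function(w) {
            if (grepl("aliasing-free", conditionMessage(w)))
              invokeRestart("muffleWarning")
          })
      } else {
        field <- matrix(complex(real = 1, imaginary = 0), h, w)
      }
      bg <- if (bd$amplitude > 0)
        bd$amplitude * sin(2 * pi * tf / bd$timescale_s + ph0) * pat
      else NULL
      arr[, , f] <- render_hologram(field, config$photon_budget,
                                    config$read_noise_sd, background = bg)
    }
    arr
  })

  # --- PMT traces (sub-stream 4) -------------------------------------------
  traces <- with_seed(seed + 4L, {
    tt <- seq(0, config$duration_s, by = 1 / config$pmt_rate_hz)
    sig <- matrix(config$pmt_baseline, length(tt), length(markers))
    if (n_ev > 0) {
      sig_sd <- config$transit_s / (2 * sqrt(2 * log(2)))  # FWHM = transit
      for (i in seq_len(n_ev)) {
        cm <- config$cell_models[[truth$class_label[i]]]
        for (mi in seq_along(markers)) {
          if (!expr[i, mi]) next
          amp <- cm$fluorescence_amplitude[[markers[mi]]]
          sig[, mi] <- sig[, mi] +
            amp * exp(-(tt - truth$pulse_center_s[i])^2 / (2 * sig_sd^2))
        }
      }
    }
    sig <- sig + matrix(stats::rnorm(length(sig), 0, config$pmt_noise_sd),
                        nrow(sig))
    out <- data.frame(time_s = tt, pmt1 = sig[, 1], pmt2 = sig[, 2])
    attr(out, "channels") <- markers
    out
  })

  manifest <- run_manifest(sample_id = sample_id, cohort = cohort,
                           session_id = session_id,
                           volume_ml = config$volume_ml_equiv,
                           optical = opt, seed = seed)
  list(frames = frames, traces = traces, truth = truth, tracks = tracks,
       manifest = manifest, config = config)
}
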