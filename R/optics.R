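#' Optical configuration of the holographic imaging station
#'
#' Bundles the fixed optical constants of the in-line (Gabor) holography
#' setup: a pulsed 405 nm laser, a 10x / 0.30 NA objective, a machine-vision
#' sensor with 3.45 um pixel pitch read at 450 frames per second over a
#' 1440 x 256 px region of interest. The object-space pixel size is
#' `sensor_pixel_pitch_um / magnification` (0.345 um at defaults).
#'
#' @param wavelength_um Illumination wavelength in micrometres.
#' @param magnification Objective magnification (dimensionless).
#' @param numerical_aperture Objective NA (dimensionless).
#' @param sensor_pixel_pitch_um Physical sensor pixel pitch in micrometres.
#' @param frame_rate_hz Synchronized camera/laser frame rate (1/s).
#' @param roi Integer pair `c(width, height)` of the capture region in pixels;
#'   the long axis is the flow axis.
#' @param focal_offset_um Distance of the object plane from the sensor focal
#'   plane (defocus); this is what turns cells into fringe patterns.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength_um = 0.405,
                           magnification = 10,
                           numerical_aperture = 0.30,
                           sensor_pixel_pitch_um = 3.45,
                           frame_rate_hz = 450,
                           roi = c(1440L, 256L),
                           focal_offset_um = 30) {
  vals <- c(wavelength_um, magnification, numerical_aperture,
            sensor_pixel_pitch_um, frame_rate_hz, roi, abs(focal_offset_um))
  if (any(!is.finite(vals)) || any(vals[-length(vals)] <= 0))
    stop("all optical parameters must be positive and finite")
  roi <- as.integer(roi)
  if (length(roi) != 2L || any(roi < 32L))
    stop("roi must be two integers >= 32")
  structure(list(
    wavelength_um = wavelength_um,
    magnification = magnification,
    numerical_aperture = numerical_aperture,
    sensor_pixel_pitch_um = sensor_pixel_pitch_um,
    frame_rate_hz = frame_rate_hz,
    roi = roi,
    focal_offset_um = focal_offset_um,
    object_pixel_um = sensor_pixel_pitch_um / magnification
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0(
    "optical_config: %g nm, %gx/%0.2f NA, pitch %g um (object px %g um),\n",
    "  %g fps, ROI %d x %d px, focal offset %g um\n"),
    x$wavelength_um * 1e3, x$magnification, x$numerical_aperture,
    x$sensor_pixel_pitch_um, x$object_pixel_um, x$frame_rate_hz,
    x$roi[1], x$roi[2], x$focal_offset_um))
  invisible(x)
}

#' Render a cell as a pure phase object
#'
#' In-line holography of unstained cells is modelled by a unit-modulus
#' complex transmission field: the cell delays the wavefront in proportion to
#' its optical thickness but absorbs nothing. The phase profile is a
#' cosine-tapered bump (smooth, compactly supported) with peak phase
#' `phi_max = 2*pi*peak_optical_thickness / wavelength`, which avoids the
#' edge ringing a hard disc would produce after propagation.
#'
#' @param cell A [cell_model()].
#' @param optics An [optical_config()].
#' @param shape Integer pair `c(height, width)` of the field grid in pixels;
#'   defaults to the ROI of `optics` (height = roi[2], width = roi[1]).
#' @param center_px Numeric pair `c(x, y)`: 0-based pixel-centre coordinates
#'   of the cell centroid. Defaults to the grid centre.
#' @return Complex matrix (`height x width`) with unit modulus.
#' @export
make_phase_object <- function(cell, optics, shape = NULL, center_px = NULL) {
  stopifnot(inherits(cell, "cell_model"), inherits(optics, "optical_config"))
  dx <- optics$object_pixel_um
  if (cell$radius_um < 2 * dx)
    stop("unresolvable object: cell radius below 2 object-space pixels")
  if (is.null(shape)) shape <- c(optics$roi[2], optics$roi[1])
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (is.null(center_px)) center_px <- c((w - 1) / 2, (h - 1) / 2)
  field <- matrix(complex(real = 1, imaginary = 0), h, w)
  phi_max <- 2 * pi * cell$peak_optical_thickness_um / optics$wavelength_um
  if (phi_max == 0) return(field)
  r_px <- cell$radius_um / dx
  # only touch the bounding box of the support
  x0 <- max(0L, floor(center_px[1] - r_px)); x1 <- min(w - 1L, ceiling(center_px[1] + r_px))
  y0 <- max(0L, floor(center_px[2] - r_px)); y1 <- min(h - 1L, ceiling(center_px[2] + r_px))
  if (x0 > x1 || y0 > y1) return(field)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- outer(rep(1, length(ys)), (xs - center_px[1])^2)
  dy2 <- outer((ys - center_px[2])^2, rep(1, length(xs)))
  r <- sqrt(dx2 + dy2)
  phi <- ifelse(r <= r_px, phi_max * 0.5 * (1 + cos(pi * r / r_px)), 0)
  field[ys + 1L, xs + 1L] <- exp(1i * phi)
  field
}

#' Angular-spectrum free-space propagation
#'
#' Band-limited angular-spectrum propagation of a scalar complex field over
#' `distance_um`. Evanescent components are suppressed; when the propagation
#' distance exceeds the aliasing-free limit of the sampled grid the transfer
#' function is additionally band-limited (with a warning) so that the result
#' stays artefact-free.
#'
#' @param field Complex (or numeric) matrix.
#' @param distance_um Signed propagation distance in micrometres.
#' @param wavelength_um Wavelength in micrometres.
#' @param pixel_size_um Sampling interval of the field grid in micrometres.
#' @return Complex matrix of the same shape.
#' @export
propagate_angular_spectrum <- function(field, distance_um, wavelength_um,
                                       pixel_size_um) {
  stopifnot(is.matrix(field), is.finite(distance_um),
            wavelength_um > 0, pixel_size_um > 0)
  if (distance_um == 0) return(field + 0i)
  h <- nrow(field); w <- ncol(field)
  fy <- fft_freq(h, pixel_size_um)
  fx <- fft_freq(w, pixel_size_um)
  f2 <- outer(fy^2, rep(1, w)) + outer(rep(1, h), fx^2)
  inv_lam2 <- 1 / wavelength_um^2
  prop <- f2 < inv_lam2                      # propagating components only
  kz <- matrix(0, h, w)
  kz[prop] <- 2 * pi * sqrt(inv_lam2 - f2[prop])
  mask <- prop
  z_alias <- min(h, w) * pixel_size_um^2 / wavelength_um
  if (abs(distance_um) > z_alias) {
    warning("propagation distance exceeds aliasing-free limit; band-limiting")
    fl_y <- 1 / (wavelength_um * sqrt((2 * distance_um / (h * pixel_size_um))^2 + 1))
    fl_x <- 1 / (wavelength_um * sqrt((2 * distance_um / (w * pixel_size_um))^2 + 1))
    mask <- mask & (outer(abs(fy), rep(1, w)) <= fl_y) &
      (outer(rep(1, h), abs(fx)) <= fl_x)
  }
  tf <- exp(1i * kz * distance_um) * mask
  stats::fft(stats::fft(field) * tf, inverse = TRUE) / (h * w)
}

# FFT sample frequencies (cycles per unit), numpy fftfreq convention
fft_freq <- function(n, d) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

#' Record a hologram intensity frame
#'
#' Converts the complex field at the sensor plane into a noisy intensity
#' image: `|field|^2` scaled to the per-pixel photon budget, Poisson shot
#' noise, additive Gaussian read noise, and an optional additive background
#' (fixed pattern and/or drift), finally clipped to the sensor dynamic range.
#' Randomness is drawn from the caller's RNG stream.
#'
#' @param field Complex matrix at the sensor plane.
#' @param photon_budget Mean photon count per pixel for unit intensity (> 0).
#' @param read_noise_sd Gaussian read-noise standard deviation (counts);
#'   0 disables.
#' @param background Optional numeric matrix (same shape) added after the
#'   photon noise, e.g. a fixed pattern plus drift term.
#' @param full_well Upper clip of the sensor (counts).
#' @param shot_noise Set `FALSE` for a noise-free render.
#' @return Numeric matrix of counts in `[0, full_well]`.
#' @export
render_hologram <- function(field, photon_budget, read_noise_sd = 0,
                            background = NULL, full_well = 65535,
                            shot_noise = TRUE) {
  if (!is.numeric(photon_budget) || photon_budget <= 0)
    stop("photon_budget must be positive")
  intensity <- Mod(field)^2 * photon_budget
  img <- if (shot_noise) {
    matrix(stats::rpois(length(intensity), intensity),
           nrow(intensity), ncol(intensity))
  } else intensity
  if (read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, read_noise_sd),
                        nrow(img), ncol(img))
  if (!is.null(background)) {
    stopifnot(all(dim(background) == dim(img)))
    img <- img + background
  }
  pmin(pmax(img, 0), full_well)
}
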