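test_that("phase objects obey the optical-thickness closed form", {
  oc <- optical_config(roi = c(96L, 64L))
  # zero thickness: empty unit field
  empty <- make_phase_object(cell_model("ctc_like",
                                        peak_optical_thickness_um = 0),
                             oc, shape = c(64, 96))
  expect_equal(empty, matrix(1 + 0i, 64, 96))
  # peak phase 2*pi*t/lambda, evaluated exactly at the centroid pixel
  cm <- cell_model("ctc_like", peak_optical_thickness_um = 0.2025)
  fld <- make_phase_object(cm, oc, shape = c(64, 96), center_px = c(48, 32))
  expect_equal(Arg(fld[33, 49]), pi, tolerance = 1e-12)
  expect_equal(max(abs(Mod(fld) - 1)), 0, tolerance = 1e-12)
  # disjoint supports: combined field is the elementwise product
  a <- make_phase_object(cm, oc, shape = c(64, 96), center_px = c(20, 32))
  b <- make_phase_object(cm, oc, shape = c(64, 96), center_px = c(75, 32))
  both <- a * b
  expect_true(all(Mod(both) - 1 < 1e-12))
  expect_equal(Arg(both[33, 21]), Arg(a[33, 21]), tolerance = 1e-12)
  # sub-resolution cells are rejected
  expect_error(make_phase_object(cell_model("blood_like", radius_um = 0.5),
                                 oc, shape = c(64, 96)),
               "unresolvable")
})

test_that("angular-spectrum propagation passes identity, energy and plane-wave oracles", {
  set.seed(11)
  lam <- 0.405; dx <- 0.345
  u <- matrix(complex(real = rnorm(128 * 128), imaginary = rnorm(128 * 128)),
              128, 128)
  expect_equal(propagate_angular_spectrum(u, 0, lam, dx), u + 0i)
  # band-limit u first (remove evanescent content), then check conservation
  ubl <- propagate_angular_spectrum(propagate_angular_spectrum(u, 10, lam, dx),
                                    -10, lam, dx)
  uz <- propagate_angular_spectrum(ubl, 25, lam, dx)
  expect_equal(sum(Mod(uz)^2) / sum(Mod(ubl)^2), 1, tolerance = 1e-6)
  # forward/backward round trip
  back <- propagate_angular_spectrum(uz, -25, lam, dx)
  expect_lt(sqrt(sum(Mod(back - ubl)^2) / sum(Mod(ubl)^2)), 1e-6)
  # uniform unit field picks up the plane-wave phase 2*pi*z/lambda
  pw <- matrix(1 + 0i, 64, 64)
  pz <- propagate_angular_spectrum(pw, 12, lam, dx)
  expect_lt(max(Mod(pz - exp(2i * pi * 12 / lam))), 1e-10)
  # distances beyond the grid's aliasing-free limit warn and band-limit
  expect_warning(propagate_angular_spectrum(pw, 500, lam, dx),
                 "aliasing-free")
})

test_that("hologram rendering is unbiased and respects the photon budget", {
  pw <- matrix(1 + 0i, 24, 32)
  clean <- render_hologram(pw, photon_budget = 1500, shot_noise = FALSE)
  expect_equal(clean, matrix(1500, 24, 32))
  expect_error(render_hologram(pw, photon_budget = 0), "positive")
  # mean over many noisy renders converges to the noise-free intensity
  set.seed(21)
  oc <- optical_config(roi = c(64L, 32L))
  cm <- cell_model("ctc_like", radius_um = 4)
  fld <- propagate_angular_spectrum(
    make_phase_object(cm, oc, shape = c(32, 64)), 8, 0.405, 0.345)
  ref <- render_hologram(fld, 1000, shot_noise = FALSE)
  acc <- matrix(0, 32, 64)
  for (i in 1:1000) acc <- acc + render_hologram(fld, 1000, read_noise_sd = 3)
  expect_lt(max(abs(acc / 1000 - ref)) / mean(ref), 0.01)
})

test_that("simulated runs are deterministic and internally consistent", {
  run <- tiny_run()
  run2 <- simulate_run(run$config)
  expect_identical(run$frames, run2$frames)
  expect_identical(run$traces, run2$traces)
  expect_identical(run$truth, run2$truth)

  # every event's centroid track stays in the ROI for >= 2 consecutive frames
  h <- dim(run$frames)[1]; w <- dim(run$frames)[2]
  for (ev in unique(run$tracks$event_id)) {
    tr <- run$tracks[run$tracks$event_id == ev, ]
    expect_gte(nrow(tr), 2)
    expect_true(all(diff(tr$frame) == 1))
    expect_true(all(tr$x_px >= 0 & tr$x_px < w & tr$y_px >= 0 & tr$y_px < h))
    # along-flow advance per frame equals flow_speed / frame_rate
    step_px <- run$config$flow_speed_um_s / run$config$optical$frame_rate_hz /
      run$config$optical$object_pixel_um
    if (nrow(tr) > 1) expect_equal(diff(tr$x_px),
                                   rep(step_px, nrow(tr) - 1),
                                   tolerance = 1e-9)
  }

  # pulse bookkeeping: width equals the transit time, FOV / flow speed
  expect_equal(unique(run$truth$pulse_width_s),
               run$config$fov_um / run$config$flow_speed_um_s)
})

test_that("transit-time arithmetic matches the field-of-view closed form", {
  oc <- optical_config()  # 1440 px x 0.345 um = 496.8 um FOV
  sc <- sim_config(optical = oc, flow_speed_um_s = 10000, duration_s = 0.5)
  expect_equal(sc$fov_um, 496.8)
  expect_equal(sc$transit_s, 0.04968)
})

test_that("degenerate and invalid simulation configs are handled", {
  oc <- optical_config(roi = c(96L, 32L))
  blank <- simulate_run(sim_config(
    optical = oc, flow_speed_um_s = 3000,
    cell_rate_per_s = c(ctc_like = 0, blood_like = 0),
    duration_s = 0.2, seed = 5))
  expect_equal(nrow(blank$truth), 0)
  expect_equal(nrow(blank$tracks), 0)
  # noise-only frames: mean near photon budget, no structure beyond noise
  expect_equal(mean(blank$frames), blank$config$photon_budget,
               tolerance = 0.05)
  # too-short duration errors
  expect_error(simulate_run(sim_config(optical = oc,
                                       flow_speed_um_s = 3000,
                                       duration_s = 0.005, seed = 1)),
               "too short")
  # too-fast flow violates the two-frame transit invariant
  expect_error(sim_config(optical = oc, flow_speed_um_s = 2e5,
                          duration_s = 1), "transit")
})

test_that("event counts follow the Poisson arrival model", {
  oc <- optical_config(roi = c(64L, 32L))
  sc <- sim_config(optical = oc, flow_speed_um_s = 3000,
                   cell_rate_per_s = c(ctc_like = 40, blood_like = 0),
                   background_drift = list(amplitude = 0, timescale_s = 5),
                   duration_s = 1, seed = 17)
  run <- simulate_run(sc)
  lambda <- 40 * 1
  expect_lt(abs(nrow(run$truth) - lambda), 3 * sqrt(lambda))
  # expression frequencies stay within binomial error of the model
  n <- nrow(run$truth)
  p_hat <- mean(run$truth$psma_expressed[run$truth$class_label == "ctc_like"])
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n))
})
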