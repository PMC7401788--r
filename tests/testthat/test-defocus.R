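make_thon_sim <- function() {
  fixture("thon_sim", function() {
    g <- xrt_geometry(energy_kev = 16.7, focus_sample_x = 0.371e-3,
                      focus_sample_y = 0.40e-3,
                      sample_detector = 0.71 - 0.371e-3,
                      detector_shape = c(128L, 128L), pixel_size = 55e-6)
    d <- derive_geometry(g)
    ps <- d$demagnified_pixel / 2
    phan <- make_speckle_phantom(shape = c(512L, 512L), pitch = ps,
                                 grain = 50e-9, seed = 5,
                                 wavelength = g$wavelength)
    pup <- make_pupil_phase(g)
    pos <- scan_positions(3, step = 0.5e-6)
    sim <- simulate_scan(phan, pup, pos, flux = 3000, mode = "wave",
                         noise = "poisson", seed = 1)
    list(g = g, d = d, sim = sim)
  })
}

test_that("cumulative power spectrum is linear and obeys Parseval", {
  g <- small_geometry(n = 32L)
  set.seed(6)
  frame <- matrix(rpois(1024, 900), 32, 32)
  imgs <- array(rep(frame, 4), c(32, 32, 4))
  scan <- scan_data(imgs, matrix(0, 4, 2), g)
  W <- matrix(900, 32, 32)
  S4 <- cumulative_power_spectrum(scan, W)
  S1 <- cumulative_power_spectrum(
    scan_data(array(frame, c(32, 32, 1)), matrix(0, 1, 2), g), W)
  expect_equal(S4, 4 * S1, tolerance = 1e-12, ignore_attr = TRUE)
  # Parseval: sum of spectrum = npix * sum of squared contrast (DC removed)
  r <- frame / 900 - 1
  expect_equal(sum(S1), 1024 * (sum(r^2) - sum(r)^2 / 1024),
               tolerance = 1e-9)
})

test_that("Thon rings give defocus and astigmatism within tolerance", {
  ts <- make_thon_sim()
  sp <- cumulative_power_spectrum(ts$sim$scan)
  est <- fit_thon_rings(sp, ts$g$wavelength, ts$g$sample_detector,
                        z1_range = c(0.2e-3, 0.8e-3))
  expect_equal(est$status, "ok")
  expect_equal(est$zbar_x / ts$d$effective_defocus_x, 1, tolerance = 0.05)
  expect_equal(est$zbar_y / ts$d$effective_defocus_y, 1, tolerance = 0.05)
  # astigmatism sign: z1y > z1x in this scan
  expect_gt(est$z1y, est$z1x)
})

test_that("isotropic scans fit with negligible spurious astigmatism", {
  ts <- make_thon_sim()
  g2 <- xrt_geometry(energy_kev = 16.7, focus_sample_x = 0.385e-3,
                     focus_sample_y = 0.385e-3,
                     sample_detector = 0.71 - 0.385e-3,
                     detector_shape = c(128L, 128L), pixel_size = 55e-6)
  d2 <- derive_geometry(g2)
  ps <- d2$demagnified_pixel / 2
  phan <- make_speckle_phantom(shape = c(512L, 512L), pitch = ps,
                               grain = 50e-9, seed = 5,
                               wavelength = g2$wavelength)
  pup <- make_pupil_phase(g2)
  sim <- simulate_scan(phan, pup, scan_positions(3, step = 0.5e-6),
                       flux = 3000, mode = "wave", noise = "poisson",
                       seed = 2)
  est <- fit_thon_rings(cumulative_power_spectrum(sim$scan), g2$wavelength,
                        g2$sample_detector, z1_range = c(0.2e-3, 0.8e-3))
  expect_equal(est$status, "ok")
  expect_lt(abs(est$zbar_x - est$zbar_y) /
              mean(c(est$zbar_x, est$zbar_y)), 0.02)
})

test_that("ring-free spectra fail gracefully", {
  flat <- matrix(1, 128, 128)
  attr(flat, "pixel_size") <- 55e-6
  est <- fit_thon_rings(flat, energy_to_wavelength(16.7), 0.71,
                        z1_range = c(0.2e-3, 0.8e-3))
  expect_equal(est$status, "failed")
  expect_true(is.na(est$z1x))
})

test_that("SSE defocus scan locates the focus within one grid step", {
  g <- small_geometry(n = 128L)
  d <- derive_geometry(g)
  phan <- make_speckle_phantom(shape = c(448L, 448L),
                               pitch = d$demagnified_pixel,
                               grain = 80e-9, seed = 6,
                               wavelength = g$wavelength)
  pup <- make_pupil_phase(g)
  sim <- simulate_scan(phan, pup, scan_positions(5, step = 0.8e-6),
                       flux = 2000, mode = "geometric", noise = "poisson",
                       seed = 3)
  cand <- seq(0.31e-3, 0.43e-3, length.out = 11)
  est <- scan_defocus_sse(sim$scan, cand)
  expect_equal(est$status, "ok")
  expect_lte(abs(est$z1x - 0.371e-3), diff(cand)[1] + 1e-12)
  # curve is convex around the truth on noiseless-ish data
  k <- which(est$candidates == est$z1x)
  expect_true(all(diff(est$sse[1:k]) < 0))
  expect_true(all(diff(est$sse[k:length(est$sse)]) > 0))
  # single candidate passes through
  est1 <- scan_defocus_sse(sim$scan, 0.371e-3)
  expect_equal(est1$z1x, 0.371e-3)
  # monotone curve warns about the range
  expect_warning(scan_defocus_sse(sim$scan, seq(0.42e-3, 0.55e-3, length.out = 5)),
                 "range")
})
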