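# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

rms_ <- function(x) sqrt(mean(x^2, na.rm = TRUE))

# Siemens-like geometry scaled to a 64 px detector
small_geometry <- function(z1x = 0.371e-3, z1y = z1x, n = 64L) {
  xrt_geometry(energy_kev = 16.7, focus_sample_x = z1x, focus_sample_y = z1y,
               sample_detector = 0.71 - z1x, detector_shape = c(n, n),
               pixel_size = 55e-6)
}

# small speckle scan used by several reconstruction tests
speckle_scan_fixture <- function() {
  fixture("speckle_scan", function() {
    g <- small_geometry()
    d <- derive_geometry(g)
    ps <- d$demagnified_pixel / 2
    fov <- 64 * d$demagnified_pixel
    phan <- make_speckle_phantom(shape = c(320L, 320L), pitch = ps,
                                 grain = 6 * ps, seed = 11,
                                 wavelength = g$wavelength)
    pup <- make_pupil_phase(g, residual_coeffs = data.frame(
      kx = c(3, 0), ky = c(0, 3), coeff = c(4, -3)))
    pos <- scan_positions(5, step = fov / 5)
    sim <- simulate_scan(phan, pup, pos, flux = 2000, mode = "geometric",
                         noise = "none")
    list(g = g, d = d, phan = phan, pup = pup, pos = pos, sim = sim)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small metrology scan + reconstruction, parameterized by geometry/flux
met_case <- function(z1, flux, seed, noise = "poisson",
                     n_side = 5, absorber = FALSE) {
  g <- small_geometry(z1x = z1)
  d <- derive_geometry(g)
  ps <- d$demagnified_pixel / 2
  fov <- 64 * d$demagnified_pixel
  phan <- make_speckle_phantom(shape = c(320L, 320L), pitch = ps,
                               grain = 6 * ps, seed = 11,
                               mean_thickness = if (absorber) 1.5e-6 else 0.5e-6,
                               rms_thickness = if (absorber) 0.5e-6 else 0.25e-6,
                               wavelength = g$wavelength)
  if (absorber)
    phan <- phantom_from_thickness(phan$thickness, ps, delta = 0,
                                   beta = 7e-6, wavelength = g$wavelength)
  pup <- make_pupil_phase(g)
  pos <- scan_positions(n_side, step = 1.3 * fov / n_side)
  sim <- simulate_scan(phan, pup, pos, flux = flux, mode = "geometric",
                       noise = noise, seed = seed)
  res <- suppressWarnings(run_pxst(sim$scan, n_iter = 2, search_radius = 3))
  list(g = g, d = d, sim = sim, res = res)
}
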