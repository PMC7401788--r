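test_that("Siemens star geometry: duty cycle, cuts and limits", {
  ph <- make_siemens_star(shape = c(384L, 384L), pitch = 15e-9,
                          diameter = 5e-6)
  expect_s3_class(ph, "sample_phantom")
  expect_true(all(Mod(ph$transmission) <= 1 + 1e-12))
  # 50% angular duty cycle inside the spoke annulus, away from the cuts
  n <- 384
  x <- (seq_len(n) - (n + 1) / 2) * 15e-9
  R <- sqrt(outer(x^2, rep(1, n)) + outer(rep(1, n), x^2))
  annulus <- R > 1.3e-6 & R < 1.9e-6
  frac <- mean(ph$thickness[annulus] > 0)
  expect_equal(frac, 0.5, tolerance = 0.03)
  # annular cuts present: zero-thickness ring at the cut radius
  cutring <- abs(R - 0.5 * 2.5e-6) < 0.01 * 2.5e-6
  expect_lt(mean(ph$thickness[cutring] > 0), 0.05)
  # empty-beam limit
  ph0 <- make_siemens_star(shape = c(64L, 64L), pitch = 40e-9,
                           thickness_range = c(0, 0))
  expect_equal(unname(Mod(ph0$transmission)), matrix(1, 64, 64),
               tolerance = 1e-12)
  # coarse grid triggers the documented low-pass warning
  expect_warning(make_siemens_star(shape = c(64L, 64L), pitch = 100e-9,
                                   tip_width = 100e-9), "low-pass")
})

test_that("single-material transmission is consistent with thickness", {
  ph <- make_siemens_star(shape = c(96L, 96L), pitch = 40e-9)
  lam <- ph$wavelength
  k <- 2 * pi / lam
  expected <- exp(-k * (ph$beta + 1i * ph$delta) * ph$thickness)
  expect_equal(ph$transmission, expected, tolerance = 1e-12)
})

test_that("hexagonal phantom has first-order peaks at the reciprocal lattice", {
  a <- 601e-9
  ph <- make_hex_lattice_phantom(shape = c(256L, 256L), pitch = 30e-9,
                                 lattice_constant = a,
                                 envelope_strength = 0)
  S <- Mod(stats::fft(ph$thickness - mean(ph$thickness)))^2
  fy <- pxst:::freq_vector(256, 30e-9)
  q <- sqrt(outer(fy^2, rep(1, 256)) + outer(rep(1, 256), fy^2))
  q_hex <- 2 / (sqrt(3) * a)
  ring <- q > 0.9 * q_hex & q < 1.1 * q_hex
  inner <- q > 0.3 * q_hex & q < 0.7 * q_hex
  expect_gt(max(S[ring]), 50 * max(S[inner]))
  # zero motif -> uniform transmission
  ph0 <- make_hex_lattice_phantom(shape = c(64L, 64L), pitch = 30e-9,
                                  motif_thickness = 0)
  expect_equal(sd(Mod(ph0$transmission)), 0, tolerance = 1e-15)
  # translation by one lattice vector reproduces the pattern (periodic case)
  ph1 <- make_hex_lattice_phantom(shape = c(128L, 128L), pitch = 30e-9,
                                  lattice_constant = a,
                                  envelope_strength = 0)
  ph2 <- make_hex_lattice_phantom(shape = c(128L, 128L), pitch = 30e-9,
                                  lattice_constant = a,
                                  envelope_strength = 0,
                                  offset = c(0, a))
  inner_px <- 30:98
  expect_lt(rms_(ph1$thickness[inner_px, inner_px] -
                   ph2$thickness[inner_px, inner_px]),
            0.02 * rms_(ph1$thickness))
})

test_that("pupil phase matches the astigmatic quadratic plus residuals", {
  g <- small_geometry(z1x = 0.371e-3, z1y = 0.40e-3)
  pup <- make_pupil_phase(g)
  # pure quadratic: removing low orders leaves nothing
  fit <- remove_low_orders(pup$phase, pixel_size = g$pixel_size)
  expect_lt(rms_(fit$residual), 1e-9 * rms_(pup$phase))
  # distinct x/y curvatures
  lam <- g$wavelength; z <- g$sample_detector
  expect_equal(fit$coefficients[["x2"]], pi / (lam * (0.371e-3 + z)),
               tolerance = 1e-6)
  expect_equal(fit$coefficients[["y2"]], pi / (lam * (0.40e-3 + z)),
               tolerance = 1e-6)
  # ray angle at the support edge equals the geometric ray angle
  th <- ray_angles(pup$grad_y, pup$grad_x, lam)
  co <- pxst:::det_coords(g)
  expect_equal(th$tx[1, 64], co$x[64] / (0.371e-3 + z), tolerance = 1e-10)
  # analytic residual gradients match numeric differentiation
  rc <- data.frame(kx = c(3, 1), ky = c(0, 2), coeff = c(5, -2))
  pup2 <- make_pupil_phase(g, residual_coeffs = rc)
  num <- pxst:::centre_gradient(pup2$phase, pitch = g$pixel_size)
  inner <- 5:60
  expect_equal(pup2$grad_x[inner, inner], num$gx[inner, inner],
               tolerance = 1e-3)
})

test_that("angular-spectrum propagation: identity, energy, Gaussian, Talbot", {
  n <- 256; pitch <- 1e-6; lam <- 1e-10
  x <- (seq_len(n) - (n + 1) / 2) * pitch
  w0 <- 8e-6
  field <- outer(exp(-x^2 / w0^2), exp(-x^2 / w0^2))
  expect_identical(propagate_angular_spectrum(field, 0, lam, pitch), field)
  d <- 0.3 * n * pitch^2 / lam
  fp <- propagate_angular_spectrum(field, d, lam, pitch)
  expect_equal(sum(Mod(fp)^2) / sum(Mod(field)^2), 1, tolerance = 1e-10)
  I <- Mod(fp[n / 2, ])^2
  w_meas <- sqrt(4 * sum(x^2 * I) / sum(I))
  w_theory <- w0 * sqrt(1 + (lam * d / (pi * w0^2))^2)
  expect_equal(w_meas / w_theory, 1, tolerance = 5e-3)
  # Talbot self-imaging of a binary grating
  p_g <- 8 * pitch
  grating <- matrix(rep(as.numeric((seq_len(n) %% 8) < 4), n), n,
                    byrow = TRUE)
  zt <- 2 * p_g^2 / lam
  ft <- propagate_angular_spectrum(grating + 0i, zt, lam, pitch)
  It <- Mod(ft)^2
  expect_gt(cor(as.vector(It[, 32:224]), as.vector(grating[, 32:224])), 0.99)
  # aliasing guard names the bound
  expect_error(propagate_angular_spectrum(field, 10 * n * pitch^2 / lam,
                                          lam, pitch), "aliasing")
})

test_that("simulated scans reproduce the white field and Poisson statistics", {
  fx <- speckle_scan_fixture()
  g <- fx$g
  # empty beam: every frame equals the white field exactly
  empty <- phantom_from_thickness(matrix(0, 160, 160),
                                  fx$d$demagnified_pixel / 2,
                                  delta = 1e-6, beta = 1e-8,
                                  wavelength = g$wavelength)
  sim0 <- simulate_scan(empty, fx$pup, fx$pos[1:4, ], flux = 1234,
                        mode = "geometric", noise = "none")
  for (n in 1:4)
    expect_equal(sim0$scan$images[, , n], sim0$truth$W, tolerance = 1e-12)
  # geometric forward model is self-consistent by construction
  sim <- fx$sim
  tr <- sim$truth$reference
  cov <- matrix(1L, nrow(tr$image), ncol(tr$image))
  n_test <- 3
  for (n in seq_len(n_test)) {
    ry <- (sim$truth$u[, , 1] - fx$pos[n, 1] - tr$origin[1]) / tr$pitch
    rx <- (sim$truth$u[, , 2] - fx$pos[n, 2] - tr$origin[2]) / tr$pitch
    pred <- sim$truth$W *
      pxst:::cpp_bilinear_lookup(tr$image, cov, ry, rx, 1)
    expect_equal(as.vector(sim$scan$images[, , n]), as.vector(pred),
                 tolerance = 1e-12)
  }
  # Poisson noise: mean over frames approaches the expectation, seeded runs
  # are bit-identical
  simp1 <- simulate_scan(empty, fx$pup, fx$pos, flux = 500,
                         mode = "geometric", noise = "poisson", seed = 7)
  simp2 <- simulate_scan(empty, fx$pup, fx$pos, flux = 500,
                         mode = "geometric", noise = "poisson", seed = 7)
  expect_identical(simp1$scan$images, simp2$scan$images)
  m <- apply(simp1$scan$images, c(1, 2), mean)
  relerr <- rms_((m - simp1$truth$W) / simp1$truth$W)
  expect_lt(relerr, 3 / sqrt(25 * 500))
})

test_that("wave and geometric modes agree for small NA, resolved features", {
  g <- small_geometry()
  d <- derive_geometry(g)
  ps <- d$demagnified_pixel / 2
  phan <- make_speckle_phantom(shape = c(320L, 320L), pitch = ps,
                               grain = 10 * ps, seed = 21,
                               wavelength = g$wavelength)
  pup <- make_pupil_phase(g)
  pos <- scan_positions(2, step = 4e-7)
  gsim <- simulate_scan(phan, pup, pos, flux = 1000, mode = "geometric",
                        noise = "none", ref_pitch = ps)
  wsim <- simulate_scan(phan, pup, pos, flux = 1000, mode = "wave",
                        noise = "none")
  inner <- 9:56   # periodic Fourier shifts wrap at the frame borders
  for (n in 1:4) {
    a <- (gsim$scan$images[, , n] / gsim$truth$W)[inner, inner]
    b <- (wsim$scan$images[, , n] / wsim$truth$W)[inner, inner]
    expect_gt(cor(as.vector(a), as.vector(b)), 0.98)
  }
})
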