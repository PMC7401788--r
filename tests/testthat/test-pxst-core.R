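test_that("median white field ignores occasional occlusion exactly", {
  g <- small_geometry(n = 16L)
  set.seed(5)
  W_true <- matrix(runif(256, 500, 1500), 16, 16)
  N <- 11
  imgs <- array(rep(W_true, N), c(16, 16, N))
  # occlude each pixel in < 50% of frames
  for (i in 1:16) for (j in 1:16) {
    k <- sample(N, 4)
    imgs[i, j, k] <- imgs[i, j, k] * runif(4, 0.1, 0.9)
  }
  scan <- scan_data(imgs, matrix(0, N, 2), g)
  W <- estimate_white_field(scan)
  expect_equal(W, W_true, tolerance = 1e-12)
  # masked pixels propagate as NA
  mask <- matrix(TRUE, 16, 16); mask[3, 4] <- FALSE
  scan2 <- scan_data(imgs, matrix(0, N, 2), g, mask = mask)
  expect_true(is.na(estimate_white_field(scan2)[3, 4]))
})

test_that("initial pixel map is the per-axis magnification map", {
  g <- small_geometry(z1x = 0.371e-3, z1y = 0.45e-3)
  u <- initial_pixel_map(g)
  co <- pxst:::det_coords(g)
  z <- g$sample_detector
  expect_equal(u[1, , 2], co$x * 0.371e-3 / (0.371e-3 + z))
  expect_equal(u[, 1, 1], co$y * 0.45e-3 / (0.45e-3 + z))
  # isotropic case: u = x / M
  g2 <- small_geometry()
  M <- derive_geometry(g2)$M
  u2 <- initial_pixel_map(g2)
  expect_equal(u2[1, , 2], pxst:::det_coords(g2)$x / M, tolerance = 1e-12)
})

test_that("reference synthesis reproduces the hologram and its coverage", {
  fx <- speckle_scan_fixture()
  sim <- fx$sim
  W <- sim$truth$W
  ref <- build_reference(sim$scan, W, sim$truth$u)
  expect_s3_class(ref, "reference_image")
  # compare against the simulator's ground-truth hologram on shared support
  tr <- sim$truth$reference
  mr <- nrow(ref$image); mc <- ncol(ref$image)
  ry <- (ref$origin[1] + (seq_len(mr) - 1) * ref$pitch - tr$origin[1]) /
    tr$pitch
  rx <- (ref$origin[2] + (seq_len(mc) - 1) * ref$pitch - tr$origin[2]) /
    tr$pitch
  cov <- matrix(1L, nrow(tr$image), ncol(tr$image))
  tt <- pxst:::cpp_bilinear_lookup(tr$image, cov,
                                   matrix(ry, mr, mc),
                                   matrix(rx, mr, mc, byrow = TRUE), NA)
  dim(tt) <- c(mr, mc)
  ok <- is.finite(ref$image) & is.finite(tt) &
    ref$coverage > stats::quantile(ref$coverage, 0.5)
  expect_lt(rms_(ref$image[ok] - tt[ok]) / mean(tt[ok]), 0.02)
  # counting oracle: unit splat weights sum to the number of samples
  g <- small_geometry(n = 8L)
  one <- array(1, c(8, 8, 2))
  scan1 <- scan_data(one, matrix(0, 2, 2), g)
  W1 <- matrix(1, 8, 8)
  u1 <- initial_pixel_map(g)
  r1 <- build_reference(scan1, W1, u1)
  expect_equal(sum(r1$count), 2 * 64, tolerance = 1e-9)
  expect_error(build_reference(scan1, matrix(0, 8, 8), u1), "coverage")
})

test_that("pixel-map update is a fixed point on self-consistent data", {
  fx <- speckle_scan_fixture()
  sim <- fx$sim
  W <- sim$truth$W
  d <- fx$d
  ref <- build_reference(sim$scan, W, sim$truth$u,
                         pitch = d$demagnified_pixel / 2)
  u1 <- update_pixel_map(sim$scan, W, ref, sim$truth$u, search_radius = 6L)
  du <- attr(u1, "du") * ref$pitch / d$demagnified_pixel
  fl <- attr(u1, "flagged")
  expect_lt(rms_(du[, , 1][!fl]), 0.05)
  expect_lt(rms_(du[, , 2][!fl]), 0.05)
})

test_that("a known shift of the reference pattern is recovered", {
  # single Gaussian-blob reference, one frame shifted by a known sub-pixel
  # amount; brute-force construction is its own oracle
  g <- small_geometry(n = 32L)
  d <- derive_geometry(g)
  dr <- d$demagnified_pixel
  mr <- 120
  yy <- (seq_len(mr) - 1) * dr - 60 * dr
  Iref <- matrix(1, mr, mr)
  set.seed(8)
  for (k in 1:25) {
    cy <- runif(1, yy[15], yy[105]); cx <- runif(1, yy[15], yy[105])
    s <- dr * runif(1, 1.5, 3)
    Iref <- Iref + 0.8 * outer(exp(-(yy - cy)^2 / (2 * s^2)),
                               exp(-(yy - cx)^2 / (2 * s^2)))
  }
  origin <- c(yy[1], yy[1])
  cov <- matrix(1L, mr, mr)
  u <- initial_pixel_map(g)
  shift_px <- 3.40
  N <- 5
  imgs <- array(0, c(32, 32, N))
  W <- matrix(800, 32, 32)
  pos <- cbind(rep(0, N), c(0, 0, 0, 0, shift_px * dr))
  for (n in 1:N) {
    ry <- (u[, , 1] - pos[n, 1] - origin[1]) / dr
    rx <- (u[, , 2] - pos[n, 2] - origin[2]) / dr
    imgs[, , n] <- W * pxst:::cpp_bilinear_lookup(Iref, cov, ry, rx, 1)
  }
  # pretend frame 5 sat at 0: its true offset (3.40 px) must be recovered
  scan <- scan_data(imgs, cbind(rep(0, N), rep(0, N)), g)
  ref <- list(image = Iref, coverage = matrix(1, mr, mr), pitch = dr,
              origin = origin)
  class(ref) <- "reference_image"
  tr <- update_translations(scan, W, ref, u, search_radius = 6L)
  # zero-mean gauge spreads the correction; frame-to-frame difference is
  # gauge-free
  rec <- (tr[5, 2] - mean(tr[1:4, 2])) / dr
  expect_equal(rec, shift_px, tolerance = 0.1)
})

test_that("translation refinement recovers injected offsets and drift", {
  fx <- speckle_scan_fixture()
  sim <- fx$sim
  W <- sim$truth$W
  d <- fx$d
  ref <- build_reference(sim$scan, W, sim$truth$u,
                         pitch = d$demagnified_pixel / 2)
  # correct positions: corrections stay tiny
  tr0 <- update_translations(sim$scan, W, ref, sim$truth$u,
                             search_radius = 8L)
  expect_lt(max(abs(tr0 - sim$scan$translations)) / d$demagnified_pixel, 0.05)
  # one frame reported 2 px off in y
  scan2 <- sim$scan
  err <- 2 * d$demagnified_pixel
  scan2$translations[7, 1] <- scan2$translations[7, 1] + err
  tr2 <- update_translations(scan2, W, ref, sim$truth$u, search_radius = 8L)
  # up to a common (gauge) constant, refined translations match the truth
  resid <- (tr2[, 1] - sim$scan$translations[, 1]) / d$demagnified_pixel
  expect_lt(sd(resid), 0.2)
})

test_that("error map decompositions are exact and vanish on perfect data", {
  fx <- speckle_scan_fixture()
  sim <- fx$sim
  W <- sim$truth$W
  tr <- sim$truth$reference
  ref <- list(image = tr$image,
              coverage = matrix(1, nrow(tr$image), ncol(tr$image)),
              pitch = tr$pitch, origin = tr$origin)
  class(ref) <- "reference_image"
  e <- compute_error_map(sim$scan, W, ref, sim$truth$u)
  # the simulator used this exact reference: SSE is numerically zero
  expect_lt(e$total, 1e-10 * sum(sim$scan$images^2))
  expect_equal(sum(e$frame_sse), e$total, tolerance = 1e-9)
  expect_equal(sum(e$pixel_sse), e$total, tolerance = 1e-9)
  # Poisson data: total SSE approaches the summed expected counts
  empty <- phantom_from_thickness(matrix(0, 160, 160), tr$pitch / 2,
                                  delta = 1e-6, beta = 1e-8,
                                  wavelength = fx$g$wavelength)
  simp <- simulate_scan(empty, fx$pup, fx$pos, flux = 400,
                        mode = "geometric", noise = "poisson", seed = 3)
  refp <- list(image = matrix(1, 50, 50),
               coverage = matrix(1, 50, 50), pitch = 1e-6,
               origin = c(-25e-6, -25e-6))
  class(refp) <- "reference_image"
  ep <- compute_error_map(simp$scan, simp$truth$W, refp, sim$truth$u * 0)
  expected_counts <- sum(simp$truth$W) * dim(simp$scan$images)[3]
  expect_equal(ep$total / expected_counts, 1, tolerance = 0.05)
})

test_that("full reconstruction converges with non-increasing error", {
  fx <- speckle_scan_fixture()
  res <- run_pxst(fx$sim$scan, n_iter = 3, search_radius = 4)
  expect_true(res$converged)
  expect_true(all(diff(res$sse_mean) < 1e-3 * res$sse_mean[-length(res$sse_mean)]))
  expect_lt(res$sse_mean[length(res$sse_mean)], res$sse_mean[1])
  # gauge invariance: shifting all translations and the map together leaves
  # the predicted images (hence the SSE) unchanged
  shift <- c(3.2e-9, -1.7e-9)
  sc2 <- fx$sim$scan
  sc2$translations <- sweep(sc2$translations, 2, -shift)
  u2 <- res$pixel_map
  u2[, , 1] <- u2[, , 1] + shift[1]
  u2[, , 2] <- u2[, , 2] + shift[2]
  W <- res$white_field
  e1 <- compute_error_map(fx$sim$scan, W, res$reference, res$pixel_map)
  e2 <- compute_error_map(sc2, W, res$reference, u2)
  expect_equal(e2$total, e1$total, tolerance = 1e-6)
})
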