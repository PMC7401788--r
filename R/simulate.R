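#' Scan data container
#'
#' Bundles the recorded frames, sample translations, good-pixel mask and
#' geometry of a projection-imaging scan.
#'
#' @param images numeric array (rows, cols, N) of photon counts.
#' @param translations N x 2 matrix of sample translations (y, x) in metres
#'   (sample plane).
#' @param geometry an [xrt_geometry()].
#' @param mask logical (rows, cols) good-pixel mask; default all good.
#' @return object of class `scan_data`.
#' @export
scan_data <- function(images, translations, geometry, mask = NULL) {
  stopifnot(length(dim(images)) == 3)
  nr <- dim(images)[1]; nc <- dim(images)[2]; N <- dim(images)[3]
  translations <- as.matrix(translations)
  stopifnot(nrow(translations) == N, ncol(translations) == 2,
            all(is.finite(translations)), N >= 1)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  stopifnot(all(dim(mask) == c(nr, nc)))
  bad <- !is.finite(images) | images < 0
  if (any(bad)) {
    images[bad] <- 0
    mask <- mask & apply(is.finite(images), c(1, 2), all)
  }
  structure(list(images = images, translations = translations,
                 mask = mask, geometry = geometry),
            class = "scan_data")
}

#' @export
print.scan_data <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<scan_data> %d frames of %d x %d px, %d masked pixels\n",
              d[3], d[1], d[2], sum(!x$mask)))
  invisible(x)
}

#' Regular-grid scan positions
#'
#' @param n_side frames per side (total n_side^2) or a length-2 vector.
#' @param step step size (m).
#' @param jitter_sd Gaussian jitter standard deviation (m), to exercise
#'   translation refinement.
#' @param seed RNG seed for the jitter.
#' @return N x 2 matrix of (y, x) translations in metres, centred on zero.
#' @export
scan_positions <- function(n_side, step, jitter_sd = 0, seed = NULL) {
  if (length(n_side) == 1) n_side <- c(n_side, n_side)
  gy <- (seq_len(n_side[1]) - 1 - (n_side[1] - 1) / 2) * step
  gx <- (seq_len(n_side[2]) - 1 - (n_side[2] - 1) / 2) * step
  pos <- as.matrix(expand.grid(y = gy, x = gx))
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pos <- pos + matrix(rnorm(length(pos), 0, jitter_sd), nrow(pos))
  }
  pos
}

# smooth default illumination envelope on normalized detector coords
default_envelope <- function(nr, nc) {
  Yn <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  Xn <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  env <- 1 - 0.12 * Xn^2 - 0.08 * Yn^2 + 0.05 * Xn * Yn + 0.04 * Yn
  env / max(env)
}

# sub-pixel periodic shift via the Fourier shift theorem
fourier_shift <- function(field, dy_px, dx_px) {
  if (dy_px == 0 && dx_px == 0) return(field)
  fy <- freq_vector(nrow(field), 1)
  fx <- freq_vector(ncol(field), 1)
  H <- exp(-2i * pi * (outer(fy * dy_px, rep(1, ncol(field))) +
                       outer(rep(1, nrow(field)), fx * dx_px)))
  stats::fft(stats::fft(field) * H, inverse = TRUE) / length(field)
}

# residual (non-quadratic) pupil phase evaluated at demagnified sample-plane
# coordinates ys, xs (metres)
residual_phase_demag <- function(pupil, ys, xs) {
  g <- pupil$geometry
  co <- det_coords(g)
  yn <- max(abs(co$y)); xn <- max(abs(co$x))
  d <- derive_geometry(g)
  out <- matrix(0, length(ys), length(xs))
  rc <- pupil$residual_coeffs
  if (is.null(rc) || nrow(rc) == 0) return(out)
  Yn <- matrix(d$M_y * ys / yn, length(ys), length(xs))
  Xn <- matrix(d$M_x * xs / xn, length(ys), length(xs), byrow = TRUE)
  for (r in seq_len(nrow(rc)))
    out <- out + rc$coeff[r] * Xn^rc$kx[r] * Yn^rc$ky[r]
  out
}

#' Simulate a projection-imaging scan
#'
#' Generates N shadow images of a phantom under divergent aberrated
#' illumination, together with the ground truth used by tests: the white
#' field, the pixel map, the undistorted reference hologram and the pupil
#' phase.
#'
#' Two forward models are available. `"geometric"` evaluates the speckle
#' tracking forward model exactly: each frame is the white field times the
#' reference hologram looked up through the true pixel map. `"wave"`
#' propagates each translated exit wave by the per-axis effective defocus
#' (Fresnel scaling theorem) with the residual pupil phase applied on the
#' demagnified grid, so diffraction effects beyond the geometric model are
#' present.
#'
#' @param phantom a `sample_phantom`.
#' @param pupil a `pupil_phase` (its geometry is used).
#' @param positions N x 2 matrix of sample translations (y, x) in metres.
#' @param flux expected photons per pixel at the envelope maximum.
#' @param mode `"geometric"` or `"wave"`.
#' @param noise `"poisson"` or `"none"`.
#' @param seed RNG seed (Poisson noise); fixed seed gives bit-identical scans.
#' @param envelope optional white-field envelope matrix (detector shape,
#'   max 1); default a smooth built-in profile.
#' @param ref_pitch pitch (m) to which the ground-truth hologram is
#'   band-limited and resampled in geometric mode; defaults to the
#'   demagnified detector pixel, so the generated data are exactly
#'   representable by the reconstruction's reference grid.
#' @return a list of class `pxst_sim` with elements `scan` ([scan_data()]) and
#'   `truth` (list: `W`, `u` (rows, cols, 2 metres), `reference` (image,
#'   pitch, origin), `phase`, `grad_y`, `grad_x`).
#' @export
simulate_scan <- function(phantom, pupil, positions, flux = 1e3,
                          mode = c("geometric", "wave"),
                          noise = c("poisson", "none"),
                          seed = NULL, envelope = NULL, ref_pitch = NULL) {
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  g <- pupil$geometry
  d <- derive_geometry(g)
  lam <- g$wavelength
  z <- g$sample_detector
  nr <- g$detector_shape[1]; nc <- g$detector_shape[2]
  positions <- as.matrix(positions)
  N <- nrow(positions)

  if (is.null(envelope)) envelope <- default_envelope(nr, nc)
  W <- flux * envelope * ifelse(pupil$support, 1, 0)

  co <- det_coords(g)
  Y <- matrix(co$y, nr, nc)
  X <- matrix(co$x, nr, nc, byrow = TRUE)
  u <- array(0, c(nr, nc, 2))
  u[, , 1] <- Y - (lam * z / (2 * pi)) * pupil$grad_y
  u[, , 2] <- X - (lam * z / (2 * pi)) * pupil$grad_x

  # sample-plane grid of the phantom
  ps <- phantom$pitch
  nrs <- nrow(phantom$thickness); ncs <- ncol(phantom$thickness)
  ys <- (seq_len(nrs) - 1 - (nrs - 1) / 2) * ps
  xs <- (seq_len(ncs) - 1 - (ncs - 1) / 2) * ps
  origin <- c(ys[1], xs[1])

  # undistorted reference hologram: plane-wave Fresnel propagation of the
  # exit wave by the per-axis effective defocus
  holo_fine <- Mod(fresnel_propagate_aniso(
    phantom$transmission, d$effective_defocus_y, d$effective_defocus_x,
    lam, ps))^2
  cov_fine <- matrix(1L, nrs, ncs)

  # band-limit and resample the hologram to the reconstruction pitch
  # (default: the demagnified detector pixel), so the geometric forward
  # model is interpolation-exact for the tracking engine
  if (is.null(ref_pitch)) ref_pitch <- d$demagnified_pixel
  Iref_true <- holo_fine
  if (ref_pitch >= ps) {
    fys <- freq_vector(nrs, ps); fxs <- freq_vector(ncs, ps)
    qn <- sqrt(outer(fys^2, rep(1, ncs)) + outer(rep(1, nrs), fxs^2)) *
      (2 * ref_pitch)                      # 1 at the target Nyquist
    H <- 0.5 * (1 + cos(pi * pmin(pmax((qn - 0.5) / 0.35, 0), 1)))
    sm <- Re(stats::fft(stats::fft(holo_fine) * H, inverse = TRUE)) /
      (nrs * ncs)
    if (ref_pitch > ps) {
      nrr <- floor((nrs - 1) * ps / ref_pitch) + 1
      ncr <- floor((ncs - 1) * ps / ref_pitch) + 1
      yr <- (seq_len(nrr) - 1) * ref_pitch / ps   # 0-based fine-grid coords
      xr <- (seq_len(ncr) - 1) * ref_pitch / ps
      RY <- matrix(yr, nrr, ncr)
      RX <- matrix(xr, nrr, ncr, byrow = TRUE)
      Iref_true <- cpp_bilinear_lookup(sm, cov_fine, RY, RX, fill = 1)
      dim(Iref_true) <- c(nrr, ncr)
    } else Iref_true <- sm
  }
  cov_all <- matrix(1L, nrow(Iref_true), ncol(Iref_true))

  images <- array(0, c(nr, nc, N))
  if (mode == "geometric") {
    pr <- if (ref_pitch > ps) ref_pitch else ps
    for (n in seq_len(N)) {
      ry <- (u[, , 1] - positions[n, 1] - origin[1]) / pr
      rx <- (u[, , 2] - positions[n, 2] - origin[2]) / pr
      hol <- cpp_bilinear_lookup(Iref_true, cov_all, ry, rx, fill = 1)
      images[, , n] <- W * hol
    }
  } else {
    pres <- residual_phase_demag(pupil, ys, xs)
    # detector -> demagnified sample-plane coordinates via the quadratic map
    qy <- (Y * g$focus_sample_y / (g$focus_sample_y + z) - origin[1]) / ps
    qx <- (X * g$focus_sample_x / (g$focus_sample_x + z) - origin[2]) / ps
    # taper the transmission contrast at the grid border so the periodic
    # Fourier shift does not ring across the field
    wtp <- 8
    ty_ <- stats::pnorm((seq_len(nrs) - 1) / wtp - 2) *
      stats::pnorm((nrs - seq_len(nrs)) / wtp - 2)
    tx_ <- stats::pnorm((seq_len(ncs) - 1) / wtp - 2) *
      stats::pnorm((ncs - seq_len(ncs)) / wtp - 2)
    Tap <- outer(ty_, tx_)
    T0 <- 1 + (phantom$transmission - 1) * Tap
    for (n in seq_len(N)) {
      Tn <- fourier_shift(T0,
                          positions[n, 1] / ps, positions[n, 2] / ps)
      psi <- fresnel_propagate_aniso(Tn * exp(1i * pres),
                                     d$effective_defocus_y,
                                     d$effective_defocus_x, lam, ps)
      In <- Mod(psi)^2
      hol <- cpp_bilinear_lookup(In, cov_fine, qy, qx, fill = 1)
      images[, , n] <- W * hol
    }
  }
  if (noise == "poisson") {
    if (!is.null(seed)) set.seed(seed)
    images[] <- rpois(length(images), pmax(images, 0))
  }
  scan <- scan_data(images, positions, g)
  truth <- list(W = W, u = u,
                reference = list(image = Iref_true,
                                 pitch = if (ref_pitch > ps) ref_pitch else ps,
                                 origin = origin),
                phase = pupil$phase,
                grad_y = pupil$grad_y, grad_x = pupil$grad_x)
  structure(list(scan = scan, truth = truth), class = "pxst_sim")
}
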