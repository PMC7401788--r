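#' Material presets for single-material phantoms
#'
#' Nominal refractive-index decrement `delta` and absorption index `beta`
#' around 16-17 keV for the shipped phantom materials.
#'
#' @param material `"gold"` or `"silica"`.
#' @return list with `delta`, `beta`.
#' @export
material_constants <- function(material = c("gold", "silica")) {
  material <- match.arg(material)
  switch(material,
    gold   = list(delta = 1.05e-5, beta = 7.3e-7),
    silica = list(delta = 1.9e-6,  beta = 1.3e-8))
}

#' Phantom from an arbitrary thickness map
#'
#' Builds a single-material phantom with transmission
#' T = exp(-(2 pi / lambda) (beta + i delta) t) from a projected thickness
#' map. Setting `delta = 0` gives a pure absorber, `beta = 0` a pure phase
#' object.
#'
#' @param thickness projected thickness matrix (m), >= 0.
#' @param pitch sample-grid pixel size (m).
#' @param delta,beta refractive index decrement and absorption index.
#' @param wavelength wavelength (m).
#' @return a `sample_phantom`.
#' @export
phantom_from_thickness <- function(thickness, pitch, delta, beta,
                                   wavelength) {
  stopifnot(all(thickness >= 0), pitch > 0, beta >= 0, delta >= 0)
  new_phantom(thickness, pitch, delta, beta, wavelength)
}

new_phantom <- function(thickness, pitch, delta, beta, wavelength) {
  k <- 2 * pi / wavelength
  transmission <- exp(-k * (beta + 1i * delta) * thickness)
  structure(list(
    transmission = transmission,
    thickness = thickness,
    pitch = pitch,
    delta = delta, beta = beta,
    wavelength = wavelength
  ), class = "sample_phantom")
}

#' @export
print.sample_phantom <- function(x, ...) {
  cat(sprintf("<sample_phantom> %d x %d px, pitch %.3g m, max thickness %.3g m\n",
              nrow(x$thickness), ncol(x$thickness), x$pitch,
              max(x$thickness)))
  invisible(x)
}

#' Siemens star resolution phantom
#'
#' A radial spoke target: `n_spokes` opaque spokes alternating with equal
#' gaps (50% angular duty cycle), truncated where the spoke width would fall
#' below `tip_width`, with annular gaps ("circular cuts") at two radii.
#' Projected thickness ramps linearly from `thickness_range[2]` at the tips
#' to `thickness_range[1]` at the rim.
#'
#' @param shape integer (rows, cols) of the sample grid.
#' @param pitch sample-grid pixel size (m).
#' @param diameter star diameter (m).
#' @param n_spokes number of spokes.
#' @param tip_width width of the spoke tip facing the centre (m).
#' @param thickness_range (min, max) projected thickness (m). `c(0, 0)` gives
#'   an empty beam.
#' @param cut_radii radii of the two annular cuts, as fractions of the outer
#'   radius.
#' @param cut_width width of each annular cut as a fraction of the radius.
#' @param material,wavelength material preset and wavelength (m).
#' @return a `sample_phantom`.
#' @export
make_siemens_star <- function(shape = c(512L, 512L), pitch = 20e-9,
                              diameter = 10e-6, n_spokes = 30L,
                              tip_width = 100e-9,
                              thickness_range = c(0.5e-6, 1e-6),
                              cut_radii = c(0.5, 0.8), cut_width = 0.04,
                              material = "gold",
                              wavelength = energy_to_wavelength(16.7)) {
  stopifnot(tip_width < diameter, n_spokes >= 2)
  mc <- material_constants(material)
  nr <- shape[1]; nc <- shape[2]
  y <- (seq_len(nr) - 1 - (nr - 1) / 2) * pitch
  x <- (seq_len(nc) - 1 - (nc - 1) / 2) * pitch
  Y <- matrix(y, nr, nc)
  X <- matrix(x, nr, nc, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  ang_period <- 2 * pi / n_spokes
  spoke <- (th %% ang_period) < (ang_period / 2)
  r_out <- diameter / 2
  r_in <- tip_width / (ang_period / 2)     # radius where spoke width = tip_width
  inside <- spoke & r >= r_in & r <= r_out
  for (cr in cut_radii) {
    inside <- inside & !(abs(r - cr * r_out) < cut_width * r_out / 2)
  }
  ramp <- thickness_range[2] +
    (thickness_range[1] - thickness_range[2]) *
      pmin(pmax((r - r_in) / max(r_out - r_in, pitch), 0), 1)
  thick <- ifelse(inside, ramp, 0)
  if (tip_width < 2 * pitch) {
    warning("grid too coarse to resolve tip_width; phantom low-pass filtered")
    thick <- smooth_field(thick, sigma = 1)
  }
  new_phantom(thick, pitch, mc$delta, mc$beta, wavelength)
}

#' Quasi-periodic hexagonal lattice phantom
#'
#' Gaussian bumps on a hexagonal lattice, optionally modulated by a smooth
#' aperiodic envelope. Used to stress-test speckle registration against
#' translational pseudo-symmetry.
#'
#' @param shape integer (rows, cols) of the sample grid.
#' @param pitch sample-grid pixel size (m).
#' @param lattice_constant primitive lattice constant a (m); must exceed two
#'   grid pixels.
#' @param motif_sd Gaussian bump standard deviation (m); default 0.2 a.
#' @param motif_thickness peak projected thickness of each bump (m); 0 gives
#'   uniform transmission.
#' @param envelope_strength amplitude of the smooth aperiodic thickness
#'   modulation, as a fraction of `motif_thickness` (0 = perfectly periodic).
#' @param offset lattice origin offset (y, x) in metres.
#' @param material,wavelength material preset and wavelength (m).
#' @return a `sample_phantom`.
#' @export
make_hex_lattice_phantom <- function(shape = c(512L, 512L), pitch = 20e-9,
                                     lattice_constant = 601e-9,
                                     motif_sd = NULL,
                                     motif_thickness = 0.4e-6,
                                     envelope_strength = 0.15,
                                     offset = c(0, 0),
                                     material = "silica",
                                     wavelength = energy_to_wavelength(16.3)) {
  a <- lattice_constant
  if (a <= 2 * pitch) stop("lattice_constant must exceed two grid pixels")
  if (is.null(motif_sd)) motif_sd <- 0.2 * a
  mc <- material_constants(material)
  nr <- shape[1]; nc <- shape[2]
  y <- (seq_len(nr) - 1 - (nr - 1) / 2) * pitch
  x <- (seq_len(nc) - 1 - (nc - 1) / 2) * pitch
  # hexagonal lattice: a1 = (0, a), a2 = (a*sqrt(3)/2, a/2) in (y, x)
  ext_y <- diff(range(y)); ext_x <- diff(range(x))
  n1 <- ceiling(ext_x / a) + 3
  n2 <- ceiling(ext_y / (a * sqrt(3) / 2)) + 3
  thick <- matrix(0, nr, nc)
  s2 <- 2 * motif_sd^2
  wy <- ceiling(4 * motif_sd / pitch)
  for (i2 in -n2:n2) {
    for (i1 in -n1:n1) {
      cy <- i2 * a * sqrt(3) / 2 + offset[1]
      cx <- i1 * a + i2 * a / 2 + offset[2]
      if (cy < y[1] - 4 * motif_sd || cy > y[nr] + 4 * motif_sd) next
      if (cx < x[1] - 4 * motif_sd || cx > x[nc] + 4 * motif_sd) next
      iy <- which.min(abs(y - cy)); ix <- which.min(abs(x - cx))
      ry <- max(1, iy - wy):min(nr, iy + wy)
      rx <- max(1, ix - wy):min(nc, ix + wy)
      g <- outer(exp(-(y[ry] - cy)^2 / s2), exp(-(x[rx] - cx)^2 / s2))
      thick[ry, rx] <- thick[ry, rx] + motif_thickness * g
    }
  }
  if (envelope_strength > 0) {
    Y <- matrix(y / max(abs(y)), nr, nc)
    X <- matrix(x / max(abs(x)), nr, nc, byrow = TRUE)
    env <- 1 + envelope_strength *
      (0.6 * sin(2.1 * pi * X + 0.7) * cos(1.7 * pi * Y - 0.4) +
       0.4 * (X^2 - Y^2))
    thick <- thick * env
  }
  new_phantom(thick, pitch, mc$delta, mc$beta, wavelength)
}

#' Random speckle (diffuser) phantom
#'
#' Gaussian-correlated random thickness map, emulating a dense random object
#' such as a diffuser: detailed, non-repeating modulation across all relevant
#' spatial frequencies. Edge-rich, so its defocused hologram carries strong
#' Thon rings.
#'
#' @param shape integer (rows, cols) of the sample grid.
#' @param pitch sample-grid pixel size (m).
#' @param mean_thickness,rms_thickness mean and standard deviation of the
#'   projected thickness (m); negative excursions are clipped at zero.
#' @param grain correlation length of the structure (m).
#' @param seed RNG seed.
#' @param material,wavelength material preset and wavelength (m).
#' @return a `sample_phantom`.
#' @export
make_speckle_phantom <- function(shape = c(512L, 512L), pitch = 20e-9,
                                 mean_thickness = 0.5e-6,
                                 rms_thickness = 0.25e-6,
                                 grain = 150e-9, seed = NULL,
                                 material = "silica",
                                 wavelength = energy_to_wavelength(16.7)) {
  mc <- material_constants(material)
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  noise <- matrix(rnorm(nr * nc), nr, nc)
  fy <- freq_vector(nr, pitch); fx <- freq_vector(nc, pitch)
  f2 <- outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2)
  H <- exp(-2 * pi^2 * grain^2 * f2 / 2)
  sm <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (nr * nc)
  sm <- sm / sd(sm) * rms_thickness
  thick <- pmax(mean_thickness + sm, 0)
  new_phantom(thick, pitch, mc$delta, mc$beta, wavelength)
}

#' Aberrated pupil phase on the detector grid
#'
#' Ground-truth phase of the illumination in the detector plane: the per-axis
#' quadratic of an astigmatic diverging beam, pi x^2/(lambda (z1x + z)) +
#' pi y^2/(lambda (z1y + z)), plus a polynomial residual specified on
#' normalized detector coordinates (x, y in -1..1 across the half-extent).
#'
#' @param geometry an [xrt_geometry()].
#' @param residual_coeffs data.frame with columns `kx`, `ky`, `coeff` (rad):
#'   residual terms coeff * xn^kx * yn^ky. `NULL` for a pure quadratic.
#' @param support optional logical matrix (aperture); default full grid.
#' @return object of class `pupil_phase` with `phase`, analytic gradients
#'   `grad_y`, `grad_x` (rad/m), `support` and the generating parameters.
#' @export
make_pupil_phase <- function(geometry, residual_coeffs = NULL, support = NULL) {
  g <- geometry
  co <- det_coords(g)
  nr <- g$detector_shape[1]; nc <- g$detector_shape[2]
  lam <- g$wavelength
  z <- g$sample_detector
  Y <- matrix(co$y, nr, nc)
  X <- matrix(co$x, nr, nc, byrow = TRUE)
  phase <- pi * X^2 / (lam * (g$focus_sample_x + z)) +
           pi * Y^2 / (lam * (g$focus_sample_y + z))
  gx <- 2 * pi * X / (lam * (g$focus_sample_x + z))
  gy <- 2 * pi * Y / (lam * (g$focus_sample_y + z))
  yn <- max(abs(co$y)); xn <- max(abs(co$x))
  if (!is.null(residual_coeffs) && nrow(residual_coeffs) > 0) {
    stopifnot(all(c("kx", "ky", "coeff") %in% names(residual_coeffs)),
              all(is.finite(residual_coeffs$coeff)))
    Xn <- X / xn; Yn <- Y / yn
    for (r in seq_len(nrow(residual_coeffs))) {
      kx <- residual_coeffs$kx[r]; ky <- residual_coeffs$ky[r]
      cc <- residual_coeffs$coeff[r]
      phase <- phase + cc * Xn^kx * Yn^ky
      if (kx > 0) gx <- gx + cc * kx * Xn^(kx - 1) * Yn^ky / xn
      if (ky > 0) gy <- gy + cc * ky * Xn^kx * Yn^(ky - 1) / yn
    }
  }
  if (is.null(support)) support <- matrix(TRUE, nr, nc)
  structure(list(
    phase = phase, grad_y = gy, grad_x = gx, support = support,
    residual_coeffs = residual_coeffs, geometry = g
  ), class = "pupil_phase")
}
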