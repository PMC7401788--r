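#' @useDynLib pxst, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rpois rnorm runif sd lm coef optim approx quantile fft
#' @importFrom utils modifyList
NULL

# hc in nm.keV; fixed conversion constant
.HC_NM_KEV <- 1.2398

#' Convert photon energy to wavelength
#'
#' Uses lambda = 1.2398 nm keV / E.
#'
#' @param energy_kev photon energy in keV.
#' @return wavelength in metres.
#' @export
energy_to_wavelength <- function(energy_kev) {
  stopifnot(is.numeric(energy_kev), all(energy_kev > 0))
  .HC_NM_KEV * 1e-9 / energy_kev
}

#' Convert wavelength to photon energy
#'
#' @param wavelength wavelength in metres.
#' @return photon energy in keV.
#' @export
wavelength_to_energy <- function(wavelength) {
  stopifnot(is.numeric(wavelength), all(wavelength > 0))
  .HC_NM_KEV * 1e-9 / wavelength
}

#' Imaging geometry for a divergent-beam projection microscope
#'
#' Describes the focus -> sample -> detector geometry of an in-line projection
#' (shadow) imaging experiment with a (possibly astigmatic) focused beam.
#' Distances from the beam focus to the sample may differ between the
#' horizontal and vertical focal planes of the lens pair.
#'
#' @param energy_kev photon energy (keV). Exactly one of `energy_kev`,
#'   `wavelength` must be given.
#' @param wavelength wavelength (m).
#' @param focus_sample_x,focus_sample_y focus-to-sample distances z1x, z1y (m)
#'   for the horizontal / vertical focal planes. `focus_sample_y` defaults to
#'   `focus_sample_x` (stigmatic beam).
#' @param sample_detector sample-to-detector distance z (m).
#' @param detector_shape integer vector (rows, cols) of the detector region of
#'   interest.
#' @param pixel_size detector pixel size (m, square pixels).
#' @param interpolation_factor fractional effective pixel width delta_pix in
#'   (0, 1] achieved by sub-pixel interpolation.
#' @param sample_tilt tilt of the scan plane w.r.t. the transverse plane (rad).
#' @param na optional direct override for the numerical aperture; when `NULL`
#'   the NA is computed as the detector half-extent divided by (z1 + z).
#' @return an object of class `xrt_geometry`.
#' @export
xrt_geometry <- function(energy_kev = NULL, wavelength = NULL,
                         focus_sample_x, focus_sample_y = focus_sample_x,
                         sample_detector,
                         detector_shape = c(256L, 256L),
                         pixel_size = 55e-6,
                         interpolation_factor = 1,
                         sample_tilt = 0,
                         na = NULL) {
  if (is.null(wavelength) == is.null(energy_kev))
    stop("give exactly one of 'energy_kev' or 'wavelength'")
  if (is.null(wavelength)) wavelength <- energy_to_wavelength(energy_kev)
  if (is.null(energy_kev)) energy_kev <- wavelength_to_energy(wavelength)
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2L || any(detector_shape < 2L))
    stop("detector_shape must be two integers >= 2")
  stopifnot(focus_sample_x > 0, focus_sample_y > 0, sample_detector > 0,
            pixel_size > 0, wavelength > 0,
            interpolation_factor > 0, interpolation_factor <= 1)
  structure(list(
    wavelength = wavelength,
    energy_kev = energy_kev,
    focus_sample_x = focus_sample_x,
    focus_sample_y = focus_sample_y,
    sample_detector = sample_detector,
    detector_shape = detector_shape,
    pixel_size = pixel_size,
    interpolation_factor = interpolation_factor,
    sample_tilt = sample_tilt,
    na_override = na
  ), class = "xrt_geometry")
}

#' @export
print.xrt_geometry <- function(x, ...) {
  d <- derive_geometry(x)
  cat("<xrt_geometry>\n")
  cat(sprintf("  energy          %.4g keV (lambda = %.4g m)\n",
              x$energy_kev, x$wavelength))
  cat(sprintf("  z1 (x, y)       %.4g, %.4g m\n",
              x$focus_sample_x, x$focus_sample_y))
  cat(sprintf("  z               %.4g m\n", x$sample_detector))
  cat(sprintf("  detector        %d x %d px of %.3g m\n",
              x$detector_shape[1], x$detector_shape[2], x$pixel_size))
  cat(sprintf("  magnification   %.1f (x %.1f, y %.1f)\n", d$M, d$M_x, d$M_y))
  cat(sprintf("  eff. defocus    %.4g m\n", d$effective_defocus))
  invisible(x)
}

#' Geometric magnification of a point-projection microscope
#'
#' @param z1 focus-to-sample distance (m), > 0.
#' @param z sample-to-detector distance (m), >= 0.
#' @return M = (z1 + z) / z1.
#' @export
magnification <- function(z1, z) {
  if (any(z1 <= 0)) stop("invalid geometry: focus-sample distance must be > 0")
  if (any(z < 0)) stop("invalid geometry: sample-detector distance must be >= 0")
  (z1 + z) / z1
}

#' Effective defocus (equivalent plane-wave propagation distance)
#'
#' The magnified shadow image equals a plane-wave in-line hologram recorded a
#' distance zbar = z z1 / (z1 + z) downstream of the sample, scaled by M.
#'
#' @inheritParams magnification
#' @return zbar (m).
#' @export
effective_defocus <- function(z1, z) {
  if (any(z1 <= 0)) stop("invalid geometry: focus-sample distance must be > 0")
  if (any(z < 0)) stop("invalid geometry: sample-detector distance must be >= 0")
  z * z1 / (z1 + z)
}

#' Demagnified (effective sample-plane) pixel size
#'
#' @param pixel_size detector pixel size (m).
#' @param M magnification, >= 1.
#' @return delta = pixel_size / M (m).
#' @export
demagnified_pixel <- function(pixel_size, M) {
  if (any(M < 1)) stop("magnification must be >= 1")
  pixel_size / M
}

#' Sample thickness and tilt validity limits for speckle tracking
#'
#' Features at different depths of a thick sample project at different
#' magnifications; registration stays sub-pixel only while the projected
#' thickness is below delta / (2 NA), and the scan-plane tilt below delta/FOV.
#'
#' @param delta demagnified pixel size (m).
#' @param na numerical aperture of the focused beam.
#' @param fov side length of the beam footprint on the sample (m).
#' @return list with `thickness_limit` (m) and `tilt_limit` (rad).
#' @export
validity_limits <- function(delta, na, fov) {
  stopifnot(delta > 0)
  if (na <= 0 || fov <= 0) stop("NA and FOV must be > 0")
  list(thickness_limit = delta / (2 * na), tilt_limit = delta / fov)
}

#' Ideal angular sensitivity bound
#'
#' Smallest resolvable ray-angle deviation: one (interpolated) detector pixel
#' viewed over the lever arm z, referred to the sample through M.
#'
#' @param pixel_size detector point-spread width (m), >= physical pixel.
#' @param interpolation_factor fractional pixel delta_pix in (0, 1]
#'   (0 allowed as an idealized limit).
#' @param z sample-to-detector distance (m).
#' @param M magnification.
#' @return Delta-Theta = delta_pix * pixel_size / (z * M), in rad.
#' @export
angular_sensitivity_bound <- function(pixel_size, interpolation_factor, z, M) {
  stopifnot(pixel_size > 0, z > 0, M > 0, interpolation_factor >= 0)
  interpolation_factor * pixel_size / (z * M)
}

#' Effective Fresnel number of a sample feature
#'
#' @param X full-period size of the feature (m).
#' @param wavelength wavelength (m).
#' @param zbar effective defocus (m).
#' @return N_F = X^2 / (lambda * zbar).
#' @export
effective_fresnel_number <- function(X, wavelength, zbar) {
  stopifnot(X > 0, wavelength > 0, zbar > 0)
  X^2 / (wavelength * zbar)
}

#' Edge-overlap (Rayleigh-type) resolution of a defocused hologram
#'
#' Two conventions are in circulation for the separation at which the first
#' Fresnel-fringe minimum of one edge lands on the zeroth-order maximum of an
#' adjacent edge: `"2sqrt"` gives 2*sqrt(lambda*zbar), `"sqrt"` gives
#' sqrt(lambda*zbar). A numerically computed criterion is available via
#' [fresnel_edge_overlap_separation()].
#'
#' @param wavelength wavelength (m).
#' @param zbar effective defocus (m).
#' @param convention `"2sqrt"` or `"sqrt"`.
#' @return separation (m).
#' @export
rayleigh_resolution <- function(wavelength, zbar,
                                convention = c("2sqrt", "sqrt")) {
  convention <- match.arg(convention)
  stopifnot(wavelength > 0, zbar > 0)
  s <- sqrt(wavelength * zbar)
  if (convention == "2sqrt") 2 * s else s
}

#' Numeric Fresnel-edge overlap separation
#'
#' Computes, from the Fresnel-integral edge diffraction profile, the distance
#' between an edge and the first minimum of its fringe pattern; at this
#' separation that minimum coincides with the bright zeroth-order band of an
#' adjacent parallel edge. Serves as an oracle for the closed-form conventions
#' of [rayleigh_resolution()].
#'
#' @inheritParams rayleigh_resolution
#' @return separation (m).
#' @export
fresnel_edge_overlap_separation <- function(wavelength, zbar) {
  stopifnot(wavelength > 0, zbar > 0)
  # edge intensity I(v) = 0.5*[(C(v)+0.5)^2 + (S(v)+0.5)^2],
  # v = x * sqrt(2/(lambda*zbar)); first minimum at the first
  # stationary point of I beyond the first maximum.
  v <- seq(0, 5, by = 1e-4)
  I <- 0.5 * ((pracma::fresnelC(v) + 0.5)^2 + (pracma::fresnelS(v) + 0.5)^2)
  dI <- diff(I)
  sign_change <- which(dI[-1] < 0 & dI[-length(dI)] >= 0)  # maxima
  first_max <- sign_change[1]
  after <- which(dI[-1] >= 0 & dI[-length(dI)] < 0)        # minima
  first_min <- after[after > first_max][1]
  v_min <- v[first_min + 1]
  v_min * sqrt(wavelength * zbar / 2)
}

#' Derived geometric quantities
#'
#' Computes per-axis and mean magnification, effective defocus, demagnified
#' pixel, numerical aperture, field of view, validity limits, angular
#' sensitivity bound and (optionally) the effective Fresnel number of a
#' feature period.
#'
#' @param geometry an [xrt_geometry()].
#' @param feature_period optional full-period feature size X (m) for the
#'   Fresnel number.
#' @return a list of class `xrt_derived`.
#' @export
derive_geometry <- function(geometry, feature_period = NULL) {
  g <- geometry
  z <- g$sample_detector
  M_x <- magnification(g$focus_sample_x, z)
  M_y <- magnification(g$focus_sample_y, z)
  M <- (M_x + M_y) / 2
  zb_x <- effective_defocus(g$focus_sample_x, z)
  zb_y <- effective_defocus(g$focus_sample_y, z)
  zbar <- (zb_x + zb_y) / 2
  delta_x <- demagnified_pixel(g$pixel_size, M_x)
  delta_y <- demagnified_pixel(g$pixel_size, M_y)
  delta <- g$pixel_size / M
  half_extent <- max(g$detector_shape) / 2 * g$pixel_size
  na <- if (!is.null(g$na_override)) g$na_override else
    half_extent / (mean(c(g$focus_sample_x, g$focus_sample_y)) + z)
  fov <- max(g$detector_shape) * g$pixel_size / M
  lim <- validity_limits(delta, na, fov)
  out <- list(
    M_x = M_x, M_y = M_y, M = M,
    effective_defocus_x = zb_x, effective_defocus_y = zb_y,
    effective_defocus = zbar,
    demagnified_pixel_x = delta_x, demagnified_pixel_y = delta_y,
    demagnified_pixel = delta,
    na = na, fov = fov,
    thickness_limit = lim$thickness_limit,
    tilt_limit = lim$tilt_limit,
    sensitivity_bound = angular_sensitivity_bound(
      g$pixel_size, g$interpolation_factor, z, M)
  )
  if (!is.null(feature_period))
    out$fresnel_number <- effective_fresnel_number(
      feature_period, g$wavelength, zbar)
  class(out) <- "xrt_derived"
  out
}

# physical detector-plane pixel-centre coordinates (metres, optical axis at
# the grid centre): list(y, x); axis 0 = rows = y
det_coords <- function(geometry) {
  nr <- geometry$detector_shape[1]
  nc <- geometry$detector_shape[2]
  p <- geometry$pixel_size
  list(y = (seq_len(nr) - 1 - (nr - 1) / 2) * p,
       x = (seq_len(nc) - 1 - (nc - 1) / 2) * p)
}
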