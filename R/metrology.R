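# achieved angular and phase sensitivity via the split-half procedure

#' Split-half angular sensitivity
#'
#' Randomly assigns every (frame, pixel) sample to one of two half data sets,
#' repeats the phase-gradient (pixel-map) refinement independently on each
#' half while keeping the reference image and translations fixed, and reports
#' the spread of the difference between the two recovered ray-angle maps.
#'
#' The headline `delta_theta` is the standard deviation of the raw
#' componentwise difference Theta_1 - Theta_2; the per-reconstruction
#' uncertainty (raw / sqrt(2)) is also reported.
#'
#' @param scan a [scan_data()].
#' @param result a `pxst_result` from [run_pxst()] (its reference,
#'   translations and pixel map are used).
#' @param seed RNG seed for the pixel split (recorded in the report).
#' @param search_radius search half-width for the per-half refinement.
#' @param n_bins histogram bin count.
#' @return list of class `sensitivity_report`: `delta_theta` (rad),
#'   `delta_theta_single` (rad), `gaussian_sd` (rad, from a Gaussian fit to
#'   the histogram), `histogram` (`mids`, `counts`), `n_pixels`, `seed`.
#' @export
split_half_sensitivity <- function(scan, result, seed = 1L,
                                   search_radius = 3L, n_bins = 61L) {
  g <- result$geometry
  W <- result$white_field
  ref <- result$reference
  u0 <- result$pixel_map
  sc <- scan
  sc$translations <- result$translations
  set.seed(seed)
  dims <- dim(sc$images)
  half <- array(runif(prod(dims)) < 0.5, dims)
  u1 <- update_pixel_map(sc, W, ref, u0, keep = half, min_frames = 2L,
                         search_radius = search_radius)
  u2 <- update_pixel_map(sc, W, ref, u0, keep = !half, min_frames = 2L,
                         search_radius = search_radius)
  z <- g$sample_detector
  # Theta = (x - u)/z, so the angle difference is -(u1 - u2)/z
  dth <- (u2 - u1) / z
  ok <- scan$mask & is.finite(W) & (W > 0) &
    !attr(u1, "flagged") & !attr(u2, "flagged")
  d <- c(dth[, , 1][ok], dth[, , 2][ok])
  d <- d[is.finite(d)]
  sdev <- sd(d)
  h <- graphics::hist(d, breaks = n_bins, plot = FALSE)
  # Gaussian fit by moments on the histogram
  mu <- sum(h$mids * h$counts) / sum(h$counts)
  gsd <- sqrt(sum((h$mids - mu)^2 * h$counts) / sum(h$counts))
  structure(list(delta_theta = sdev,
                 delta_theta_single = sdev / sqrt(2),
                 gaussian_sd = gsd,
                 histogram = list(mids = h$mids, counts = h$counts),
                 n_pixels = sum(ok), seed = seed),
            class = "sensitivity_report")
}


#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "<sensitivity_report> delta_theta = %.3g rad (single: %.3g), %d pixels\n",
    x$delta_theta, x$delta_theta_single, x$n_pixels))
  invisible(x)
}

#' Phase sensitivity from angular sensitivity
#'
#' Propagates an angular uncertainty to a phase uncertainty through an
#' assumed transverse correlation length L of the angle errors:
#' delta_Phi = (2 pi / lambda) * delta_Theta * L. The correlation length is
#' an explicit model parameter of this propagation.
#'
#' @param delta_theta angular sensitivity (rad).
#' @param wavelength wavelength (m).
#' @param correlation_length transverse correlation length (m).
#' @return phase sensitivity (rad).
#' @export
phase_sensitivity <- function(delta_theta, wavelength, correlation_length) {
  stopifnot(delta_theta >= 0, wavelength > 0, correlation_length > 0)
  (2 * pi / wavelength) * delta_theta * correlation_length
}

#' Correlation length implied by a phase sensitivity
#'
#' Inverse of [phase_sensitivity()]: the correlation length that maps a given
#' angular sensitivity to a given phase sensitivity.
#'
#' @param delta_phi phase sensitivity (rad).
#' @param delta_theta angular sensitivity (rad).
#' @param wavelength wavelength (m).
#' @return correlation length (m).
#' @export
implied_correlation_length <- function(delta_phi, delta_theta, wavelength) {
  stopifnot(delta_phi >= 0, delta_theta > 0, wavelength > 0)
  delta_phi * wavelength / (2 * pi * delta_theta)
}
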