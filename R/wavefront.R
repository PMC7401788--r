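#' Phase gradient from a pixel map
#'
#' Inverts u(x) = x - (lambda z / 2 pi) grad Phi: the detector-plane phase
#' gradient is (2 pi / (lambda z)) (x - u(x)), sampled at pixel centres.
#'
#' @param u pixel map array (rows, cols, 2), metres (sample-plane scale).
#' @param geometry an [xrt_geometry()].
#' @return list with `gy`, `gx` (rad/m) on the detector grid.
#' @export
gradient_from_map <- function(u, geometry) {
  g <- geometry
  co <- det_coords(g)
  nr <- g$detector_shape[1]; nc <- g$detector_shape[2]
  fac <- 2 * pi / (g$wavelength * g$sample_detector)
  list(gy = fac * (matrix(co$y, nr, nc) - u[, , 1]),
       gx = fac * (matrix(co$x, nr, nc, byrow = TRUE) - u[, , 2]))
}

#' Ray angles from the phase gradient
#'
#' @param gy,gx phase-gradient components (rad/m).
#' @param wavelength wavelength (m).
#' @return list with `ty`, `tx` ray angles (rad): Theta = (lambda/2 pi) grad Phi.
#' @export
ray_angles <- function(gy, gx, wavelength) {
  f <- wavelength / (2 * pi)
  list(ty = f * gy, tx = f * gx)
}

#' Remove constant, tilt and defocus terms from a phase map
#'
#' Weighted least-squares fit of \{1, x, y, x^2, y^2, xy\} (physical detector
#' coordinates, metres) subtracted from the phase. The x^2 and y^2
#' coefficients of a diverging beam equal pi / (lambda (z1 + z)) per axis and
#' therefore carry refined defocus estimates (see [refine_defocus()]).
#'
#' @param phi phase matrix (rad).
#' @param pixel_size detector pixel size (m).
#' @param mask logical matrix of valid pixels.
#' @param weights optional non-negative weight matrix.
#' @return list with `residual` (rad, NA off the mask), `fitted`, and
#'   `coefficients` named `c0, x, y, x2, y2, xy` (SI units).
#' @export
remove_low_orders <- function(phi, pixel_size = 1, mask = NULL,
                              weights = NULL) {
  nr <- nrow(phi); nc <- ncol(phi)
  if (is.null(mask)) mask <- is.finite(phi)
  if (sum(mask) < 12) stop("mask too small for a 6-parameter fit")
  y <- (seq_len(nr) - 1 - (nr - 1) / 2) * pixel_size
  x <- (seq_len(nc) - 1 - (nc - 1) / 2) * pixel_size
  Y <- matrix(y, nr, nc); X <- matrix(x, nr, nc, byrow = TRUE)
  sel <- which(mask & is.finite(phi))
  # normalized coordinates for conditioning; coefficients rescaled after
  sy <- max(abs(y)); sx <- max(abs(x))
  A <- cbind(1, X[sel] / sx, Y[sel] / sy, (X[sel] / sx)^2, (Y[sel] / sy)^2,
             X[sel] * Y[sel] / (sx * sy))
  w <- if (is.null(weights)) rep(1, length(sel)) else weights[sel]
  fit <- stats::lm.wfit(A, phi[sel], w)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  co <- c(c0 = cf[[1]], x = cf[[2]] / sx, y = cf[[3]] / sy,
          x2 = cf[[4]] / sx^2, y2 = cf[[5]] / sy^2, xy = cf[[6]] / (sx * sy))
  fitted <- co[["c0"]] + co[["x"]] * X + co[["y"]] * Y +
    co[["x2"]] * X^2 + co[["y2"]] * Y^2 + co[["xy"]] * X * Y
  residual <- phi - fitted
  residual[!mask] <- NA_real_
  list(residual = residual, fitted = fitted, coefficients = co)
}

#' Refined defocus from the recovered phase curvature
#'
#' Fits the quadratic part of the recovered detector-plane phase and converts
#' the per-axis curvatures to focus-sample distances and effective defocus:
#' a = pi / (lambda (z1 + z)) implies z1 = pi/(lambda a) - z.
#'
#' @param phi recovered phase (rad) on the detector grid.
#' @param geometry an [xrt_geometry()].
#' @param mask optional logical matrix.
#' @return list with `z1x`, `z1y`, `zbar_x`, `zbar_y` (m) and the fit
#'   coefficients.
#' @export
refine_defocus <- function(phi, geometry, mask = NULL) {
  fit <- remove_low_orders(phi, pixel_size = geometry$pixel_size, mask = mask)
  lam <- geometry$wavelength
  z <- geometry$sample_detector
  zt_x <- pi / (lam * fit$coefficients[["x2"]])   # z1x + z
  zt_y <- pi / (lam * fit$coefficients[["y2"]])
  z1x <- zt_x - z; z1y <- zt_y - z
  list(z1x = z1x, z1y = z1y,
       zbar_x = if (z1x > 0) effective_defocus(z1x, z) else NA_real_,
       zbar_y = if (z1y > 0) effective_defocus(z1y, z) else NA_real_,
       coefficients = fit$coefficients)
}

# full wavefront assembly from a converged pixel map
make_wavefront <- function(W, u, geometry, mask = NULL) {
  g <- gradient_from_map(u, geometry)
  p <- geometry$pixel_size
  phi <- integrate_gradient(g$gy, g$gx, pitch = p, stagger = TRUE)
  cg <- centre_gradient(phi, pitch = p)
  fit <- remove_low_orders(phi, pixel_size = p, mask = mask)
  th <- ray_angles(g$gy, g$gx, geometry$wavelength)
  list(W = W, phase = phi, gy = g$gy, gx = g$gx,
       gy_proj = cg$gy, gx_proj = cg$gx,
       phase_residual = fit$residual,
       low_order_coefficients = fit$coefficients,
       theta_y = th$ty, theta_x = th$tx,
       pixel_size = p)
}
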