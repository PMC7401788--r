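#' Cumulative power spectrum of a scan
#'
#' Sum over frames of |FT(I_n/W - 1)|^2. Fresnel fringes from sample edges
#' imprint a ring system (Thon rings) whose spacing encodes the effective
#' defocus and whose ellipticity encodes astigmatism. Masked or non-positive
#' white-field pixels are filled with the frame mean of the contrast (zero).
#'
#' @param scan a [scan_data()].
#' @param W white field; computed with [estimate_white_field()] when NULL.
#' @return spectrum matrix in raw FFT ordering (DC suppressed), with
#'   attribute `pixel_size`.
#' @export
cumulative_power_spectrum <- function(scan, W = NULL) {
  if (is.null(W)) W <- estimate_white_field(scan)
  N <- dim(scan$images)[3]
  good <- scan$mask & is.finite(W) & (W > 0)
  S <- matrix(0, dim(scan$images)[1], dim(scan$images)[2])
  for (n in seq_len(N)) {
    r <- scan$images[, , n] / W - 1
    r[!good] <- 0
    S <- S + Mod(stats::fft(r))^2
  }
  S[1, 1] <- 0
  attr(S, "pixel_size") <- scan$geometry$pixel_size
  S
}

# effective plane-wave distance of detector-plane fringes for one axis:
# the magnified hologram at zbar has detector-scale fringes matching
# z_eff = M^2 zbar = M z
thon_zeff <- function(z1, z) z * (z1 + z) / z1

#' Thon-ring defocus and astigmatism fit
#'
#' Fits the cumulative power spectrum with the ring model
#' sin^2(pi lambda (z_eff,x fx^2 + z_eff,y fy^2)) (the CTFFIND-style
#' elliptically interpolated defocus z(theta) = zx cos^2 theta +
#' zy sin^2 theta), after subtracting a smooth radial background (moving 30th
#' percentile). Maximizes the normalized correlation over a frequency band.
#'
#' @param spectrum output of [cumulative_power_spectrum()].
#' @param wavelength wavelength (m).
#' @param z sample-detector distance (m).
#' @param z1_range search range (m) for the focus-sample distance, length 2.
#' @param pixel_size detector pixel size (m); taken from the spectrum
#'   attribute when NULL.
#' @param band fitted frequency band as fractions of Nyquist.
#' @param n_coarse coarse-search grid points.
#' @param corr_threshold minimum correlation for success (ring-free spectra score near zero).
#' @return object of class `defocus_estimate` with `z1x`, `z1y`, `zbar_x`,
#'   `zbar_y`, `score`, `method = "thon"`, `status` (`"ok"` or `"failed"`).
#' @export
fit_thon_rings <- function(spectrum, wavelength, z, z1_range,
                           pixel_size = NULL, band = c(0.1, 0.8),
                           n_coarse = 41L, corr_threshold = 0.1) {
  if (is.null(pixel_size)) pixel_size <- attr(spectrum, "pixel_size")
  stopifnot(length(z1_range) == 2, all(z1_range > 0))
  nr <- nrow(spectrum); nc <- ncol(spectrum)
  fy <- freq_vector(nr, pixel_size)
  fx <- freq_vector(nc, pixel_size)
  FY2 <- outer(fy^2, rep(1, nc))
  FX2 <- outer(rep(1, nr), fx^2)
  q <- sqrt(FY2 + FX2)
  nyq <- 1 / (2 * pixel_size)
  sel <- q >= band[1] * nyq & q <= band[2] * nyq

  # ring-count precondition at the band edge for the largest candidate z_eff
  ze_hi <- thon_zeff(min(z1_range), z)
  n_rings <- wavelength * ze_hi * (band[2] * nyq)^2
  if (n_rings < 2)
    return(structure(list(z1x = NA_real_, z1y = NA_real_,
                          zbar_x = NA_real_, zbar_y = NA_real_,
                          score = NA_real_, method = "thon",
                          search_range = z1_range, status = "failed",
                          reason = "fewer than 2 rings in the fitted band"),
                     class = "defocus_estimate"))

  # radial background: per-bin 30th percentile, median-smoothed
  df <- min(1 / (nr * pixel_size), 1 / (nc * pixel_size))
  bin <- pmin(round(q / df), round(nyq / df)) + 1
  bg_bin <- tapply(spectrum[sel], bin[sel], quantile, probs = 0.3, names = FALSE)
  bins <- as.integer(names(bg_bin))
  bg_s <- stats::runmed(as.numeric(bg_bin), k = min(9L, length(bg_bin) -
                                                      (1 - length(bg_bin) %% 2)))
  Sb <- spectrum
  Sb[sel] <- spectrum[sel] -
    approx(bins, bg_s, xout = bin[sel], rule = 2)$y
  sv <- Sb[sel]
  sv <- sv - mean(sv)
  sn <- sqrt(sum(sv^2))
  if (!is.finite(sn) || sn <= 0)
    return(structure(list(z1x = NA_real_, z1y = NA_real_,
                          zbar_x = NA_real_, zbar_y = NA_real_,
                          score = 0, method = "thon",
                          search_range = z1_range, status = "failed",
                          reason = "spectrum has no structure in the band"),
                     class = "defocus_estimate"))

  score_fn <- function(z1x, z1y) {
    if (!is.finite(z1x) || !is.finite(z1y) || z1x <= 0 || z1y <= 0)
      return(-Inf)
    chi <- pi * wavelength * (thon_zeff(z1x, z) * FX2[sel] +
                              thon_zeff(z1y, z) * FY2[sel])
    m <- sin(chi)^2
    m <- m - mean(m)
    s <- sum(sv * m) / (sn * sqrt(sum(m^2)))
    if (!is.finite(s)) -Inf else s
  }
  cand <- exp(seq(log(z1_range[1]), log(z1_range[2]), length.out = n_coarse))
  cs <- vapply(cand, function(c1) score_fn(c1, c1), numeric(1))
  best <- cand[which.max(cs)]
  opt <- optim(c(best, best), function(p) -score_fn(p[1], p[2]),
               method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 300))
  z1x <- opt$par[1]; z1y <- opt$par[2]
  score <- -opt$value
  status <- if (!is.finite(score) || score < corr_threshold) "failed" else "ok"
  structure(list(
    z1x = if (status == "ok") z1x else NA_real_,
    z1y = if (status == "ok") z1y else NA_real_,
    zbar_x = if (status == "ok") effective_defocus(z1x, z) else NA_real_,
    zbar_y = if (status == "ok") effective_defocus(z1y, z) else NA_real_,
    score = score, method = "thon", search_range = z1_range,
    status = status), class = "defocus_estimate")
}

#' @export
print.defocus_estimate <- function(x, ...) {
  cat(sprintf("<defocus_estimate:%s> status %s", x$method, x$status))
  if (x$status == "ok")
    cat(sprintf(": z1 = (%.4g, %.4g) m, zbar = (%.4g, %.4g) m, score %.3f",
                x$z1x, x$z1y, x$zbar_x, x$zbar_y, x$score))
  cat("\n")
  invisible(x)
}

#' Brute-force defocus search by forward-model error
#'
#' For each candidate focus-sample distance, builds the quadratic pixel map
#' and reference and evaluates the total forward-model error; returns the
#' candidate with the smallest error. Used when fringing is too weak for the
#' ring fit.
#'
#' @param scan a [scan_data()].
#' @param z1_candidates candidate z1 values (m), length >= 1.
#' @param W optional white field.
#' @return `defocus_estimate` with the SSE curve in `$sse`.
#' @export
scan_defocus_sse <- function(scan, z1_candidates, W = NULL) {
  stopifnot(length(z1_candidates) >= 1, all(z1_candidates > 0))
  if (is.null(W)) W <- estimate_white_field(scan)
  g0 <- scan$geometry
  sse <- vapply(z1_candidates, function(z1) {
    g <- g0
    g$focus_sample_x <- z1
    g$focus_sample_y <- z1
    sc <- scan; sc$geometry <- g
    u <- initial_pixel_map(g)
    ref <- build_reference(sc, W, u)
    compute_error_map(sc, W, ref, u)$total
  }, numeric(1))
  k <- which.min(sse)
  if (length(z1_candidates) > 2 && (k == 1 || k == length(z1_candidates)))
    warning("SSE minimum at the edge of the candidate range; widen the range")
  z1 <- z1_candidates[k]
  structure(list(z1x = z1, z1y = z1,
                 zbar_x = effective_defocus(z1, g0$sample_detector),
                 zbar_y = effective_defocus(z1, g0$sample_detector),
                 score = sse[k], method = "sse_scan",
                 search_range = range(z1_candidates),
                 status = "ok", sse = sse, candidates = z1_candidates),
            class = "defocus_estimate")
}
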