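# thickness retrieval from the reference hologram and resolution metrology

ref_to_matrix <- function(ref, pitch = NULL, fill = 1) {
  if (inherits(ref, "reference_image")) {
    img <- ref$image
    img[!is.finite(img)] <- fill
    list(img = img, pitch = ref$pitch)
  } else {
    stopifnot(is.matrix(ref), !is.null(pitch))
    img <- ref
    img[!is.finite(img)] <- fill
    list(img = img, pitch = pitch)
  }
}

#' Attenuation coefficient of a single material
#'
#' @param beta absorption index.
#' @param wavelength wavelength (m).
#' @return mu = 4 pi beta / lambda (1/m).
#' @export
attenuation_coefficient <- function(beta, wavelength) 4 * pi * beta / wavelength

#' Projected thickness by transport-of-intensity (single-material) inversion
#'
#' Paganin-form single-material phase retrieval: the normalized hologram is
#' low-pass filtered with 1 / (1 + (delta zbar / mu) k^2) in Fourier space and
#' the thickness is -(1/mu) log of the result. Most accurate at large Fresnel
#' numbers.
#'
#' @param ref a `reference_image` (white-field-normalized hologram) or a
#'   matrix with `pitch` supplied.
#' @param wavelength wavelength (m).
#' @param zbar effective propagation distance of the hologram (m): the
#'   effective defocus of the scan.
#' @param delta,beta refractive index decrement and absorption index of the
#'   material (see [material_constants()]).
#' @param pitch reference pixel size (m) when `ref` is a bare matrix.
#' @return list of class `thickness_map`: `thickness` (m), `mu`, `delta`,
#'   `beta`, `method`, `n_clipped` (non-positive filtered pixels clipped).
#' @export
tie_thickness <- function(ref, wavelength, zbar, delta, beta, pitch = NULL) {
  rm_ <- ref_to_matrix(ref, pitch)
  img <- rm_$img; p <- rm_$pitch
  mu <- attenuation_coefficient(beta, wavelength)
  fy <- freq_vector(nrow(img), p)
  fx <- freq_vector(ncol(img), p)
  k2 <- 4 * pi^2 * (outer(fy^2, rep(1, ncol(img))) +
                    outer(rep(1, nrow(img)), fx^2))
  filt <- 1 / (1 + (delta * zbar / mu) * k2)
  sm <- Re(stats::fft(stats::fft(img) * filt, inverse = TRUE)) / length(img)
  n_clipped <- sum(sm <= 0)
  sm <- pmax(sm, .Machine$double.eps)
  structure(list(thickness = -log(sm) / mu, mu = mu, delta = delta,
                 beta = beta, method = "tie", n_clipped = n_clipped,
                 pitch = p), class = "thickness_map")
}

# weak-object single-material contrast transfer denominator:
# I(f) - delta_D = -D(f) * T(f), D = 2[(2 pi delta/lambda) sin chi
#                                      + (mu/2) cos chi]
ctf_denominator <- function(nrow_, ncol_, pitch, wavelength, zbar,
                            delta, beta) {
  mu <- attenuation_coefficient(beta, wavelength)
  fy <- freq_vector(nrow_, pitch)
  fx <- freq_vector(ncol_, pitch)
  f2 <- outer(fy^2, rep(1, ncol_)) + outer(rep(1, nrow_), fx^2)
  chi <- pi * wavelength * zbar * f2
  2 * ((2 * pi * delta / wavelength) * sin(chi) + (mu / 2) * cos(chi))
}

#' Weak-object forward hologram (contrast-transfer model)
#'
#' Generates the defocused intensity of a weak single-material object from
#' its thickness map; the exact inverse of [ctf_thickness()] away from the
#' transfer-function zeros. Used as a self-consistency oracle.
#'
#' @param thickness projected thickness map (m).
#' @param pitch grid pixel size (m).
#' @inheritParams tie_thickness
#' @return intensity matrix (background 1).
#' @export
ctf_forward_image <- function(thickness, pitch, wavelength, zbar,
                              delta, beta) {
  D <- ctf_denominator(nrow(thickness), ncol(thickness), pitch,
                       wavelength, zbar, delta, beta)
  Tf <- stats::fft(thickness)
  1 + Re(stats::fft(-D * Tf, inverse = TRUE)) / length(thickness)
}

#' Projected thickness by contrast-transfer-function inversion
#'
#' Tikhonov-regularized Fourier division of the weak-object transfer function
#' \[sin chi + (beta/delta) cos chi\], chi = pi lambda zbar q^2. Ideal for
#' weak phase objects; fails (flagged) when the transfer function vanishes
#' identically (e.g. zero defocus with a pure phase object).
#'
#' @inheritParams tie_thickness
#' @param regularization Tikhonov parameter as a fraction of the maximum
#'   squared transfer value.
#' @return list of class `thickness_map`.
#' @export
ctf_thickness <- function(ref, wavelength, zbar, delta, beta, pitch = NULL,
                          regularization = 1e-3) {
  rm_ <- ref_to_matrix(ref, pitch)
  img <- rm_$img; p <- rm_$pitch
  D <- ctf_denominator(nrow(img), ncol(img), p, wavelength, zbar, delta, beta)
  if (max(abs(D)) < 1e-12)
    stop("contrast transfer function is identically zero; ",
         "no contrast to invert (zero defocus, pure phase object)")
  C <- stats::fft(img - mean(img))
  eps <- regularization * max(abs(D))^2
  Tf <- -C * D / (D^2 + eps)
  th <- Re(stats::fft(Tf, inverse = TRUE)) / length(img)
  th <- th - stats::quantile(th, 0.05)   # background to ~0 (DC damped by reg.)
  structure(list(thickness = th, mu = attenuation_coefficient(beta, wavelength),
                 delta = delta, beta = beta, method = "ctf",
                 n_clipped = 0L, pitch = p), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map:%s> %d x %d px, range %.3g..%.3g m\n",
              x$method, nrow(x$thickness), ncol(x$thickness),
              min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' Image resolution from the Fourier power spectrum
#'
#' Azimuthally averaged power spectrum of the (edge-tapered) image; the noise
#' floor is the mean over the last `n_floor` radial bins and the cut-off is
#' the highest frequency at which the spectrum still reaches `threshold`
#' times the floor.
#'
#' @param ref a `reference_image` or matrix (with `pitch`).
#' @param pitch pixel size (m) when `ref` is a matrix.
#' @param edge_frac standard deviation of the error-function edge taper, as a
#'   fraction of the image side.
#' @param n_floor number of highest-frequency bins averaged into the floor.
#' @param threshold cut-off criterion in multiples of the noise floor.
#' @return list of class `resolution_report`: `freq` (cycles/m), `power`,
#'   `noise_floor`, `cutoff_freq`, `full_period` (m), `half_period` (m),
#'   `flag` (`"ok"`, `"no_noise_floor"` or `"no_signal"`).
#' @export
fps_resolution <- function(ref, pitch = NULL, edge_frac = 0.02,
                           n_floor = 30L, threshold = 2) {
  rm_ <- ref_to_matrix(ref, pitch, fill = NA)
  img <- rm_$img; p <- rm_$pitch
  img[!is.finite(img)] <- mean(img, na.rm = TRUE)
  nr <- nrow(img); nc <- ncol(img)
  s_px <- edge_frac * min(nr, nc)
  wr <- stats::pnorm((seq_len(nr) - 1) / s_px - 2) *
        stats::pnorm((nr - seq_len(nr)) / s_px - 2)
  wc <- stats::pnorm((seq_len(nc) - 1) / s_px - 2) *
        stats::pnorm((nc - seq_len(nc)) / s_px - 2)
  wd <- outer(wr, wc)
  imw <- (img - mean(img)) * wd
  S <- Mod(stats::fft(imw))^2
  fy <- freq_vector(nr, p)
  fx <- freq_vector(nc, p)
  q <- sqrt(outer(fy^2, rep(1, nc)) + outer(rep(1, nr), fx^2))
  nyq <- 1 / (2 * p)
  df <- min(1 / (nr * p), 1 / (nc * p))
  sel <- q <= nyq & q > 0
  bin <- round(q[sel] / df)
  power <- as.numeric(tapply(S[sel], bin, mean))
  freq <- as.integer(names(tapply(S[sel], bin, mean))) * df
  o <- order(freq)
  freq <- freq[o]; power <- power[o]
  nb <- length(power)
  floor_bins <- max(nb - n_floor + 1, 1):nb
  noise_floor <- mean(power[floor_bins])
  flag <- "ok"
  if (noise_floor <= 0) {
    flag <- "no_noise_floor"
    cutoff_idx <- nb
  } else {
    above <- which(power >= threshold * noise_floor)
    if (!length(above)) {
      flag <- "no_signal"
      cutoff_idx <- NA_integer_
    } else cutoff_idx <- max(above)
  }
  cutoff_freq <- if (is.na(cutoff_idx)) NA_real_ else freq[cutoff_idx]
  structure(list(freq = freq, power = power, noise_floor = noise_floor,
                 cutoff_freq = cutoff_freq,
                 full_period = if (is.na(cutoff_freq)) NA_real_ else 1 / cutoff_freq,
                 half_period = if (is.na(cutoff_freq)) NA_real_ else 1 / (2 * cutoff_freq),
                 flag = flag), class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("<resolution_report> floor %.3g, cutoff %.4g cycles/m (%s)\n",
              x$noise_floor, x$cutoff_freq, x$flag))
  if (is.finite(x$full_period))
    cat(sprintf("  full period %.4g m, half period %.4g m\n",
                x$full_period, x$half_period))
  invisible(x)
}
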