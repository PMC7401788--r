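#' White-field estimate from a scan
#'
#' Per-pixel median of the recorded frames: with the sample occluding any
#' given detector pixel in fewer than half of the frames, the median returns
#' the unobstructed illumination without needing an empty-beam exposure.
#'
#' @param scan a [scan_data()] (N >= 3 for a meaningful median).
#' @return matrix of white-field photon counts; masked pixels are NA.
#' @export
estimate_white_field <- function(scan) {
  N <- dim(scan$images)[3]
  if (N < 3) warning("fewer than 3 frames; median white field is weak")
  W <- apply(scan$images, c(1, 2), median)
  W[!scan$mask] <- NA_real_
  n_bad <- sum(!is.finite(W) | W <= 0) - sum(!scan$mask)
  if (n_bad > 0)
    warning(sprintf("%d unmasked pixels have a non-positive white field", n_bad))
  W
}

#' Initial pixel map from the astigmatic quadratic illumination
#'
#' Pure per-axis magnification: u_x = x z1x/(z1x + z), u_y = y z1y/(z1y + z),
#' i.e. the pixel map of an ideal (aberration-free) diverging beam.
#'
#' @param geometry an [xrt_geometry()].
#' @return array (rows, cols, 2) of reference-frame coordinates (m).
#' @export
initial_pixel_map <- function(geometry) {
  g <- geometry
  co <- det_coords(g)
  nr <- g$detector_shape[1]; nc <- g$detector_shape[2]
  z <- g$sample_detector
  u <- array(0, c(nr, nc, 2))
  u[, , 1] <- matrix(co$y * g$focus_sample_y / (g$focus_sample_y + z), nr, nc)
  u[, , 2] <- matrix(co$x * g$focus_sample_x / (g$focus_sample_x + z),
                     nr, nc, byrow = TRUE)
  u
}

#' Synthesize the undistorted reference image
#'
#' Deposits each white-field-normalized detector sample I_n(x)/W(x) at the
#' reference-frame position u(x) - dx_n with bilinear splatting and weight
#' W(x)^2; the reference is the weighted mean. Pixels without coverage are NA.
#'
#' @param scan a [scan_data()].
#' @param W white-field matrix (from [estimate_white_field()]).
#' @param u pixel map array (rows, cols, 2), metres.
#' @param pitch reference pixel size (m); defaults to the demagnified
#'   detector pixel.
#' @param pad margin in reference pixels around the covered area.
#' @return object of class `reference_image`: `image` (NA off coverage),
#'   `coverage` (summed splat weights), `count`, `pitch`, `origin` (m).
#' @export
build_reference <- function(scan, W, u, pitch = NULL, pad = 2L) {
  g <- scan$geometry
  if (is.null(pitch)) pitch <- derive_geometry(g)$demagnified_pixel
  mask <- scan$mask & is.finite(W) & (W > 0)
  Wc <- W; Wc[!mask] <- 0
  ty <- range(scan$translations[, 1]); tx <- range(scan$translations[, 2])
  lo <- c(min(u[, , 1]) - ty[2], min(u[, , 2]) - tx[2]) - pad * pitch
  hi <- c(max(u[, , 1]) - ty[1], max(u[, , 2]) - tx[1]) + pad * pitch
  shape <- as.integer(ceiling((hi - lo) / pitch)) + 1L
  res <- cpp_splat_reference(scan$images, Wc, mask, u, scan$translations,
                             lo, pitch, shape)
  if (all(res$den == 0)) stop("empty coverage: no sample lands on the reference grid")
  img <- res$num / res$den
  img[res$den == 0] <- NA_real_
  structure(list(image = img, coverage = res$den, count = res$count,
                 pitch = pitch, origin = lo), class = "reference_image")
}

#' @export
print.reference_image <- function(x, ...) {
  cat(sprintf("<reference_image> %d x %d px, pitch %.3g m, %.1f%% covered\n",
              nrow(x$image), ncol(x$image), x$pitch,
              100 * mean(x$coverage > 0)))
  invisible(x)
}

ref_cov <- function(ref) {
  cov <- matrix(0L, nrow(ref$image), ncol(ref$image))
  cov[ref$coverage > 0 & is.finite(ref$image)] <- 1L
  cov
}

ref_img0 <- function(ref) {
  img <- ref$image
  img[!is.finite(img)] <- 0
  img
}

#' Refine the pixel map against the current reference
#'
#' For every detector pixel the forward-model error
#' sum_n m(x) \[I_n(x) - W(x) I_ref(u' - dx_n)\]^2 is minimized over integer
#' reference-grid displacements of half-width `search_radius`, refined to
#' sub-pixel precision by a quadratic fit to the 3x3 error neighbourhood, and
#' (optionally) regularized by convolving the displacement update with a
#' Gaussian of standard deviation `reg_sigma` detector pixels.
#'
#' @inheritParams build_reference
#' @param ref a `reference_image`.
#' @param search_radius integer search half-width (reference pixels).
#' @param reg_sigma Gaussian regularization sigma (pixels); 0 disables. The
#'   regularization convolves the recovered pixel-shift field (the map's
#'   deviation from `base_map`), not the per-iteration increment.
#' @param min_frames minimum frames with coverage for a valid comparison;
#'   pixels below keep their previous map value and are flagged.
#' @param flat_tol relative contrast below which the error surface is deemed
#'   degenerate (flat); such pixels keep their previous value and are
#'   flagged.
#' @param signal_tol pixels whose frame-to-frame contrast variance (see
#'   [pixel_contrast_variance()]) is below this fraction of the scan's 90th
#'   percentile are treated as featureless: they keep their previous value
#'   and are flagged. 0 disables.
#' @param keep optional logical array (rows, cols, N) selecting the samples
#'   to use (e.g. a split-half subset); others are ignored.
#' @param base_map reference map against which pixel shifts are defined for
#'   the regularization; the ideal magnification map of `scan$geometry` when
#'   NULL.
#' @return updated pixel map array with attributes `du` (reference pixels)
#'   and `flagged` (logical matrix).
#' @export
update_pixel_map <- function(scan, W, ref, u, search_radius = 3L,
                             reg_sigma = 0, min_frames = 3L,
                             flat_tol = 1e-3, signal_tol = 0.05,
                             keep = NULL, base_map = NULL) {
  mask <- scan$mask & is.finite(W) & (W > 0)
  Wc <- W; Wc[!mask] <- 0
  imgs <- scan$images
  if (!is.null(keep)) imgs[!keep] <- NA_real_
  res <- cpp_update_pixel_map(imgs, Wc, mask, ref_img0(ref),
                              ref_cov(ref), u, scan$translations,
                              ref$origin, ref$pitch,
                              as.integer(search_radius),
                              as.integer(min_frames), flat_tol)
  du <- res$du
  flagged <- res$flagged
  if (signal_tol > 0) {
    pv <- pixel_contrast_variance(scan, W)
    featureless <- pv < signal_tol * stats::quantile(pv[mask], 0.9,
                                                     na.rm = TRUE)
    flagged <- flagged | featureless
  }
  ok <- mask & !flagged
  du[, , 1][!ok] <- 0
  du[, , 2][!ok] <- 0
  if (reg_sigma > 0) {
    # regularize the recovered pixel shifts, i.e. the accumulated deviation
    # of the map from the ideal magnification map, so drift from earlier
    # iterations is re-smoothed as well; flagged pixels inherit the value
    # interpolated from their informative neighbours
    if (is.null(base_map)) base_map <- initial_pixel_map(scan$geometry)
    dev1 <- u[, , 1] + ref$pitch * du[, , 1] - base_map[, , 1]
    dev2 <- u[, , 2] + ref$pitch * du[, , 2] - base_map[, , 2]
    dev1 <- smooth_field(dev1, reg_sigma, mask = ok, fill_masked = TRUE)
    dev2 <- smooth_field(dev2, reg_sigma, mask = ok, fill_masked = TRUE)
    u_new <- base_map
    u_new[, , 1] <- u_new[, , 1] + dev1
    u_new[, , 2] <- u_new[, , 2] + dev2
    du <- (u_new - u) / ref$pitch
  } else {
    u_new <- u + ref$pitch * du
  }
  attr(u_new, "du") <- du
  attr(u_new, "flagged") <- flagged
  u_new
}

#' Frame-to-frame contrast variance per detector pixel
#'
#' Sample variance over frames of the white-field-normalized counts. Pixels
#' whose variance is negligible saw the same transmission in every frame and
#' carry no tracking information (featureless background or untextured
#' sample regions).
#'
#' @inheritParams build_reference
#' @return matrix of variances.
#' @export
pixel_contrast_variance <- function(scan, W) {
  N <- dim(scan$images)[3]
  nr <- dim(scan$images)[1]; nc <- dim(scan$images)[2]
  m <- matrix(scan$images, nr * nc, N) / as.vector(W)
  s1 <- rowSums(m); s2 <- rowSums(m^2)
  v <- (s2 - s1^2 / N) / max(N - 1, 1)
  matrix(v, nr, nc)
}

#' Refine the sample translations
#'
#' Per frame, finds the global reference-frame offset minimizing that frame's
#' forward-model error (integer grid search plus sub-pixel quadratic fit).
#' The mean correction over frames is constrained to zero (gauge fixing: a
#' common shift of all translations is indistinguishable from a shift of u).
#'
#' @inheritParams update_pixel_map
#' @return updated N x 2 translation matrix with attribute `flagged`.
#' @export
update_translations <- function(scan, W, ref, u, search_radius = 3L) {
  mask <- scan$mask & is.finite(W) & (W > 0)
  Wc <- W; Wc[!mask] <- 0
  res <- cpp_update_translations(scan$images, Wc, mask, ref_img0(ref),
                                 ref_cov(ref), u, scan$translations,
                                 ref$origin, ref$pitch,
                                 as.integer(search_radius))
  corr <- -res$shift * ref$pitch
  ok <- !res$flagged
  if (any(ok)) corr <- sweep(corr, 2, colMeans(corr[ok, , drop = FALSE]))
  corr[!ok, ] <- 0
  out <- scan$translations + corr
  attr(out, "flagged") <- res$flagged
  out
}

#' Forward-model error decomposition
#'
#' @inheritParams update_pixel_map
#' @return list with `pixel_sse` (matrix), `frame_sse` (vector), `total` and
#'   `n_terms` (number of (frame, pixel) residuals summed); the
#'   decompositions sum exactly to the total.
#' @export
compute_error_map <- function(scan, W, ref, u) {
  mask <- scan$mask & is.finite(W) & (W > 0)
  Wc <- W; Wc[!mask] <- 0
  cpp_error_map(scan$images, Wc, mask, ref_img0(ref), ref_cov(ref),
                u, scan$translations, ref$origin, ref$pitch)
}

# curl-free projection of a pixel map (via the displacement potential)
project_pixel_map <- function(u, geometry) {
  g <- geometry
  co <- det_coords(g)
  nr <- g$detector_shape[1]; nc <- g$detector_shape[2]
  Y <- matrix(co$y, nr, nc)
  X <- matrix(co$x, nr, nc, byrow = TRUE)
  vy <- Y - u[, , 1]; vx <- X - u[, , 2]
  pot <- integrate_gradient(vy, vx, pitch = g$pixel_size, stagger = TRUE)
  cg <- centre_gradient(pot, pitch = g$pixel_size)
  out <- array(0, dim(u))
  out[, , 1] <- Y - cg$gy
  out[, , 2] <- X - cg$gx
  out
}

#' Run the full speckle-tracking reconstruction
#'
#' Orchestrates white-field estimation, quadratic pixel-map initialization and
#' the iterative loop: reference synthesis, pixel-map refinement (with a
#' scheduled Gaussian regularization), curl-free projection of the map and
#' translation refinement, logging the total forward-model error after each
#' iteration.
#'
#' @param scan a [scan_data()].
#' @param geometry geometry; defaults to `scan$geometry` (override after a
#'   defocus search).
#' @param n_iter number of iterations (>= 1).
#' @param search_radius search half-width in demagnified detector pixels;
#'   either a single value or one per iteration (a shrinking radius pairs
#'   naturally with a shrinking regularization kernel for coarse-to-fine
#'   refinement).
#' @param ref_oversample reference grid oversampling factor: the reference
#'   pitch is the demagnified pixel divided by this. Oversampling keeps the
#'   bilinear interpolation error of the reference sub-dominant.
#' @param reg_schedule vector of Gaussian sigmas (detector pixels), one per
#'   iteration; `NULL` disables regularization. See [reg_schedule_linear()].
#' @param refine_translations refine the sample translations each iteration.
#' @param project_irrotational enforce integrability of the phase gradients
#'   each iteration.
#' @param white_field optional white-field matrix; the per-pixel median of
#'   the frames when NULL. Supply a direct empty-beam measurement here when
#'   the scan range is too small for the median estimator.
#' @param min_frames minimum frame coverage per pixel comparison.
#' @param sse_tol relative tolerance on error increase; two consecutive
#'   violations abort the loop with a diagnostic.
#' @param verbose print per-iteration error.
#' @return list of class `pxst_result`: `reference`, `pixel_map`,
#'   `translations`, `white_field`, `wavefront` (see package docs), `sse`
#'   (per-iteration totals, element 1 = before any update), `sse_mean`
#'   (totals divided by the number of residual terms, comparable across
#'   iterations when coverage changes), `geometry`, `converged`.
#' @export
run_pxst <- function(scan, geometry = scan$geometry, n_iter = 3L,
                     search_radius = 3L, ref_oversample = 2L,
                     reg_schedule = NULL,
                     refine_translations = TRUE,
                     project_irrotational = TRUE,
                     white_field = NULL,
                     min_frames = 3L, sse_tol = 1e-3, verbose = FALSE) {
  stopifnot(n_iter >= 1)
  if (!is.null(reg_schedule) && length(reg_schedule) != n_iter)
    stop("reg_schedule must have one sigma per iteration")
  W <- if (is.null(white_field)) estimate_white_field(scan) else white_field
  u <- initial_pixel_map(geometry)
  u0_base <- u
  sc <- scan
  pitch_ref <- derive_geometry(geometry)$demagnified_pixel / ref_oversample
  if (!length(search_radius) %in% c(1L, n_iter))
    stop("search_radius must have length 1 or n_iter")
  radius_seq <- rep_len(as.integer(ceiling(search_radius * ref_oversample)),
                        n_iter)
  sse <- numeric(0)
  ref <- build_reference(sc, W, u, pitch = pitch_ref)
  e0 <- compute_error_map(sc, W, ref, u)
  sse <- c(sse, e0$total)
  sse_mean <- e0$total / max(e0$n_terms, 1)
  increases <- 0L
  converged <- TRUE
  for (it in seq_len(n_iter)) {
    sigma <- if (is.null(reg_schedule)) 0 else reg_schedule[it]
    u <- update_pixel_map(sc, W, ref, u, search_radius = radius_seq[it],
                          reg_sigma = sigma, min_frames = min_frames,
                          base_map = u0_base)
    if (project_irrotational) u <- project_pixel_map(u, geometry)
    if (refine_translations)
      sc$translations <- update_translations(sc, W, ref, u,
                                             search_radius = radius_seq[it])
    ref <- build_reference(sc, W, u, pitch = pitch_ref)
    e <- compute_error_map(sc, W, ref, u)
    sse <- c(sse, e$total)
    em <- e$total / max(e$n_terms, 1)
    sse_mean <- c(sse_mean, em)
    if (verbose)
      message(sprintf("iteration %d: sigma = %.1f px, SSE = %.6g (mean %.4g)",
                      it, sigma, e$total, em))
    if (em > sse_mean[length(sse_mean) - 1] * (1 + sse_tol)) {
      increases <- increases + 1L
      if (increases >= 2L) {
        warning(sprintf(
          "aborting: SSE increased for 2 consecutive iterations (at iteration %d)",
          it))
        converged <- FALSE
        break
      }
    } else increases <- 0L
  }
  wf <- make_wavefront(W, u, geometry, mask = scan$mask)
  structure(list(reference = ref, pixel_map = u,
                 translations = sc$translations, white_field = W,
                 wavefront = wf, sse = sse, sse_mean = sse_mean,
                 geometry = geometry,
                 converged = converged),
            class = "pxst_result")
}

#' @export
print.pxst_result <- function(x, ...) {
  cat(sprintf("<pxst_result> %d iterations, SSE %.4g -> %.4g\n",
              length(x$sse) - 1, x$sse[1], x$sse[length(x$sse)]))
  invisible(x)
}

#' Linear Gaussian regularization schedule
#'
#' Sigma reduced linearly from `from` to `to` pixels over the iterations, the
#' coarse-to-fine schedule that suppresses lattice-spacing mis-registration
#' on quasi-periodic samples.
#'
#' @param n_iter number of iterations.
#' @param from,to starting and final sigma (detector pixels).
#' @return numeric vector of length `n_iter`.
#' @export
reg_schedule_linear <- function(n_iter, from = 20, to = 0) {
  if (n_iter == 1) return(to)
  seq(from, to, length.out = n_iter)
}
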