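# Least-squares integration of 2D gradient fields and the curl-free
# (irrotational) projection.
#
# Discrete convention: the forward-difference operator D maps a potential on
# pixel centres to gradient samples on the staggered half-pixel grid; arrays
# keep full size with the last row/column zero. `phase_gradient()` is this
# operator; `integrate_gradient()` solves the corresponding normal equations
# with a DCT Poisson solver (Neumann boundaries, zero-mean gauge), so
# phase_gradient(integrate_gradient(g)) is an exact orthogonal projection
# onto discretely curl-free fields.

#' Discrete gradient of a potential
#'
#' Forward differences on the staggered grid (last row/column zero).
#'
#' @param phi matrix (potential, e.g. phase in rad).
#' @param pitch grid spacing (m); gradients are per metre.
#' @return list with `gy`, `gx` matrices of `dim(phi)`.
#' @export
phase_gradient <- function(phi, pitch = 1) {
  nr <- nrow(phi); nc <- ncol(phi)
  gy <- matrix(0, nr, nc); gx <- matrix(0, nr, nc)
  gy[-nr, ] <- (phi[-1, ] - phi[-nr, ]) / pitch
  gx[, -nc] <- (phi[, -1] - phi[, -nc]) / pitch
  list(gy = gy, gx = gx)
}

# centre-sampled gradient: central differences inside, second-order
# one-sided stencils at the edges (exact for quadratics, so the dominant
# spherical term carries no boundary bias)
centre_gradient <- function(phi, pitch = 1) {
  nr <- nrow(phi); nc <- ncol(phi)
  gy <- matrix(0, nr, nc); gx <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (phi[3:nr, ] - phi[1:(nr - 2), ]) / (2 * pitch)
  gy[1, ] <- (-3 * phi[1, ] + 4 * phi[2, ] - phi[3, ]) / (2 * pitch)
  gy[nr, ] <- (3 * phi[nr, ] - 4 * phi[nr - 1, ] + phi[nr - 2, ]) / (2 * pitch)
  gx[, 2:(nc - 1)] <- (phi[, 3:nc] - phi[, 1:(nc - 2)]) / (2 * pitch)
  gx[, 1] <- (-3 * phi[, 1] + 4 * phi[, 2] - phi[, 3]) / (2 * pitch)
  gx[, nc] <- (3 * phi[, nc] - 4 * phi[, nc - 1] + phi[, nc - 2]) / (2 * pitch)
  list(gy = gy, gx = gx)
}

#' Least-squares 2D integration of a gradient field
#'
#' Recovers the potential whose discrete gradient best matches the input, via
#' a DCT-based Poisson solve with reflective (Neumann) boundaries and a
#' zero-mean gauge. With `stagger = TRUE` the input is taken as pixel-centre
#' samples of a continuous gradient and is first averaged onto the staggered
#' half-pixel grid (exact for potentials up to quadratic order); with
#' `stagger = FALSE` the input is taken as forward-difference samples as
#' produced by [phase_gradient()].
#'
#' Disconnected regions of `mask` are integrated independently, each with its
#' own zero-mean gauge, and their count is reported via the
#' `"n_components"` attribute.
#'
#' @param gy,gx gradient components (matrices, per metre).
#' @param pitch grid spacing (m).
#' @param stagger average centre samples to the staggered grid first.
#' @param mask optional logical matrix of valid pixels.
#' @return potential matrix (zero mean over the mask).
#' @export
integrate_gradient <- function(gy, gx, pitch = 1, stagger = FALSE,
                               mask = NULL) {
  nr <- nrow(gy); nc <- ncol(gy)
  stopifnot(all(dim(gx) == c(nr, nc)))
  if (nr < 2 || nc < 2) stop("grid too small to integrate")
  if (stagger) {
    sy <- matrix(0, nr, nc); sx <- matrix(0, nr, nc)
    sy[-nr, ] <- (gy[-nr, ] + gy[-1, ]) / 2
    sx[, -nc] <- (gx[, -nc] + gx[, -1]) / 2
    gy <- sy; gx <- sx
  } else {
    gy[nr, ] <- 0; gx[, nc] <- 0
  }
  solve_rect <- function(gy, gx) {
    # rhs = D^T g (adjoint of the forward difference), per axis
    rhs <- matrix(0, nrow(gy), ncol(gy))
    n1 <- nrow(gy); n2 <- ncol(gy)
    rhs[1, ] <- rhs[1, ] - gy[1, ] / pitch
    if (n1 > 2) rhs[2:(n1 - 1), ] <- rhs[2:(n1 - 1), ] +
        (gy[1:(n1 - 2), ] - gy[2:(n1 - 1), ]) / pitch
    rhs[n1, ] <- rhs[n1, ] + gy[n1 - 1, ] / pitch
    rhs[, 1] <- rhs[, 1] - gx[, 1] / pitch
    if (n2 > 2) rhs[, 2:(n2 - 1)] <- rhs[, 2:(n2 - 1)] +
        (gx[, 1:(n2 - 2)] - gx[, 2:(n2 - 1)]) / pitch
    rhs[, n2] <- rhs[, n2] + gx[, n2 - 1] / pitch
    phi <- poisson_solve_neumann(rhs, hy = pitch, hx = pitch)
    phi - mean(phi)
  }
  if (is.null(mask) || all(mask)) {
    phi <- solve_rect(gy, gx)
    attr(phi, "n_components") <- 1L
    return(phi)
  }
  lab <- label_components(mask)
  ncomp <- max(lab)
  phi <- matrix(NA_real_, nr, nc)
  for (k in seq_len(ncomp)) {
    sel <- lab == k
    ii <- range(which(rowSums(sel) > 0))
    jj <- range(which(colSums(sel) > 0))
    gys <- gy[ii[1]:ii[2], jj[1]:jj[2], drop = FALSE]
    gxs <- gx[ii[1]:ii[2], jj[1]:jj[2], drop = FALSE]
    sels <- sel[ii[1]:ii[2], jj[1]:jj[2], drop = FALSE]
    gys[!sels] <- 0; gxs[!sels] <- 0
    if (any(dim(gys) < 2)) next
    ph <- solve_rect(gys, gxs)
    ph <- ph - mean(ph[sels])
    sub <- phi[ii[1]:ii[2], jj[1]:jj[2], drop = FALSE]
    sub[sels] <- ph[sels]
    phi[ii[1]:ii[2], jj[1]:jj[2]] <- sub
  }
  if (ncomp > 1L)
    warning(sprintf("mask has %d disconnected regions; integrated independently",
                    ncomp))
  attr(phi, "n_components") <- as.integer(ncomp)
  phi
}

#' Projection onto curl-free (integrable) gradient fields
#'
#' Integrates the input field in the least-squares sense and differentiates
#' the result again; the composition is an exact orthogonal projection for
#' the package's staggered discretization, hence idempotent to machine
#' precision.
#'
#' @inheritParams integrate_gradient
#' @return list with projected `gy`, `gx` and the potential `phi`.
#' @export
irrotational_projection <- function(gy, gx, pitch = 1) {
  phi <- integrate_gradient(gy, gx, pitch = pitch, stagger = FALSE)
  g <- phase_gradient(phi, pitch = pitch)
  list(gy = g$gy, gx = g$gx, phi = phi)
}
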