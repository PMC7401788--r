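# shared numerical helpers

rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))

# orthonormal DCT-II basis matrix, cached per size
.dct_cache <- new.env(parent = emptyenv())
dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  D[1, ] <- D[1, ] / sqrt(2)
  .dct_cache[[key]] <- D
  D
}

dct2 <- function(X) {
  Dr <- dct_matrix(nrow(X)); Dc <- dct_matrix(ncol(X))
  Dr %*% X %*% t(Dc)
}

idct2 <- function(Y) {
  Dr <- dct_matrix(nrow(Y)); Dc <- dct_matrix(ncol(Y))
  t(Dr) %*% Y %*% Dc
}

# Solve (Ly/hy^2 + Lx/hx^2) phi = rhs with homogeneous Neumann boundaries,
# where L is the 1D forward-difference normal matrix D^T D. Zero-mean gauge.
poisson_solve_neumann <- function(rhs, hy = 1, hx = 1) {
  nr <- nrow(rhs); nc <- ncol(rhs)
  ly <- 4 * sin(pi * (0:(nr - 1)) / (2 * nr))^2 / hy^2
  lx <- 4 * sin(pi * (0:(nc - 1)) / (2 * nc))^2 / hx^2
  den <- outer(ly, lx, `+`)
  co <- dct2(rhs)
  co <- co / den
  co[1, 1] <- 0
  idct2(co)
}

# frequency vector (cycles per unit) for an n-point grid of pitch p,
# fftshift = FALSE gives the raw fft ordering
freq_vector <- function(n, p = 1) {
  f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) / (n * p)
  f[seq_len(n)]
}

fftshift2 <- function(X) {
  nr <- nrow(X); nc <- ncol(X)
  X[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
}

# normalized separable Gaussian smoothing (band-matrix form; edge-corrected,
# optionally mask-aware). sigma in pixels; sigma = 0 returns x unchanged.
# With fill_masked = TRUE, off-mask pixels receive the value interpolated
# from on-mask neighbours within the kernel support (where any exist)
# instead of their original value.
smooth_field <- function(x, sigma, mask = NULL, fill_masked = FALSE) {
  if (sigma <= 0) return(x)
  blur1 <- function(n) {
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
    K[abs(outer(idx, idx, `-`)) > ceiling(4 * sigma)] <- 0
    K
  }
  Kr <- blur1(nrow(x)); Kc <- blur1(ncol(x))
  if (is.null(mask)) {
    num <- Kr %*% x %*% Kc
    den <- Kr %*% matrix(1, nrow(x), ncol(x)) %*% Kc
  } else {
    m <- 1 * mask
    xm <- x; xm[!mask] <- 0
    num <- Kr %*% xm %*% Kc
    den <- Kr %*% m %*% Kc
  }
  out <- num / pmax(den, .Machine$double.eps)
  if (!is.null(mask)) {
    if (fill_masked) {
      starved <- den < 1e-3
      out[starved] <- x[starved]
    } else out[!mask] <- x[!mask]
  }
  out
}

# connected-component labels of a logical matrix (4-connectivity)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (p - 1L) %% nr + 1L
      j <- (p - 1L) %/% nr + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
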