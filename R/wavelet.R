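## Orthogonal periodic Daubechies-4 wavelet transform.
##
## The sparsifying transform of the L1-SENSE reconstruction. Implemented as
## cached dense orthogonal per-level matrices: at the grid sizes used here
## (<= 256) a dense multiply is fast, exactly orthogonal to machine
## precision, and works directly on complex matrices.

# 4-tap Daubechies scaling filter (orthonormal)
.db4_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))

.wavelet_cache <- new.env(parent = emptyenv())

## One analysis level as an s x s orthogonal matrix: rows 1..s/2 produce the
## approximation coefficients, rows s/2+1..s the details, with periodic
## (circular) boundary handling.
wavelet_level_matrix <- function(s) {
  key <- as.character(s)
  if (!is.null(.wavelet_cache[[key]])) return(.wavelet_cache[[key]])
  if (s %% 2L != 0L || s < 4L) {
    stop("wavelet level requires an even size >= 4, got ", s)
  }
  h <- .db4_h
  g <- c(h[4], -h[3], h[2], -h[1])  # quadrature mirror filter
  half <- s %/% 2L
  W <- matrix(0, s, s)
  for (j in seq_len(half)) {
    cols <- ((2L * (j - 1L) + 0:3) %% s) + 1L
    for (k in 1:4) {
      W[j, cols[k]] <- W[j, cols[k]] + h[k]
      W[half + j, cols[k]] <- W[half + j, cols[k]] + g[k]
    }
  }
  .wavelet_cache[[key]] <- W
  W
}

check_wavelet_geometry <- function(n, levels) {
  if (levels < 1L) stop("`n_levels` must be >= 1")
  if (n %% 2L^levels != 0L || n / 2L^(levels - 1L) < 4) {
    stop(sprintf(
      "grid size %d does not support %d wavelet levels (needs n divisible by %d and n/%d >= 4)",
      n, levels, 2L^levels, 2L^(levels - 1L)
    ))
  }
  invisible(TRUE)
}

#' 2-D periodic Daubechies-4 wavelet transform
#'
#' Multi-level separable orthogonal discrete wavelet transform with periodic
#' boundaries, in the standard in-place quadrant layout: after `levels`
#' levels the top-left `n/2^levels` square block holds the coarsest
#' approximation band, everything else holds detail coefficients.
#' The transform is exactly orthogonal, so `idwt2(dwt2(x)) == x` to machine
#' precision and the soft-thresholding proximal step of the L1-SENSE
#' objective is exact.
#'
#' @param x square numeric or complex matrix; side length must be divisible
#'   by `2^levels`
#' @param levels decomposition depth (default 3)
#' @return matrix of wavelet coefficients (same size)
#' @seealso [detail_mask()] for addressing the detail bands
#' @export
dwt2 <- function(x, levels = 3L) {
  n <- nrow(x)
  stopifnot(ncol(x) == n)
  check_wavelet_geometry(n, levels)
  for (l in seq_len(levels)) {
    s <- n %/% 2L^(l - 1L)
    W <- wavelet_level_matrix(s)
    x[1:s, 1:s] <- W %*% x[1:s, 1:s] %*% t(W)
  }
  x
}

#' @rdname dwt2
#' @export
idwt2 <- function(x, levels = 3L) {
  n <- nrow(x)
  stopifnot(ncol(x) == n)
  check_wavelet_geometry(n, levels)
  for (l in rev(seq_len(levels))) {
    s <- n %/% 2L^(l - 1L)
    W <- wavelet_level_matrix(s)
    x[1:s, 1:s] <- t(W) %*% x[1:s, 1:s] %*% W
  }
  x
}

#' Logical mask of detail coefficients in the quadrant layout
#'
#' `TRUE` everywhere except the coarsest approximation block. Thresholding
#' is by default applied only where this mask is `TRUE`, preserving bulk
#' image contrast.
#'
#' @param n grid side length
#' @param levels decomposition depth
#' @return `n x n` logical matrix
#' @export
detail_mask <- function(n, levels = 3L) {
  check_wavelet_geometry(n, levels)
  s <- n %/% 2L^levels
  m <- matrix(TRUE, n, n)
  m[1:s, 1:s] <- FALSE
  m
}
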