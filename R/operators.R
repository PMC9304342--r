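## The SENSE encoding operator E = mask . Fourier . coil-weighting and its
## adjoint, plus the per-group unfolding machinery for equidistant masks.

#' Build the SENSE encoding operator for a coil set and sampling mask
#'
#' Returns closures for the forward map `E x` (image to masked multi-coil
#' k-space), its adjoint `E^H y`, and the normal operator `E^H E`. All use
#' the unitary centered FFT, so `<Ex, y> == <x, E^H y>` holds to machine
#' precision (the adjoint test).
#'
#' @param coils a `coil_maps`
#' @param mask a `sampling_mask` over the same grid
#' @return list of functions `forward(x)`, `adjoint(y)`, `normal(x)`
#' @export
encoding_operator <- function(coils, mask) {
  n <- coils$grid_size
  if (mask$n_lines != n) stop("mask/coil grid size mismatch")
  nc <- coils$n_coils
  maps <- coils$maps
  conj_maps <- Conj(maps)
  rows <- mask_rows(mask)
  drop_rows <- setdiff(seq_len(n), rows)

  forward <- function(x) {
    y <- array(0i, dim = c(n, n, nc))
    for (c in seq_len(nc)) {
      kc <- fft2c(maps[, , c] * x)
      if (length(drop_rows)) kc[drop_rows, ] <- 0i
      y[, , c] <- kc
    }
    y
  }
  adjoint <- function(y) {
    x <- matrix(0i, n, n)
    for (c in seq_len(nc)) {
      yc <- y[, , c]
      if (length(drop_rows)) yc[drop_rows, ] <- 0i
      x <- x + conj_maps[, , c] * ifft2c(yc)
    }
    x
  }
  list(forward = forward, adjoint = adjoint,
       normal = function(x) adjoint(forward(x)),
       n = n, n_coils = nc, mask = mask)
}

## For an equidistant mask with R | n the normal operator E^H E couples only
## pixels in the same column whose rows differ by multiples of n/R (the
## aliasing group). The R x R blocks are extracted exactly by applying
## E^H E to the R row-band indicator images: each group has exactly one
## member per band, so column j of its block is read off the band-j result.
## Returns array (R, R, n/R, n): block[, , r0, col].
unfolding_blocks <- function(op, R) {
  n <- op$n
  if (n %% R != 0L) stop("R must divide the number of lines for unfolding")
  m <- n %/% R
  blocks <- array(0i, dim = c(R, R, m, n))
  for (j in seq_len(R)) {
    u <- matrix(0i, n, n)
    u[((j - 1L) * m + 1L):(j * m), ] <- 1 + 0i
    w <- op$normal(u)
    for (jp in seq_len(R)) {
      # rows r0 + (jp-1)*m, all r0, all columns at once
      blocks[jp, j, , ] <- w[((jp - 1L) * m + 1L):(jp * m), ]
    }
  }
  blocks
}

## Exact per-group SENSE solve of (E^H E + l2 I) x = z for R | n.
## Errors on a singular group when l2 = 0, naming the group.
unfold_solve <- function(z, blocks, l2_reg = 0) {
  R <- dim(blocks)[1]
  m <- dim(blocks)[3]
  n <- dim(blocks)[4]
  x <- matrix(0i, n, n)
  ridge <- diag(l2_reg + 0i, R)
  for (col in seq_len(n)) {
    for (r0 in seq_len(m)) {
      rows <- r0 + (0:(R - 1)) * m
      A <- matrix(blocks[, , r0, col], R, R) + ridge
      sol <- tryCatch(solve(A, z[rows, col]), error = function(e) NULL)
      if (is.null(sol)) {
        stop(sprintf(
          "rank-deficient unfolding group (rows %s, column %d); set l2_reg > 0",
          paste(rows, collapse = "/"), col))
      }
      x[rows, col] <- sol
    }
  }
  x
}

## Conjugate gradients on the (Hermitian PSD) regularized normal equations;
## used when R does not divide the line count (no clean aliasing groups).
cg_solve <- function(op, z, l2_reg = 0, tol = 1e-10, max_iter = 400L) {
  inner <- function(a, b) Re(sum(Conj(a) * b))
  x <- matrix(0i, op$n, op$n)
  r <- z
  p <- r
  rs <- inner(r, r)
  rs0 <- rs
  if (rs0 == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- op$normal(p) + l2_reg * p
    alpha <- rs / inner(p, Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- inner(r, r)
    if (rs_new / rs0 < tol^2) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' Estimate the largest eigenvalue of the normal operator by power iteration
#'
#' Deterministic start (structured ones image); used to set the FISTA step
#' size. The estimate is inflated by 5% to serve as an upper bound (for
#' RSS-normalized coil maps the true value never exceeds 1).
#'
#' @param op an [encoding_operator()]
#' @param iters number of power iterations
#' @return estimated spectral bound `L`
#' @export
power_iteration_bound <- function(op, iters = 30L) {
  n <- op$n
  v <- matrix(1 + 0i, n, n) + outer(seq_len(n), seq_len(n)) / n^2
  lam <- NA_real_
  for (it in seq_len(iters)) {
    w <- op$normal(v)
    nw <- sqrt(Re(sum(Conj(w) * w)))
    if (!is.finite(nw) || nw == 0) stop("power iteration failed (degenerate operator)")
    lam <- Re(sum(Conj(v) * w)) / Re(sum(Conj(v) * v))
    v <- w / nw
  }
  if (!is.finite(lam) || lam <= 0) stop("power iteration failed to produce a positive bound")
  1.05 * lam
}
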