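## Smooth multi-coil sensitivity profiles (torso phased-array stand-in).

#' Generate smooth complex coil sensitivity maps
#'
#' Coils are placed on a circle around the field of view; each has a broad
#' Gaussian magnitude profile and a low-order (linear) phase ramp with small
#' seeded jitter. Maps are normalized so the root-sum-of-squares across
#' coils equals 1 at every pixel, which makes the SENSE forward operator a
#' contraction (largest singular value <= 1) and keeps reconstructed signal
#' on the phantom's scale. With distinct coil positions every equidistant
#' unfolding group at R <= n_coils is full rank.
#'
#' @param n_coils number of receive channels (>= 1); a single coil returns
#'   the uniform unit map
#' @param grid_size pixels per dimension
#' @param seed integer seed for the placement jitter
#' @return a `coil_maps` object: complex array `maps` of dim
#'   `(grid_size, grid_size, n_coils)`
#' @export
make_coil_maps <- function(n_coils, grid_size, seed = 1L) {
  n_coils <- as.integer(n_coils)
  if (is.na(n_coils) || n_coils < 1L) stop("`n_coils` must be >= 1")
  n <- as.integer(grid_size)
  maps <- array(0i, dim = c(n, n, n_coils))
  if (n_coils == 1L) {
    maps[, , 1] <- 1 + 0i
    return(structure(list(maps = maps, n_coils = 1L, grid_size = n, seed = seed),
                     class = "coil_maps"))
  }
  with_seed(seed, {
    ang_jit <- stats::rnorm(n_coils, 0, 0.1)
    ramp <- matrix(stats::runif(2 * n_coils, -0.3, 0.3), ncol = 2)
    ph0 <- stats::runif(n_coils, 0, 2 * pi)
  })
  ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  cy <- n / 2; cx <- n / 2
  sigma <- 0.45 * n
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils + ang_jit[c]
    pos_i <- cy + 0.55 * n * sin(ang)
    pos_j <- cx + 0.55 * n * cos(ang)
    d2 <- (ij$i - pos_i)^2 + (ij$j - pos_j)^2
    mag <- exp(-d2 / (2 * sigma^2)) + 0.05
    phase <- ph0[c] + 2 * pi * (ramp[c, 1] * (ij$i - cy) + ramp[c, 2] * (ij$j - cx)) / n
    maps[, , c] <- matrix(mag * exp(1i * phase), n, n)
  }
  rss <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / rss
  structure(list(maps = maps, n_coils = n_coils, grid_size = n, seed = seed),
            class = "coil_maps")
}

#' @export
print.coil_maps <- function(x, ...) {
  cat(sprintf("<coil_maps> %d coil(s) on a %dx%d grid (RSS-normalized)\n",
              x$n_coils, x$grid_size, x$grid_size))
  invisible(x)
}

#' Smallest singular value of every SENSE unfolding group
#'
#' For an equidistant mask with `R | n`, each column splits into groups of
#' `R` pixels aliased onto each other; the per-group coil matrix
#' (`n_coils x R`, entries `s_c(p)`) must be full rank for exact unfolding.
#' Returns the minimum over all groups of the smallest singular value —
#' strictly positive means every group is solvable.
#'
#' @param coils a `coil_maps`
#' @param R acceleration factor dividing the grid size
#' @return smallest singular value across all unfolding groups
#' @export
min_unfolding_singular_value <- function(coils, R) {
  n <- coils$grid_size
  if (n %% R != 0L) stop("R must divide the grid size for group analysis")
  m <- n %/% R
  smin <- Inf
  for (col in seq_len(n)) {
    for (r0 in seq_len(m)) {
      rows <- r0 + (0:(R - 1)) * m
      S <- t(matrix(coils$maps[rows, col, ], nrow = R))  # n_coils x R
      smin <- min(smin, min(svd(S, nu = 0, nv = 0)$d))
    }
  }
  smin
}
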