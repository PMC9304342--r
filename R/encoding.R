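## Forward encoding: image -> multi-coil k-space, equidistant undersampling,
## complex Gaussian noise injection, and signal-free noise scans.

#' Equidistant Cartesian sampling mask
#'
#' The phase-encode sampling pattern of accelerated single-shot EPI: every
#' `R`-th line is kept, starting at `offset` (0-based line index). By
#' default `offset = (n_lines/2) %% R`, which guarantees the centered DC
#' line (stored at 0-based row `n_lines/2`) is sampled.
#'
#' @param n_lines total number of phase-encode lines (grid rows)
#' @param R integer acceleration factor (>= 1)
#' @param offset 0-based index of the first kept line, `0 <= offset < R`
#' @return a `sampling_mask` with 0-based `kept_lines`
#' @export
sampling_mask <- function(n_lines, R, offset = NULL) {
  n_lines <- as.integer(n_lines); R <- as.integer(R)
  if (is.na(R) || R < 1L) stop("`R` must be an integer >= 1")
  if (is.null(offset)) offset <- (n_lines %/% 2L) %% R
  offset <- as.integer(offset)
  if (offset < 0L || offset >= R) stop("`offset` must satisfy 0 <= offset < R")
  kept <- seq.int(offset, n_lines - 1L, by = R)
  structure(list(kept_lines = kept, R = R, offset = offset, n_lines = n_lines),
            class = "sampling_mask")
}

## 1-based row indices of the kept lines
mask_rows <- function(mask) mask$kept_lines + 1L

masks_equal <- function(a, b) {
  identical(a$R, b$R) && identical(a$offset, b$offset) &&
    identical(a$n_lines, b$n_lines)
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> R=%d offset=%d: %d/%d lines kept\n",
              x$R, x$offset, length(x$kept_lines), x$n_lines))
  invisible(x)
}

#' Encode a DWI series into fully sampled multi-coil k-space
#'
#' For each b-value, average and coil: `k = fft2c(s_c * image)` with the
#' unitary centered Fourier transform, so per-coil k-space energy equals
#' coil-weighted image energy (Parseval). Averages (NSA) are stored
#' separately and identical before noise injection.
#'
#' @param series a `bvalue_series` from [simulate_dwi_series()]
#' @param coils a `coil_maps` on the same grid
#' @param n_averages number of signal acquisitions (NSA), default 4
#' @return a `kspace_series` with complex `data` of dim
#'   `(ky, kx, coil, average, b)`, a full (`R = 1`) mask and `noise_sd = 0`
#' @export
encode <- function(series, coils, n_averages = 4L) {
  stopifnot(inherits(series, "bvalue_series"), inherits(coils, "coil_maps"))
  n <- series$grid_size
  if (coils$grid_size != n) stop("grid size mismatch between series and coil maps")
  n_averages <- as.integer(n_averages)
  if (n_averages < 1L) stop("`n_averages` must be >= 1")
  nb <- length(series$b_values)
  nc <- coils$n_coils
  data <- array(0i, dim = c(n, n, nc, n_averages, nb))
  for (bi in seq_len(nb)) {
    img <- series$images[, , bi]
    for (c in seq_len(nc)) {
      kc <- fft2c(coils$maps[, , c] * img)
      for (a in seq_len(n_averages)) data[, , c, a, bi] <- kc
    }
  }
  structure(
    list(data = data, mask = sampling_mask(n, 1L, 0L), noise_sd = 0,
         b_values = series$b_values, n_averages = n_averages,
         n_coils = nc, grid_size = n),
    class = "kspace_series"
  )
}

#' @export
print.kspace_series <- function(x, ...) {
  cat(sprintf("<kspace_series> %dx%d, %d coil(s), NSA=%d, b = %s, R=%d, noise_sd=%g\n",
              x$grid_size, x$grid_size, x$n_coils, x$n_averages,
              paste(x$b_values, collapse = "/"), x$mask$R, x$noise_sd))
  invisible(x)
}

#' Apply equidistant undersampling to a k-space series
#'
#' Zeroes every phase-encode line not in the mask and records the mask.
#' Idempotent for a fixed `(R, offset)`.
#'
#' @param k a `kspace_series`
#' @param R acceleration factor
#' @param offset 0-based first kept line (default: DC-preserving, see
#'   [sampling_mask()])
#' @return the undersampled `kspace_series`
#' @export
undersample <- function(k, R, offset = NULL) {
  stopifnot(inherits(k, "kspace_series"))
  mask <- sampling_mask(k$grid_size, R, offset)
  drop_rows <- setdiff(seq_len(k$grid_size), mask_rows(mask))
  k$data[drop_rows, , , , ] <- 0i
  k$mask <- mask
  k
}

#' Add complex Gaussian acquisition noise to sampled k-space entries
#'
#' i.i.d. complex Gaussian noise with standard deviation `sd` per real and
#' imaginary channel, independently for every coil, average and b-value, on
#' sampled lines only (no measurement exists elsewhere). White across coils.
#'
#' @param k a `kspace_series`
#' @param sd per-channel noise standard deviation (signal units)
#' @param seed integer seed; the same seed reproduces the realization
#' @return the noisy `kspace_series` (`noise_sd` recorded)
#' @export
add_noise <- function(k, sd, seed) {
  stopifnot(inherits(k, "kspace_series"))
  stop_if_not_scalar_number(sd, "sd")
  if (sd < 0) stop("`sd` must be >= 0")
  if (sd == 0) return(k)
  rows <- mask_rows(k$mask)
  d <- dim(k$data)
  n_entries <- length(rows) * d[2] * d[3] * d[4] * d[5]
  noise <- with_seed(seed, complex_noise(n_entries, sd))
  k$data[rows, , , , ] <- k$data[rows, , , , ] + noise
  k$noise_sd <- sd
  k
}

#' Simulate a signal-free noise scan
#'
#' The computational analogue of running the identical pulse sequence with
#' no radio-frequency excitation: the returned series has the same mask,
#' coil count, b-values and NSA as `template` but zero signal, with fresh
#' complex Gaussian noise on the sampled entries. Passing it through the
#' same reconstruction as the signal data yields the noise map used for SNR
#' measurement.
#'
#' @param template a `kspace_series` providing geometry and mask
#' @param sd per-channel noise standard deviation (> 0)
#' @param seed integer seed
#' @return a noise-only `kspace_series`
#' @export
simulate_noise_scan <- function(template, sd, seed) {
  stopifnot(inherits(template, "kspace_series"))
  stop_if_not_scalar_number(sd, "sd")
  if (sd <= 0) stop("`sd` must be > 0 for a noise scan")
  template$data[] <- 0i
  template$noise_sd <- 0
  add_noise(template, sd, seed)
}

#' Extract one (b-value, average) multi-coil k-space slice
#' @param k a `kspace_series`
#' @param b_index index into `k$b_values`
#' @param average index into averages
#' @return complex array `(ky, kx, coil)`
#' @export
kspace_slice <- function(k, b_index = 1L, average = 1L) {
  stopifnot(inherits(k, "kspace_series"))
  k$data[, , , average, b_index, drop = FALSE][, , , 1, 1, drop = TRUE] |>
    array(dim = dim(k$data)[1:3])
}
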