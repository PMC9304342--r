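## Shared numeric helpers: centered unitary FFTs and scoped RNG.

#' Circularly shift a matrix so the DC sample moves to the grid center
#'
#' Even-size analogue of the usual fftshift: element `[1, 1]` moves to
#' `[n/2 + 1, n/2 + 1]`. `ifftshift2` is its inverse (identical for even
#' sizes, which is all this package uses).
#'
#' @param x a matrix
#' @return the shifted matrix
#' @keywords internal
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2), drop = FALSE]
}

#' @rdname fftshift2
#' @keywords internal
ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2), drop = FALSE]
}

#' Unitary centered 2-D Fourier transform
#'
#' `fft2c` maps an image (spatial grid with its origin at pixel
#' `(n/2, n/2)` in 0-based coordinates) to k-space with the DC coefficient
#' stored at the grid center; `ifft2c` inverts it. The pair is unitary
#' (`sum(abs(k)^2) == sum(abs(img)^2)`), which is what makes Parseval
#' checks, the adjoint of the sampling operator and the proximal step of
#' the L1 reconstruction exact.
#'
#' @param x complex (or numeric) matrix
#' @return complex matrix of the same size
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

## complex white noise, sd per real/imaginary channel
complex_noise <- function(n, sd) {
  complex(real = stats::rnorm(n, sd = sd), imaginary = stats::rnorm(n, sd = sd))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
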