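## Quantitative readouts: ROI statistics, noise-map SNR, ADC mapping.

#' Define a region of interest as an explicit pixel set
#'
#' @param pixels 2-column integer matrix of `(row, col)` pixel coordinates
#'   (1-based)
#' @param label descriptive text
#' @return an `roi`
#' @export
roi <- function(pixels, label = "roi") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("ROI must contain at least one pixel")
  if (ncol(pixels) != 2L) stop("`pixels` must have two columns (row, col)")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, label = label), class = "roi")
}

check_roi_in_grid <- function(r, n) {
  if (any(r$pixels < 1L) || any(r$pixels > n)) {
    stop(sprintf("ROI '%s' has pixels outside the %dx%d grid", r$label, n, n))
  }
  invisible(TRUE)
}

roi_values <- function(image, r) {
  check_roi_in_grid(r, nrow(image))
  image[r$pixels]
}

#' Circular parenchyma ROIs placed automatically
#'
#' Mirrors manual ROI placement "in uniform parenchyma, avoiding vessels and
#' lesions": draws disc ROIs whose every pixel is pure parenchyma (label 1)
#' with a one-pixel safety margin, chosen deterministically from a seeded
#' candidate scan.
#'
#' @param truth a `phantom_truth`
#' @param n_rois number of ROIs (default 2, as in per-subject placement)
#' @param radius_px disc radius in pixels
#' @param seed integer seed
#' @return list of `roi` objects
#' @export
auto_parenchyma_rois <- function(truth, n_rois = 2L, radius_px = 4L, seed = 1L) {
  lab <- truth$label_map
  n <- nrow(lab)
  offs <- expand.grid(di = -(radius_px + 1L):(radius_px + 1L),
                      dj = -(radius_px + 1L):(radius_px + 1L))
  offs <- offs[sqrt(offs$di^2 + offs$dj^2) <= radius_px + 1, ]
  disc <- offs[sqrt(offs$di^2 + offs$dj^2) <= radius_px, ]
  cand <- which(lab == LABEL_PARENCHYMA, arr.ind = TRUE)
  cand <- cand[cand[, 1] > radius_px + 1 & cand[, 1] <= n - radius_px - 1 &
               cand[, 2] > radius_px + 1 & cand[, 2] <= n - radius_px - 1, , drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(cand)))
  rois <- list()
  taken <- matrix(FALSE, n, n)
  for (idx in ord) {
    ci <- cand[idx, 1]; cj <- cand[idx, 2]
    guard_px <- cbind(ci + offs$di, cj + offs$dj)
    if (all(lab[guard_px] == LABEL_PARENCHYMA) && !any(taken[guard_px])) {
      px <- cbind(ci + disc$di, cj + disc$dj)
      taken[guard_px] <- TRUE
      rois[[length(rois) + 1L]] <- roi(px, sprintf("parenchyma_%d", length(rois) + 1L))
      if (length(rois) == n_rois) break
    }
  }
  if (length(rois) < n_rois) {
    stop("could not place the requested number of parenchyma ROIs")
  }
  rois
}

#' Mean and sample standard deviation over an ROI
#'
#' @param image magnitude slice (matrix)
#' @param r an [roi()]
#' @return list with `mean`, `sd` (n-1 denominator; `NA` with a warning for
#'   a single-pixel ROI) and `n`
#' @export
roi_stats <- function(image, r) {
  v <- roi_values(image, r)
  if (length(v) == 1L) {
    warning("single-pixel ROI: sd is undefined")
    return(list(mean = mean(v), sd = NA_real_, n = 1L))
  }
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

provenance_matches <- function(a, b) {
  same_num <- function(x, y) isTRUE(all.equal(as.numeric(x), as.numeric(y)))
  identical(a$method, b$method) &&
    same_num(a$lam_abs, b$lam_abs) &&
    identical(a$mask, b$mask) &&
    identical(a$n_levels, b$n_levels)
}

#' SNR from a signal image and a reconstructed noise map
#'
#' `SNR = mean(signal ROI) / SD(noise ROI)`. The noise image must come from
#' passing a signal-free noise scan through the *same* reconstruction
#' operator (method, absolute regularization weight, mask) as the signal —
#' this is what lets the measurement capture the reconstruction's effect on
#' noise, including the nonlinear L1 case where no analytic propagation
#' exists. Enforced by comparing provenance; mismatches are an error.
#'
#' No Rayleigh/Rician correction is applied to the plain ratio by default; a
#' multiplicative correction factor can be supplied.
#'
#' @param signal_recon,noise_recon `recon_image` or `recon_series` objects
#'   (for a series, pick the slice with `b_index`)
#' @param roi_signal,roi_noise ROIs for the signal mean and the noise SD
#' @param b_index slice selector for `recon_series` inputs
#' @param correction multiplicative factor applied to the noise SD
#' @return an `snr_report` list: `snr`, `signal_mean`, `noise_sd`,
#'   `b_value`, `method`
#' @export
snr_from_noise_map <- function(signal_recon, noise_recon, roi_signal,
                               roi_noise, b_index = 1L, correction = 1) {
  get_mag <- function(x) {
    if (inherits(x, "recon_image")) x$magnitude
    else if (inherits(x, "recon_series")) x$magnitude[, , b_index]
    else stop("expected a recon_image or recon_series")
  }
  pa <- signal_recon$provenance; pb <- noise_recon$provenance
  if (!provenance_matches(pa, pb)) {
    stop("signal and noise images were not reconstructed with the same operator ",
         "(method/lam_abs/mask mismatch)")
  }
  s <- roi_stats(get_mag(signal_recon), roi_signal)
  nz <- roi_stats(get_mag(noise_recon), roi_noise)
  noise_sd <- nz$sd * correction
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise ROI SD must be positive")
  b_value <- if (inherits(signal_recon, "recon_series"))
    signal_recon$b_values[b_index] else NA_real_
  structure(list(snr = s$mean / noise_sd, signal_mean = s$mean,
                 noise_sd = noise_sd, b_value = b_value, method = pa$method),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("<snr_report> %s: SNR %.2f (signal %.3g / noise SD %.3g)\n",
              x$method, x$snr, x$signal_mean, x$noise_sd))
  invisible(x)
}

#' Per-pixel ADC map from a multi-b-value magnitude series
#'
#' Ordinary least-squares fit of `log S(b)` against `b` per pixel;
#' `ADC = -slope`, reported in 1e-3 mm^2/s. Pixels where any b-value signal
#' is non-positive (log undefined) are masked invalid. `method =
#' "two_point"` uses only the first and last b-values.
#'
#' @param series magnitude array `(n, n, n_b)`, a `recon_series`, or a list
#'   of magnitude matrices
#' @param b_values b-values in s/mm^2 (>= 2 required); taken from a
#'   `recon_series` automatically
#' @param method `"ols"` (all b-values) or `"two_point"`
#' @return an `adc_map`: `adc` (1e-3 mm^2/s), `fit_residual` (RMS log
#'   residual), `valid_mask`
#' @export
fit_adc <- function(series, b_values = NULL, method = c("ols", "two_point")) {
  method <- match.arg(method)
  if (inherits(series, "recon_series")) {
    b_values <- series$b_values
    series <- series$magnitude
  }
  if (is.list(series)) series <- simplify2array(series)
  if (is.null(b_values)) stop("`b_values` required")
  nb <- length(b_values)
  if (nb < 2L) stop("at least two b-values are required")
  stopifnot(dim(series)[3] == nb)
  n <- dim(series)[1]
  if (method == "two_point") {
    keep <- c(1L, nb)
    series <- series[, , keep, drop = FALSE]
    b_values <- b_values[keep]
    nb <- 2L
  }
  valid <- apply(series > 0, c(1, 2), all)
  S <- matrix(series, ncol = nb)  # pixels x b
  S[S <= 0] <- NA
  logS <- log(S)
  b <- b_values
  bc <- b - mean(b)
  # per-pixel OLS slope of log S on b; bc is centered so the intercept drops
  slope <- as.vector(logS %*% bc) / sum(bc^2)
  fitted <- outer(rowMeans(logS), rep(1, nb)) + outer(slope, bc)
  resid <- sqrt(rowMeans((logS - fitted)^2))
  adc <- matrix(-slope * 1e3, n, n)
  adc[!valid] <- NA_real_
  if (!any(valid)) warning("ADC map has no valid pixels")
  structure(list(adc = adc, fit_residual = matrix(resid, n, n),
                 valid_mask = valid, b_values = b_values, method = method),
            class = "adc_map")
}

#' ADC mean and SD over the valid pixels of an ROI
#'
#' @param map an `adc_map`
#' @param r an [roi()]
#' @return list with `mean`, `sd` (1e-3 mm^2/s) and `n` valid pixels
#' @export
adc_roi_summary <- function(map, r) {
  check_roi_in_grid(r, nrow(map$adc))
  valid <- map$valid_mask[r$pixels]
  if (!any(valid)) stop("ROI contains no valid ADC pixels")
  v <- map$adc[r$pixels][valid]
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n = length(v))
}

#' Analytic per-pixel noise SD of the linear SENSE reconstruction
#'
#' For k-space noise with per-channel SD `sigma` and an equidistant mask
#' with `R` dividing the line count, the unfolded pixel estimate has
#' per-channel noise variance `sigma^2 * R * [(S^H S)^{-1}]_pp` with `S` the
#' per-group coil matrix — the classical SENSE noise-amplification
#' (g-factor) expression, computed directly from the coil maps and mask,
#' independent of the reconstruction code. Used as the oracle for the
#' noise-map SNR pathway.
#'
#' @param coils a `coil_maps`
#' @param mask a `sampling_mask` with `R | n_lines`
#' @param sigma per-channel k-space noise SD
#' @return matrix of per-pixel per-channel noise SDs
#' @export
sense_noise_sd_analytic <- function(coils, mask, sigma) {
  n <- coils$grid_size
  R <- mask$R
  if (n %% R != 0L) stop("analytic propagation requires R | n_lines")
  m <- n %/% R
  out <- matrix(NA_real_, n, n)
  for (col in seq_len(n)) {
    for (r0 in seq_len(m)) {
      rows <- r0 + (0:(R - 1)) * m
      S <- t(matrix(coils$maps[rows, col, ], nrow = R))  # n_coils x R
      Ainv <- solve(Conj(t(S)) %*% S)
      out[rows, col] <- sigma * sqrt(R * Re(diag(Ainv)))
    }
  }
  out
}
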