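## Digital liver phantom: parenchyma, vessels, focal lesions, and the
## mono-exponential diffusion-weighted signal model.

LABEL_BACKGROUND <- 0L
LABEL_PARENCHYMA <- 1L
LABEL_VESSEL <- 2L
# lesion with id k is stored in the label map as LABEL_LESION_BASE + k
LABEL_LESION_BASE <- 2L

#' Describe a focal lesion to be rendered into a phantom
#'
#' @param center length-2 numeric, pixel coordinates `(row, col)` of the
#'   lesion center (1-based, may be fractional)
#' @param diameter_mm lesion diameter in mm; converted to pixels through the
#'   phantom's `pixel_size_mm`. Clinically interesting sizes here are 3-7 mm
#'   (the small-lesion regime) up to ~15 mm.
#' @param S0_contrast relative signal offset vs. parenchyma at b = 0
#'   (dimensionless; +0.2 means 20% hyperintense, negative values give
#'   cyst-like hypointense lesions)
#' @param lesion_ADC apparent diffusion coefficient inside the lesion, in
#'   1e-3 mm^2/s (default 0.6: restricted diffusion, metastasis-like)
#' @return a `lesion_spec` list
#' @export
lesion_spec <- function(center, diameter_mm, S0_contrast = 0.2, lesion_ADC = 0.6) {
  stopifnot(length(center) == 2L, is.numeric(center))
  stop_if_not_scalar_number(diameter_mm, "diameter_mm")
  if (diameter_mm <= 0) stop("`diameter_mm` must be > 0")
  stop_if_not_scalar_number(S0_contrast, "S0_contrast")
  stop_if_not_scalar_number(lesion_ADC, "lesion_ADC")
  if (lesion_ADC < 0) stop("`lesion_ADC` must be >= 0")
  structure(
    list(center = as.numeric(center), diameter_mm = diameter_mm,
         S0_contrast = S0_contrast, lesion_ADC = lesion_ADC),
    class = "lesion_spec"
  )
}

#' Specify a digital liver phantom
#'
#' Defaults follow a typical 1.5 T liver DWI protocol: 160 x 160 matrix,
#' 2.38 mm in-plane pixels, parenchymal ADC 0.94e-3 mm^2/s. All ADC values
#' in this package are stored in units of 1e-3 mm^2/s; the signal model
#' applies the 1e-3 factor explicitly (see [simulate_dwi_series()]).
#'
#' @param grid_size pixels per dimension (square grid, >= 32)
#' @param pixel_size_mm pixel edge length in mm
#' @param parenchyma_S0 b = 0 parenchyma signal, arbitrary units
#' @param parenchyma_ADC parenchyma ADC in 1e-3 mm^2/s
#' @param vessel_fraction target fraction of parenchyma pixels carved out as
#'   low-signal curvilinear vessels, in `[0, 1)`
#' @param lesion_specs list of [lesion_spec()] objects
#' @param seed integer seed controlling the liver outline deformation and
#'   vessel tree (phantom generation is fully deterministic given the spec)
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(grid_size = 160L, pixel_size_mm = 2.38,
                         parenchyma_S0 = 100, parenchyma_ADC = 0.94,
                         vessel_fraction = 0.03, lesion_specs = list(),
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 32L) stop("`grid_size` must be >= 32")
  if (parenchyma_S0 <= 0) stop("`parenchyma_S0` must be > 0")
  if (parenchyma_ADC <= 0) stop("`parenchyma_ADC` must be > 0")
  if (vessel_fraction < 0 || vessel_fraction >= 1) {
    stop("`vessel_fraction` must be in [0, 1)")
  }
  if (length(lesion_specs) && !all(vapply(lesion_specs, inherits, TRUE, "lesion_spec"))) {
    stop("`lesion_specs` must be a list of lesion_spec objects")
  }
  structure(
    list(grid_size = grid_size, pixel_size_mm = pixel_size_mm,
         parenchyma_S0 = parenchyma_S0, parenchyma_ADC = parenchyma_ADC,
         vessel_fraction = vessel_fraction, lesion_specs = lesion_specs,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

## Deformed-ellipse liver outline. Pixel (i, j) has 0-based coordinates
## (i-1, j-1); the image center sits at (n/2, n/2).
liver_mask <- function(n, seed) {
  with_seed(seed, {
    phase1 <- stats::runif(1, 0, 2 * pi)
    phase2 <- stats::runif(1, 0, 2 * pi)
    theta <- stats::runif(1, -0.2, 0.2)
  })
  cy <- n / 2; cx <- n / 2
  a <- 0.42 * n  # semi-axis along x
  b <- 0.34 * n  # semi-axis along y
  ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  dy <- ij$i - cy; dx <- ij$j - cx
  # rotate
  xr <- cos(theta) * dx + sin(theta) * dy
  yr <- -sin(theta) * dx + cos(theta) * dy
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  phi <- atan2(yr / b, xr / a)
  # smooth radial deformation keeps the region connected and organic-looking
  bound <- 1 + 0.06 * sin(3 * phi + phase1) + 0.04 * sin(5 * phi + phase2)
  matrix(r <= bound, n, n)
}

## Curvilinear vessels: seeded random walks inside the parenchyma.
carve_vessels <- function(parenchyma, target_fraction, seed) {
  n <- nrow(parenchyma)
  vessel <- matrix(FALSE, n, n)
  if (target_fraction <= 0) return(vessel)
  target <- target_fraction * sum(parenchyma)
  inside <- which(parenchyma)
  with_seed(seed + 7L, {
    guard <- 0L
    while (sum(vessel) < target && guard < 200L) {
      guard <- guard + 1L
      start <- inside[sample.int(length(inside), 1L)]
      i <- ((start - 1L) %% n) + 1L
      j <- ((start - 1L) %/% n) + 1L
      ang <- stats::runif(1, 0, 2 * pi)
      for (step in seq_len(3L * n)) {
        ang <- ang + stats::rnorm(1, 0, 0.25)
        i <- i + sin(ang); j <- j + cos(ang)
        ii <- round(i); jj <- round(j)
        if (ii < 1 || ii > n || jj < 1 || jj > n || !parenchyma[ii, jj]) break
        vessel[ii, jj] <- TRUE
        # 2-px thickness on alternating steps
        if (step %% 2L == 0L && ii < n && parenchyma[ii + 1L, jj]) {
          vessel[ii + 1L, jj] <- TRUE
        }
        if (sum(vessel) >= target) break
      }
    }
  })
  vessel
}

lesion_pixels <- function(les, n, pixel_size_mm) {
  r_px <- les$diameter_mm / pixel_size_mm / 2
  ci <- les$center[1]; cj <- les$center[2]
  rng_i <- max(1L, floor(ci - r_px - 1)):min(n, ceiling(ci + r_px + 1))
  rng_j <- max(1L, floor(cj - r_px - 1)):min(n, ceiling(cj + r_px + 1))
  px <- expand.grid(i = rng_i, j = rng_j)
  d <- sqrt((px$i - ci)^2 + (px$j - cj)^2)
  as.matrix(px[d <= r_px, c("i", "j"), drop = FALSE])
}

#' Render a phantom specification into per-pixel ground truth
#'
#' Builds a connected, deformed-elliptical liver parenchyma region covering
#' at least 40% of the grid, carves seeded curvilinear low-signal vessels,
#' and stamps each requested lesion as a hard-edged disc (optionally
#' anti-aliased in S0 via 4x4 supersampling, emulating partial-volume
#' averaging at lesion edges).
#'
#' @param spec a [phantom_spec()]
#' @param antialias logical; if `TRUE`, lesion edge pixels get
#'   fractional-coverage S0 (label/ADC stay hard-edged)
#' @return a `phantom_truth` list with `S0_map`, `ADC_map` (1e-3 mm^2/s),
#'   integer `label_map` (0 background, 1 parenchyma, 2 vessel, `2 + k` for
#'   lesion id `k`) and `lesion_registry` (named by lesion id)
#' @export
make_phantom <- function(spec, antialias = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  parenchyma <- liver_mask(n, spec$seed)
  vessel <- carve_vessels(parenchyma, spec$vessel_fraction, spec$seed)

  label <- matrix(LABEL_BACKGROUND, n, n)
  label[parenchyma] <- LABEL_PARENCHYMA
  label[vessel] <- LABEL_VESSEL

  S0 <- matrix(0, n, n)
  S0[parenchyma] <- spec$parenchyma_S0
  S0[vessel] <- 0.35 * spec$parenchyma_S0
  ADC <- matrix(0, n, n)
  ADC[parenchyma] <- spec$parenchyma_ADC
  ADC[vessel] <- 2.5  # fast pseudo-diffusion in blood

  registry <- list()
  for (k in seq_along(spec$lesion_specs)) {
    les <- spec$lesion_specs[[k]]
    px <- lesion_pixels(les, n, spec$pixel_size_mm)
    if (nrow(px) == 0L) {
      stop(sprintf("lesion %d renders to zero pixels (diameter below pixel size)", k))
    }
    lab <- label[px]
    if (any(lab == LABEL_BACKGROUND)) {
      stop(sprintf("lesion %d extends outside the parenchyma", k))
    }
    if (any(lab > LABEL_LESION_BASE)) {
      stop(sprintf("lesion %d overlaps lesion %d", k,
                   max(lab[lab > LABEL_LESION_BASE]) - LABEL_LESION_BASE))
    }
    label[px] <- LABEL_LESION_BASE + k
    S0[px] <- spec$parenchyma_S0 * (1 + les$S0_contrast)
    ADC[px] <- les$lesion_ADC
    if (antialias) {
      S0 <- antialias_lesion_S0(S0, les, spec, px)
    }
    registry[[as.character(k)]] <- les
  }

  structure(
    list(S0_map = S0, ADC_map = ADC, label_map = label,
         lesion_registry = registry, spec = spec),
    class = "phantom_truth"
  )
}

## fractional-coverage S0 at lesion edge pixels (4x4 supersampling)
antialias_lesion_S0 <- function(S0, les, spec, px) {
  r_px <- les$diameter_mm / spec$pixel_size_mm / 2
  ci <- les$center[1]; cj <- les$center[2]
  sub <- (seq_len(4) - 2.5) / 4
  offs <- expand.grid(di = sub, dj = sub)
  n <- nrow(S0)
  # edge band: pixels within 1 px of the boundary circle
  rng_i <- max(1L, floor(ci - r_px - 2)):min(n, ceiling(ci + r_px + 2))
  rng_j <- max(1L, floor(cj - r_px - 2)):min(n, ceiling(cj + r_px + 2))
  for (i in rng_i) for (j in rng_j) {
    d <- sqrt((i - ci)^2 + (j - cj)^2)
    if (abs(d - r_px) <= 1) {
      cov <- mean(sqrt((i + offs$di - ci)^2 + (j + offs$dj - cj)^2) <= r_px)
      base <- spec$parenchyma_S0
      S0[i, j] <- base * (1 + cov * les$S0_contrast)
    }
  }
  S0
}

#' @export
print.phantom_truth <- function(x, ...) {
  n <- nrow(x$S0_map)
  cat(sprintf("<phantom_truth> %dx%d grid, %.3g%% parenchyma, %d vessel px, %d lesion(s)\n",
              n, n, 100 * mean(x$label_map >= LABEL_PARENCHYMA), sum(x$label_map == LABEL_VESSEL),
              length(x$lesion_registry)))
  invisible(x)
}

#' Simulate the noiseless multi-b-value DWI signal of a phantom
#'
#' Mono-exponential diffusion model per pixel:
#' `S(b) = S0 * exp(-b * ADC * 1e-3)` with `b` in s/mm^2 and `ADC` stored in
#' 1e-3 mm^2/s. Images are complex with zero phase by default; an optional
#' smooth low-order background phase is available for stress-testing complex
#' reconstruction.
#'
#' @param truth a `phantom_truth`
#' @param b_values numeric vector, strictly increasing, first entry 0
#'   (default the liver protocol `c(0, 100, 400, 800)`)
#' @param background_phase logical; add a smooth spatial phase ramp
#' @return a `bvalue_series` with complex `images` array `(n, n, n_b)`
#' @export
simulate_dwi_series <- function(truth, b_values = c(0, 100, 400, 800),
                                background_phase = FALSE) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (any(b_values < 0)) stop("b-values must be non-negative")
  if (b_values[1] != 0 || is.unsorted(b_values, strictly = TRUE)) {
    stop("`b_values` must be strictly increasing and start at 0")
  }
  n <- nrow(truth$S0_map)
  phase <- matrix(0, n, n)
  if (background_phase) {
    ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
    phase <- matrix(2 * pi * (0.3 * ij$i / n + 0.2 * ij$j / n +
                              0.15 * (ij$i / n)^2), n, n)
  }
  imgs <- array(0i, dim = c(n, n, length(b_values)))
  for (bi in seq_along(b_values)) {
    mag <- truth$S0_map * exp(-b_values[bi] * truth$ADC_map * 1e-3)
    imgs[, , bi] <- mag * exp(1i * phase)
  }
  structure(list(b_values = b_values, images = imgs, grid_size = n),
            class = "bvalue_series")
}
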