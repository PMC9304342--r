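## The two reconstructions under comparison: linear SENSE unfolding and
## L1-regularized iterative SENSE (wavelet sparsity, FISTA with restart).

#' Reconstruction configuration
#'
#' @param method `"sense"` (linear unfolding / regularized least squares) or
#'   `"l1_sense"` (wavelet-L1 regularized iterative SENSE)
#' @param lam relative regularization weight, >= 0. The absolute weight is
#'   `lam_abs = lam * max(abs(dwt2(E^H y)))`, making behavior invariant to
#'   global signal scaling. Ignored if `lam_abs` is given.
#' @param lam_abs optional absolute regularization weight; set this when a
#'   noise-only scan must be reconstructed with the identical operator as
#'   its signal scan (take it from the signal recon's provenance)
#' @param wavelet_name sparsifying transform; only `"db4"` (orthogonal
#'   4-tap Daubechies, periodic) is built in
#' @param n_levels wavelet decomposition depth
#' @param max_iter FISTA iteration cap
#' @param tol relative image-change stopping tolerance
#' @param l2_reg small ridge added to the SENSE normal equations
#' @param threshold_approx if `TRUE`, also threshold the coarsest
#'   approximation band (default exempts it, preserving bulk contrast)
#' @return a `recon_config`
#' @export
recon_config <- function(method = c("sense", "l1_sense"), lam = 0.01,
                         lam_abs = NULL, wavelet_name = "db4", n_levels = 3L,
                         max_iter = 200L, tol = 1e-6, l2_reg = 0,
                         threshold_approx = FALSE) {
  method <- match.arg(method)
  if (lam < 0) stop("`lam` must be >= 0")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  if (tol <= 0) stop("`tol` must be > 0")
  if (!identical(wavelet_name, "db4")) stop("only the 'db4' wavelet is available")
  structure(
    list(method = method, lam = lam, lam_abs = lam_abs,
         wavelet_name = wavelet_name, n_levels = as.integer(n_levels),
         max_iter = as.integer(max_iter), tol = tol, l2_reg = l2_reg,
         threshold_approx = threshold_approx),
    class = "recon_config"
  )
}

#' Complex soft-thresholding (proximal operator of the absolute value)
#'
#' `soft_threshold(v, t) = v * max(1 - t/|v|, 0)`: the magnitude shrinks by
#' `t`, the phase is preserved; values inside the threshold map to zero.
#'
#' @param v complex (or numeric) vector
#' @param t non-negative threshold
#' @return shrunk values, same shape as `v`
#' @export
soft_threshold <- function(v, t) {
  if (t < 0) stop("`t` must be >= 0")
  av <- abs(v)
  scale <- ifelse(av > t, 1 - t / av, 0)
  scale[av == 0] <- 0
  v * scale
}

## prox of t * ||Psi_detail x||_1 for orthogonal Psi
wavelet_prox <- function(x, t, levels, dmask, threshold_approx) {
  w <- dwt2(x, levels)
  if (threshold_approx) {
    w <- soft_threshold(w, t)
  } else {
    w[dmask] <- soft_threshold(w[dmask], t)
  }
  idwt2(w, levels)
}

l1_penalty <- function(x, levels, dmask, threshold_approx) {
  w <- dwt2(x, levels)
  if (threshold_approx) sum(abs(w)) else sum(abs(w[dmask]))
}

## f(x) = 0.5 ||E x - y||^2 + lam_abs ||Psi_detail x||_1
objective_value <- function(x, op, y, lam_abs, levels, dmask, threshold_approx) {
  r <- op$forward(x) - y
  val <- 0.5 * sum(abs(r)^2)
  if (lam_abs > 0) {
    val <- val + lam_abs * l1_penalty(x, levels, dmask, threshold_approx)
  }
  val
}

#' Evaluate the L1-SENSE objective at an image
#'
#' `0.5 * ||E x - y||^2 + lam_abs * ||Psi_detail x||_1`, the function the
#' iterative reconstruction minimizes; exposed for convergence monitoring
#' and testing.
#'
#' @param x complex image
#' @param k a `kspace_series` (one slice selected via `b_index`/`average`)
#' @param coils a `coil_maps`
#' @param lam_abs absolute regularization weight
#' @param b_index,average slice selectors
#' @param n_levels,threshold_approx wavelet settings (see [recon_config()])
#' @return scalar objective value
#' @export
recon_objective <- function(x, k, coils, lam_abs, b_index = 1L, average = 1L,
                            n_levels = 3L, threshold_approx = FALSE) {
  op <- encoding_operator(coils, k$mask)
  y <- kspace_slice(k, b_index, average)
  dmask <- detail_mask(op$n, n_levels)
  objective_value(x, op, y, lam_abs, n_levels, dmask, threshold_approx)
}

new_recon_image <- function(image, provenance) {
  structure(list(image = image, magnitude = abs(image), provenance = provenance),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<recon_image> %s, R=%d, lam_abs=%.4g, %d iteration(s), objective %.6g\n",
              p$method, p$mask$R, ifelse(is.null(p$lam_abs), 0, p$lam_abs),
              p$n_iter, p$final_objective))
  invisible(x)
}

sense_provenance <- function(config, mask, n_iter, obj, lam_abs = 0) {
  list(method = config$method, lam = config$lam, lam_abs = lam_abs,
       mask = mask[c("R", "offset", "n_lines")], wavelet = config$wavelet_name,
       n_levels = config$n_levels, l2_reg = config$l2_reg,
       threshold_approx = config$threshold_approx,
       n_iter = n_iter, final_objective = obj)
}

## core linear SENSE on one multi-coil slice
sense_solve_slice <- function(y, op, config, blocks = NULL) {
  z <- op$adjoint(y)
  R <- op$mask$R
  if (op$n %% R == 0L) {
    if (is.null(blocks)) blocks <- unfolding_blocks(op, R)
    unfold_solve(z, blocks, config$l2_reg)
  } else {
    cg_solve(op, z, l2_reg = config$l2_reg)
  }
}

#' Conventional SENSE reconstruction
#'
#' Solves `min_x ||E x - y||^2 + l2_reg ||x||^2` for one (b-value, average)
#' slice. For equidistant masks whose acceleration factor divides the line
#' count this is done exactly by per-group unfolding: each group of `R`
#' aliased pixels is an independent `R`-unknown least-squares system whose
#' normal-equation block is extracted from `E^H E`. Otherwise (e.g. R = 3 on
#' a 160-line matrix) the same least-squares problem is solved by conjugate
#' gradients. Noiseless fully determined systems are recovered to numerical
#' precision.
#'
#' @param k a `kspace_series`
#' @param coils matching `coil_maps`
#' @param config a [recon_config()] (method `"sense"`)
#' @param b_index,average which slice to reconstruct
#' @return a `recon_image`
#' @export
sense_recon <- function(k, coils, config = recon_config("sense"),
                        b_index = 1L, average = 1L) {
  stopifnot(inherits(k, "kspace_series"), inherits(coils, "coil_maps"))
  if (coils$n_coils < k$mask$R) {
    stop("SENSE requires n_coils >= R for a determined unfolding")
  }
  op <- encoding_operator(coils, k$mask)
  y <- kspace_slice(k, b_index, average)
  x <- sense_solve_slice(y, op, config)
  obj <- 0.5 * sum(abs(op$forward(x) - y)^2)
  new_recon_image(x, sense_provenance(config, k$mask, 1L, obj))
}

## FISTA with function-value restart on one multi-coil slice.
## Monotone by construction: an accelerated step is only accepted if it does
## not increase the objective; otherwise a plain ISTA step (with step-size
## backtracking as a safety net) is taken instead.
l1_solve_slice <- function(y, op, config, lam_abs, L) {
  n <- op$n
  dmask <- detail_mask(n, config$n_levels)
  obj <- function(x) objective_value(x, op, y, lam_abs, config$n_levels,
                                     dmask, config$threshold_approx)
  prox <- function(x, step) wavelet_prox(x, lam_abs * step, config$n_levels,
                                         dmask, config$threshold_approx)
  grad <- function(x) op$adjoint(op$forward(x) - y)

  x <- op$adjoint(y)          # zero-filled adjoint initialization
  fx <- obj(x)
  xp <- x
  tk <- 1
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    n_iter <- it
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    v <- x + ((tk - 1) / t_next) * (x - xp)
    z <- prox(v - grad(v) / L, 1 / L)
    fz <- obj(z)
    if (fz > fx) {
      # restart momentum; guarantee descent with ISTA + backtracking
      gx <- grad(x)
      z <- prox(x - gx / L, 1 / L)
      fz <- obj(z)
      guard <- 0L
      while (fz > fx + 1e-12 * max(1, abs(fx)) && guard < 20L) {
        L <- 2 * L
        z <- prox(x - gx / L, 1 / L)
        fz <- obj(z)
        guard <- guard + 1L
      }
      t_next <- 1
      if (fz > fx) { z <- x; fz <- fx }  # cannot improve: stay
    }
    if (!is.finite(fz)) stop("non-finite objective during L1-SENSE iteration")
    rel <- sqrt(sum(abs(z - x)^2)) / max(sqrt(sum(abs(x)^2)), .Machine$double.eps)
    xp <- x; x <- z; fx <- fz; tk <- t_next
    if (rel < config$tol) break
  }
  list(x = x, n_iter = n_iter, objective = fx)
}

#' L1-regularized iterative SENSE reconstruction
#'
#' Approximately minimizes
#' `0.5 * ||E x - y||^2 + lam_abs * ||Psi_detail x||_1`
#' (data consistency plus wavelet-domain sparsity) by accelerated proximal
#' gradient iteration (FISTA) with function-value restart. The gradient step
#' uses step size `1/L` with `L` from [power_iteration_bound()]; the
#' proximal step is exact soft-thresholding of the orthogonal wavelet detail
#' coefficients. Stops when the relative image change drops below
#' `config$tol` or at `config$max_iter`. The objective at the returned
#' iterate never exceeds its value at the zero-filled adjoint
#' initialization.
#'
#' @inheritParams sense_recon
#' @param config a [recon_config()] with `method = "l1_sense"`; set
#'   `config$lam_abs` to reuse an absolute weight (e.g. for noise scans)
#' @return a `recon_image`; provenance records `lam_abs`, iterations used
#'   and the final objective
#' @export
l1_sense_recon <- function(k, coils, config = recon_config("l1_sense"),
                           b_index = 1L, average = 1L) {
  stopifnot(inherits(k, "kspace_series"), inherits(coils, "coil_maps"))
  if (config$method != "l1_sense") stop("config$method must be 'l1_sense'")
  op <- encoding_operator(coils, k$mask)
  y <- kspace_slice(k, b_index, average)
  lam_abs <- config$lam_abs
  if (is.null(lam_abs)) {
    lam_abs <- if (config$lam == 0) 0 else
      config$lam * max(abs(dwt2(op$adjoint(y), config$n_levels)))
  }
  L <- power_iteration_bound(op)
  fit <- l1_solve_slice(y, op, config, lam_abs, L)
  prov <- sense_provenance(config, k$mask, fit$n_iter, fit$objective, lam_abs)
  new_recon_image(fit$x, prov)
}

#' Reconstruct a full multi-b-value, multi-average series
#'
#' Every (b-value, average) slice is reconstructed independently, then
#' averages are combined. The default `"recon_then_average"` averages the
#' magnitude images after reconstruction (denoising acts on every single
#' measurement, as in the clinical pipeline under study);
#' `"average_then_recon"` averages the complex k-space data first and
#' reconstructs once per b-value.
#'
#' For the L1 method a single absolute regularization weight is derived
#' from the first (b = 0) average and reused for every slice, so all slices
#' pass through the identical reconstruction operator.
#'
#' @param k a `kspace_series`
#' @param coils matching `coil_maps`
#' @param config a [recon_config()]
#' @param combine averaging strategy (see above)
#' @return a `recon_series`: magnitude array `(n, n, n_b)`, `b_values`, and
#'   the shared `provenance`
#' @export
reconstruct_series <- function(k, coils, config = recon_config("sense"),
                               combine = c("recon_then_average",
                                           "average_then_recon")) {
  combine <- match.arg(combine)
  op <- encoding_operator(coils, k$mask)
  n <- k$grid_size
  nb <- length(k$b_values)
  na <- k$n_averages

  is_l1 <- config$method == "l1_sense"
  lam_abs <- 0
  L <- NULL
  blocks <- NULL
  if (is_l1) {
    lam_abs <- config$lam_abs
    if (is.null(lam_abs)) {
      lam_abs <- if (config$lam == 0) 0 else
        config$lam * max(abs(dwt2(op$adjoint(kspace_slice(k, 1L, 1L)),
                                  config$n_levels)))
    }
    L <- power_iteration_bound(op)
  } else if (n %% k$mask$R == 0L) {
    blocks <- unfolding_blocks(op, k$mask$R)
  }

  solve_one <- function(y) {
    if (is_l1) l1_solve_slice(y, op, config, lam_abs, L)$x
    else sense_solve_slice(y, op, config, blocks)
  }

  mag <- array(0, dim = c(n, n, nb))
  for (bi in seq_len(nb)) {
    if (combine == "average_then_recon") {
      y <- array(0i, dim = c(n, n, k$n_coils))
      for (a in seq_len(na)) y <- y + kspace_slice(k, bi, a)
      mag[, , bi] <- abs(solve_one(y / na))
    } else {
      acc <- matrix(0, n, n)
      for (a in seq_len(na)) {
        acc <- acc + abs(solve_one(kspace_slice(k, bi, a)))
      }
      mag[, , bi] <- acc / na
    }
  }
  prov <- sense_provenance(config, k$mask, NA_integer_, NA_real_, lam_abs)
  prov$combine <- combine
  structure(list(magnitude = mag, b_values = k$b_values, provenance = prov,
                 grid_size = n),
            class = "recon_series")
}
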