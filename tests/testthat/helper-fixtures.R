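# Shared small fixtures, built once per test run. 48 px grids keep every
# Monte-Carlo loop fast while supporting R = 2 and 3 unfolding and three
# wavelet levels.

fix_phantom <- function(n = 48L, vessel_fraction = 0.03, lesions = list(),
                        seed = 1L, ...) {
  make_phantom(phantom_spec(grid_size = n, vessel_fraction = vessel_fraction,
                            lesion_specs = lesions, seed = seed, ...))
}

fix_coils <- function(n_coils = 6L, n = 48L, seed = 1L) {
  make_coil_maps(n_coils, n, seed = seed)
}

rand_cplx_matrix <- function(n, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}

# complex inner product <a, b> = sum(conj(a) * b)
cdot <- function(a, b) sum(Conj(a) * b)

# uniform single-coil map on an n-grid
uniform_coil <- function(n) {
  maps <- array(1 + 0i, dim = c(n, n, 1L))
  structure(list(maps = maps, n_coils = 1L, grid_size = as.integer(n), seed = 0L),
            class = "coil_maps")
}

# hand-built coil_maps from a list of n x n complex matrices
manual_coils <- function(mats) {
  n <- nrow(mats[[1]])
  maps <- array(0i, dim = c(n, n, length(mats)))
  for (c in seq_along(mats)) maps[, , c] <- mats[[c]]
  structure(list(maps = maps, n_coils = length(mats), grid_size = as.integer(n),
                 seed = 0L),
            class = "coil_maps")
}

# wrap a single complex image as a bvalue_series at b = 0
image_series <- function(img) {
  structure(list(b_values = 0, images = array(img, dim = c(dim(img), 1L)),
                 grid_size = nrow(img)),
            class = "bvalue_series")
}
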