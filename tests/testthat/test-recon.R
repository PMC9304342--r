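# SENSE unfolding and the L1-regularized iterative reconstruction.

test_that("noiseless accelerated SENSE is exact and records provenance", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils()
  for (R in c(2L, 3L)) {
    k <- undersample(encode(ser, co, 1), R)
    rec <- sense_recon(k, co)
    rel <- max(abs(rec$image - ser$images[, , 1])) / max(abs(ser$images[, , 1]))
    expect_lt(rel, 1e-9)
    expect_equal(rec$provenance$method, "sense")
    expect_equal(rec$provenance$mask$R, R)
    expect_equal(rec$magnitude, abs(rec$image))
  }
})

test_that("SENSE solves the least-squares problem of a 2-pixel toy exactly", {
  # two aliased rows, two coils with a non-trivial sensitivity matrix
  n <- 2L
  s1 <- matrix(c(1, 0.5), n, n)    # coil 1: rows (1, 0.5)
  s2 <- matrix(c(0.3, 1), n, n)
  co <- manual_coils(list(s1, s2))
  set.seed(99)
  img <- rand_cplx_matrix(n, seed = 99)
  k <- undersample(encode(image_series(img), co, 1), 2L)
  rec <- sense_recon(k, co)
  # independent oracle: dense E from basis images, explicit least squares
  op <- encoding_operator(co, k$mask)
  E <- matrix(0i, n * n * 2, n * n)
  for (j in seq_len(n * n)) {
    e <- matrix(0i, n, n); e[j] <- 1
    E[, j] <- as.vector(op$forward(e))
  }
  y <- as.vector(kspace_slice(k))
  x_ls <- qr.solve(E, y)
  expect_lt(max(abs(as.vector(rec$image) - x_ls)), 1e-10)
})

test_that("identity-selector coils make unfolding trivially exact", {
  n <- 2L
  co <- manual_coils(list(matrix(c(1, 0), n, n), matrix(c(0, 1), n, n)))
  img <- rand_cplx_matrix(n, seed = 3)
  k <- undersample(encode(image_series(img), co, 1), 2L)
  rec <- sense_recon(k, co)
  expect_lt(max(abs(rec$image - img)), 1e-10)
})

test_that("CG path handles R not dividing the line count", {
  # 50 lines, R = 3 (as with the clinical 160-line matrix at R = 3): no clean
  # aliasing groups -> conjugate-gradient least-squares solve
  tr <- fix_phantom(n = 50L)
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils(8L, n = 50L)
  k <- undersample(encode(ser, co, 1), 3L)
  rec <- sense_recon(k, co)
  rel <- sqrt(sum(abs(rec$image - ser$images[, , 1])^2) /
              sum(abs(ser$images[, , 1])^2))
  expect_lt(rel, 1e-6)
})

test_that("soft thresholding matches its closed form on landmark cases", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(3 + 4i, 2.5), 1.5 + 2i)
  expect_equal(soft_threshold(0i, 1), 0i)
  expect_error(soft_threshold(1, -1), ">= 0")
})

test_that("an extreme lambda leaves only the approximation band", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils()
  k <- add_noise(undersample(encode(ser, co, 1), 3), 1, seed = 4)
  rec <- l1_sense_recon(k, co, recon_config("l1_sense", lam = 50,
                                            max_iter = 30, tol = 1e-8))
  w <- dwt2(rec$image)
  dm <- detail_mask(48)
  expect_lt(max(abs(w[dm])), 1e-8 * max(abs(w)))
  expect_gt(max(abs(w[!dm])), 0)
})

test_that("objective matches an independent term-by-term recomputation", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils()
  k <- add_noise(undersample(encode(ser, co, 1), 3), 0.8, seed = 9)
  x <- rand_cplx_matrix(48, seed = 17) * 10
  lam_abs <- 2.5
  got <- recon_objective(x, k, co, lam_abs)
  # independent recomputation from first principles
  kept <- k$mask$kept_lines + 1L
  data_term <- 0
  for (c in 1:6) {
    kc <- csdwi::fft2c(co$maps[, , c] * x)
    resid <- kc[kept, ] - k$data[kept, , c, 1, 1]
    data_term <- data_term + sum(Mod(resid)^2)
  }
  w <- dwt2(x)
  dm <- detail_mask(48)
  expected <- 0.5 * data_term + lam_abs * sum(Mod(w[dm]))
  expect_equal(got, expected, tolerance = 1e-10)
  # landmark values
  expect_equal(recon_objective(ser$images[, , 1],
                               undersample(encode(ser, co, 1), 3), co, 0),
               0, tolerance = 1e-12)
  y <- kspace_slice(k)
  expect_equal(recon_objective(matrix(0i, 48, 48), k, co, 0),
               0.5 * sum(abs(y)^2), tolerance = 1e-10)
})

test_that("L1 solver provenance tracks iterations and a decreasing objective", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils()
  k <- add_noise(undersample(encode(ser, co, 1), 3), 1, seed = 21)
  cfg <- recon_config("l1_sense", lam = 0.01, max_iter = 40, tol = 1e-7)
  rec <- l1_sense_recon(k, co, cfg)
  expect_lte(rec$provenance$n_iter, 40L)
  op <- encoding_operator(co, k$mask)
  init_obj <- recon_objective(op$adjoint(kspace_slice(k)), k, co,
                              rec$provenance$lam_abs)
  expect_lte(rec$provenance$final_objective, init_obj)
})

test_that("series reconstruction combines averages both ways", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr, b_values = c(0, 800))
  co <- fix_coils()
  k <- add_noise(undersample(encode(ser, co, n_averages = 2), 2), 1, seed = 31)
  ra <- reconstruct_series(k, co, recon_config("sense"))
  rb <- reconstruct_series(k, co, recon_config("sense"),
                           combine = "average_then_recon")
  expect_equal(dim(ra$magnitude), c(48, 48, 2))
  expect_equal(ra$provenance$combine, "recon_then_average")
  # both estimates approximate the truth; complex averaging before the linear
  # recon equals averaging the complex recons, so it differs from the
  # magnitude average only through noise rectification
  truth0 <- abs(ser$images[, , 1])
  expect_lt(mean(abs(ra$magnitude[, , 1] - truth0)), 2)
  expect_lt(mean(abs(rb$magnitude[, , 1] - truth0)), 2)
})
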