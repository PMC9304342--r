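# ROI statistics, the noise-map SNR pathway, ADC fitting.

test_that("roi_stats computes mean and sample SD", {
  img <- matrix(7, 8, 8)
  r <- roi(cbind(2:4, 2:4))
  s <- roi_stats(img, r)
  expect_equal(s$mean, 7)
  expect_equal(s$sd, 0)
  img2 <- matrix(0, 8, 8)
  img2[1, 1] <- 3; img2[1, 2] <- 5
  s2 <- roi_stats(img2, roi(rbind(c(1, 1), c(1, 2))))
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, sqrt(2))
  expect_error(roi(matrix(numeric(0), 0, 2)), "at least one pixel")
  expect_warning(roi_stats(img, roi(rbind(c(1, 1)))), "single-pixel")
  expect_error(roi_stats(matrix(0, 4, 4), roi(rbind(c(5, 5)))), "outside")
})

test_that("auto ROIs land on pure parenchyma and are reproducible", {
  tr <- fix_phantom(vessel_fraction = 0.03,
                    lesions = list(lesion_spec(c(24, 22), 7)))
  rois <- auto_parenchyma_rois(tr, n_rois = 2, radius_px = 4, seed = 5)
  expect_length(rois, 2)
  for (r in rois) expect_true(all(tr$label_map[r$pixels] == 1L))
  rois2 <- auto_parenchyma_rois(tr, n_rois = 2, radius_px = 4, seed = 5)
  expect_identical(rois, rois2)
})

test_that("snr_from_noise_map enforces matched reconstruction provenance", {
  tr <- fix_phantom(vessel_fraction = 0)
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils()
  k <- add_noise(undersample(encode(ser, co, 1), 3), 1, seed = 2)
  nz <- simulate_noise_scan(k, 1, seed = 3)
  rois <- auto_parenchyma_rois(tr, 2, radius_px = 4, seed = 1)
  rs <- sense_recon(k, co)
  rn <- sense_recon(nz, co)
  rep <- snr_from_noise_map(rs, rn, rois[[1]], rois[[2]])
  expect_equal(rep$snr, rep$signal_mean / rep$noise_sd)
  expect_gt(rep$snr, 0)
  # mismatched operator (different lambda) must be rejected
  rl <- l1_sense_recon(k, co, recon_config("l1_sense", lam = 0.01,
                                           max_iter = 20, tol = 1e-4))
  expect_error(snr_from_noise_map(rl, rn, rois[[1]], rois[[2]]),
               "same operator")
})

test_that("SNR is invariant to a global phase on the signal image", {
  tr <- fix_phantom(vessel_fraction = 0)
  ser <- simulate_dwi_series(tr, b_values = 0)
  co <- fix_coils()
  k <- add_noise(undersample(encode(ser, co, 1), 3), 1, seed = 2)
  nz <- simulate_noise_scan(k, 1, seed = 3)
  rois <- auto_parenchyma_rois(tr, 2, radius_px = 4, seed = 1)
  rs <- sense_recon(k, co)
  rn <- sense_recon(nz, co)
  a <- snr_from_noise_map(rs, rn, rois[[1]], rois[[2]])
  rs$image <- rs$image * exp(1i * 1.1)
  rs$magnitude <- abs(rs$image)
  b <- snr_from_noise_map(rs, rn, rois[[1]], rois[[2]])
  expect_equal(a$snr, b$snr, tolerance = 1e-12)
})

test_that("ADC fit is exact on noiseless data and honors the two-point form", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr)
  m <- fit_adc(abs(ser$images), ser$b_values)
  valid <- m$valid_mask
  expect_true(all(abs(m$adc[valid] - tr$ADC_map[valid]) < 1e-9))
  # two-point algebra: S(0)=100, S(800)=100*exp(-0.752) -> ADC 0.94
  s <- array(0, dim = c(1, 1, 2))
  s[1, 1, ] <- c(100, 100 * exp(-0.752))
  m2 <- fit_adc(s, c(0, 800), method = "two_point")
  expect_equal(m2$adc[1, 1], 0.94, tolerance = 1e-12)
})

test_that("non-positive signal marks a pixel invalid without side effects", {
  tr <- fix_phantom(vessel_fraction = 0)
  ser <- simulate_dwi_series(tr)
  mags <- abs(ser$images)
  mags[24, 24, 3] <- 0   # kill S(400) at one pixel
  m <- fit_adc(mags, ser$b_values)
  expect_false(m$valid_mask[24, 24])
  expect_true(is.na(m$adc[24, 24]))
  expect_true(m$valid_mask[24, 25])
  expect_equal(m$adc[24, 25], tr$ADC_map[24, 25], tolerance = 1e-9)
})

test_that("adc_roi_summary summarizes valid pixels and rejects empty overlap", {
  tr <- fix_phantom(vessel_fraction = 0)
  ser <- simulate_dwi_series(tr)
  m <- fit_adc(abs(ser$images), ser$b_values)
  r <- roi(rbind(c(24, 24), c(24, 25), c(25, 24)))
  s <- adc_roi_summary(m, r)
  expect_equal(s$mean, 0.94, tolerance = 1e-9)
  expect_equal(s$sd, 0, tolerance = 1e-9)
  # ROI fully outside the organ: all invalid (S0 = 0) -> rejection
  expect_error(adc_roi_summary(m, roi(rbind(c(1, 1), c(1, 2)))), "no valid")
})

test_that("property: ADC recovery is exact for random fields and any >= 2 b-values", {
  set.seed(123)
  for (trial in 1:5) {
    n <- 16L
    S0 <- matrix(runif(n * n, 50, 150), n, n)
    ADC <- matrix(runif(n * n, 0.3, 2.5), n, n)
    nb <- sample(2:5, 1)
    b <- sort(c(0, sample(seq(50, 1000, by = 50), nb - 1)))
    s <- array(0, dim = c(n, n, nb))
    for (bi in seq_len(nb)) s[, , bi] <- S0 * exp(-b[bi] * ADC * 1e-3)
    m <- fit_adc(s, b)
    expect_lt(max(abs(m$adc - ADC)), 1e-9)
    expect_true(all(m$valid_mask))
  }
})
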