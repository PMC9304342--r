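# Phantom geometry, the mono-exponential signal model, and coil maps.

test_that("degenerate spec yields only background and parenchyma labels", {
  tr <- fix_phantom(vessel_fraction = 0)
  expect_setequal(unique(as.vector(tr$label_map)), c(0L, 1L))
  expect_gte(mean(tr$label_map == 1L), 0.40)  # connected organ covers >= 40%
})

test_that("parenchyma region is connected", {
  tr <- fix_phantom(vessel_fraction = 0)
  mask <- tr$label_map == 1L
  # flood fill from one parenchyma pixel must reach all of them
  n <- nrow(mask)
  seen <- matrix(FALSE, n, n)
  start <- which(mask, arr.ind = TRUE)[1, ]
  stack <- list(start)
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- p[1]; j <- p[2]
    if (i < 1 || i > n || j < 1 || j > n || seen[i, j] || !mask[i, j]) next
    seen[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  expect_equal(sum(seen), sum(mask))
})

test_that("a 5 mm lesion at 2.38 mm pixels renders as a ~2 px disc", {
  les <- lesion_spec(c(24, 22), diameter_mm = 5)
  tr <- fix_phantom(vessel_fraction = 0, lesions = list(les),
                    pixel_size_mm = 2.38)
  px <- which(tr$label_map == 3L, arr.ind = TRUE)
  expect_gt(nrow(px), 0)
  expect_lte(diff(range(px[, 1])) + 1, 3)  # about 2 px across
  expect_lte(nrow(px), 9)
})

test_that("phantom generation is deterministic given spec and seed", {
  les <- list(lesion_spec(c(24, 22), 7))
  a <- fix_phantom(lesions = les, seed = 11L)
  b <- fix_phantom(lesions = les, seed = 11L)
  expect_identical(a, b)
  c <- fix_phantom(lesions = les, seed = 12L)
  expect_false(identical(a$label_map, c$label_map))
})

test_that("invalid lesions are rejected with the offending id", {
  outside <- lesion_spec(c(2, 2), 5)
  expect_error(fix_phantom(lesions = list(outside)), "lesion 1")
  l1 <- lesion_spec(c(24, 22), 7)
  l2 <- lesion_spec(c(24, 23), 7)
  expect_error(fix_phantom(lesions = list(l1, l2)), "overlaps")
})

test_that("lesion b = 0 contrast equals the requested offset exactly", {
  les <- lesion_spec(c(24, 22), 7, S0_contrast = 0.2)
  tr <- fix_phantom(vessel_fraction = 0, lesions = list(les))
  inside <- tr$label_map == 3L
  expect_true(all(tr$S0_map[inside] == 100 * 1.2))
  expect_equal(names(tr$lesion_registry), "1")
})

test_that("DWI signal follows S0 * exp(-b * ADC * 1e-3)", {
  tr <- fix_phantom()
  ser <- simulate_dwi_series(tr, b_values = c(0, 100, 400, 800))
  # b = 0 equals S0 exactly
  expect_equal(abs(ser$images[, , 1]), tr$S0_map)
  # closed form at one parenchyma pixel: S0 = 100, ADC = 0.94, b = 800
  p <- which(tr$label_map == 1L, arr.ind = TRUE)[1, ]
  expect_equal(abs(ser$images[p[1], p[2], 4]), 100 * exp(-0.752),
               tolerance = 1e-12)
  # monotone decay wherever ADC > 0
  mags <- abs(ser$images)
  pos <- tr$ADC_map > 0
  for (bi in 2:4) {
    expect_true(all(mags[, , bi][pos] < mags[, , bi - 1][pos]))
  }
})

test_that("zero ADC gives identical images across b-values", {
  tr <- fix_phantom(vessel_fraction = 0)
  tr$ADC_map[] <- 0
  ser <- simulate_dwi_series(tr, b_values = c(0, 400, 800))
  expect_equal(ser$images[, , 2], ser$images[, , 1])
  expect_equal(ser$images[, , 3], ser$images[, , 1])
})

test_that("b-value validation rejects malformed sequences", {
  tr <- fix_phantom()
  expect_error(simulate_dwi_series(tr, b_values = c(-100, 0)), "non-negative")
  expect_error(simulate_dwi_series(tr, b_values = c(100, 400)), "start at 0")
  expect_error(simulate_dwi_series(tr, b_values = c(0, 400, 400)), "increasing")
})

test_that("single coil map is the uniform unit map", {
  co <- make_coil_maps(1, 48)
  expect_true(all(co$maps == 1 + 0i))
  expect_error(make_coil_maps(0, 48), ">= 1")
})

test_that("coil maps are RSS-normalized and support R = 3 unfolding", {
  co <- fix_coils(8L)
  rss <- apply(abs(co$maps)^2, c(1, 2), sum)
  expect_lt(max(abs(rss - 1)), 1e-12)
  # every 3-pixel unfolding group is full rank
  expect_gt(min_unfolding_singular_value(co, 3L), 0)
})

test_that("anti-aliased lesion edges reduce edge contrast only", {
  les <- lesion_spec(c(24.5, 22.5), 9, S0_contrast = 0.2)
  hard <- make_phantom(phantom_spec(grid_size = 48L, vessel_fraction = 0,
                                    lesion_specs = list(les)))
  soft <- make_phantom(phantom_spec(grid_size = 48L, vessel_fraction = 0,
                                    lesion_specs = list(les)), antialias = TRUE)
  # inside the nominal disc coverage can only shrink the offset; just outside
  # it, spill-over raises parenchyma slightly (partial-volume both ways)
  inside <- hard$label_map == 3L
  expect_true(all(soft$S0_map[inside] <= hard$S0_map[inside] + 1e-12))
  expect_true(any(soft$S0_map > 100 & soft$S0_map < 120))
})
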