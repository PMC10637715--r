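test_that("the pixel-fraction estimator reproduces the hand-worked example", {
  # 2000 flower px of 10000 at 0.027 m/px, kappa 0.001 t/m^2, window area
  # 10000 px * 0.027^2 = 7.29 m^2 = 7.29e-4 ha
  est <- estimate_yield(2000, 10000, 0.027, area_ha = 7.29e-4,
                        config = yield_config(kappa = 0.001, flower_to_pod = 1))
  expect_equal(est$F, 0.2)
  expect_equal(est$flower_area_m2, 1.458)
  expect_equal(est$P, 1.458e-3)
  expect_equal(est$estimated, 0.4, tolerance = 1e-12)

  expect_equal(estimate_yield(0, 100, 0.027, 1)$estimated, 0)
})

test_that("the estimator is linear in kappa and inverse in dilution", {
  base <- estimate_yield(500, 2000, 0.027, 0.01,
                         config = yield_config(kappa = 0.002))
  dbl <- estimate_yield(500, 2000, 0.027, 0.01,
                        config = yield_config(kappa = 0.004))
  expect_equal(dbl$estimated, 2 * base$estimated, tolerance = 1e-12)
  # doubling total pixels (same flowers, same area) halves F and the estimate
  dil <- estimate_yield(500, 4000, 0.027, 0.01,
                        config = yield_config(kappa = 0.002))
  expect_equal(dil$estimated, base$estimated / 2, tolerance = 1e-12)
  # adding flower pixels never decreases the estimate
  more <- estimate_yield(501, 2000, 0.027, 0.01,
                         config = yield_config(kappa = 0.002))
  expect_gt(more$estimated, base$estimated)
  expect_error(estimate_yield(10, 0, 0.027, 1), "total_pixels")
  expect_error(estimate_yield(10, 5, 0.027, 1), "flower_pixels")
  expect_error(estimate_yield(1, 5, 0.027, 0), "area")
})

test_that("flower-to-pod conversion scales the mass term", {
  full <- estimate_yield(100, 400, 0.027, 0.001, yield_config(kappa = 0.01))
  pods <- estimate_yield(100, 400, 0.027, 0.001,
                         yield_config(kappa = 0.01, flower_to_pod = 0.75))
  expect_equal(pods$estimated, 0.75 * full$estimated, tolerance = 1e-12)
})

test_that("zonal estimates equal generated actual yields when noise-free", {
  sc <- generate_scene(128, 128, flower_fraction = 0.3, seed = 6)
  zones <- make_zone_grid(sc$truth, 25, side = 0.5)
  pts <- generate_yield_points(sc$truth, zones, noise_cv = 0, seed = 2)
  nd <- compute_ndyi(sc$raster)
  cm <- assign_classes(isodata_classify(nd))
  samples <- estimate_yield_zones(cm, zones,
                                  yield_config(kappa = sc$truth$kappa_true))
  expect_equal(samples$estimated, pts$yield, tolerance = 1e-9)
})

test_that("estimates ignore nodata padding", {
  vals <- matrix(c(rep(-0.7, 30), rep(0.3, 34)), 8, 8)
  ir <- index_raster(vals, 0.1)
  cm <- assign_classes(isodata_classify(ir, tiny_iso(2)))
  zone <- zone_square(0.4, 0.4, 0.8, id = "z")
  s1 <- estimate_yield_zones(cm, zone)

  padded <- matrix(NA_real_, 12, 12)
  padded[3:10, 3:10] <- vals
  irp <- index_raster(padded, 0.1, origin = c(-0.2, 1.0))
  cmp_ <- assign_classes(isodata_classify(irp, tiny_iso(2)))
  s2 <- estimate_yield_zones(cmp_, zone)
  expect_equal(s2$flower_pixels, s1$flower_pixels)
  expect_equal(s2$total_pixels, s1$total_pixels)
  expect_equal(s2$estimated, s1$estimated, tolerance = 1e-12)
})

test_that("zones without valid pixels are flagged and excluded", {
  vals <- matrix(NA_real_, 10, 10)
  vals[1:5, ] <- rep(c(-0.7, 0.3), length.out = 50)
  ir <- index_raster(vals, 0.1)
  cm <- assign_classes(isodata_classify(ir, tiny_iso(2)))
  zones <- dplyr::bind_rows(
    zone_square(0.5, 0.75, 0.4, id = "valid"),
    zone_square(0.5, 0.2, 0.3, id = "masked"))
  s <- estimate_yield_zones(cm, zones)
  expect_false(s$excluded[1])
  expect_true(s$excluded[2])
  expect_true(is.na(s$estimated[2]))
})

test_that("kappa calibration recovers exact and noisy coefficients", {
  # single sample: slope is the exact ratio
  one <- tibble::tibble(id = "a", F = 0.5, flower_area_m2 = 8, A_ha = 2e-3,
                        estimated = NA_real_, actual = 4.0, excluded = FALSE)
  # prediction at kappa = 1: 0.5 * 8 / 2e-3 = 2000 -> kappa = 4 / 2000
  expect_equal(calibrate_kappa(one), 4 / 2000, tolerance = 1e-12)

  sc <- generate_scene(128, 128, flower_fraction = 0.3, seed = 14,
                       kappa_true = 0.002)
  zones <- make_zone_grid(sc$truth, 36, side = 0.4)
  pts <- generate_yield_points(sc$truth, zones, noise_cv = 0, seed = 4)
  nd <- compute_ndyi(sc$raster)
  cm <- assign_classes(isodata_classify(nd))
  samples <- estimate_yield_zones(cm, zones)
  samples$actual <- pts$yield
  expect_equal(calibrate_kappa(samples), 0.002, tolerance = 1e-9)

  ptsn <- generate_yield_points(sc$truth, zones, noise_cv = 0.05, seed = 4)
  samples$actual <- ptsn$yield
  k <- calibrate_kappa(samples)
  expect_lt(abs(k / 0.002 - 1), 0.05)

  expect_error(calibrate_kappa(samples[0, ]), "at least one")
  zero <- one; zero$F <- 0; zero$flower_area_m2 <- 0
  expect_error(calibrate_kappa(zero), "zero")
})

test_that("the end-to-end pipeline validates against generated truth", {
  sc <- generate_scene(192, 192, flower_fraction = 0.3, seed = 8)
  zones <- make_zone_grid(sc$truth, 25, side = 0.6)
  pts <- generate_yield_points(sc$truth, zones, noise_cv = 0, seed = 9)
  actual <- tibble::tibble(id = pts$id, actual = pts$yield)
  res <- run_flower_yield_pipeline(sc$raster, zones, actual = actual)
  expect_s3_class(res, "flower_yield_result")
  expect_gte(res$report$r2, 0.99)
  expect_equal(res$kappa, sc$truth$kappa_true, tolerance = 1e-6)
  expect_equal(glance(res)$r2, res$report$r2)
  expect_equal(nrow(tidy(res)), 25)
})

test_that("a flowerless scene yields zero estimates and skips validation", {
  sc <- generate_scene(96, 96, flower_fraction = 0, seed = 13)
  zones <- make_zone_grid(sc$truth, 9, side = 0.5)
  pts <- generate_yield_points(sc$truth, zones, noise_cv = 0, seed = 2)
  actual <- tibble::tibble(id = pts$id, actual = pts$yield)
  expect_message(
    res <- run_flower_yield_pipeline(sc$raster, zones, actual = actual),
    "skipped")
  expect_true(all(res$samples$estimated[!res$samples$excluded] == 0))
  expect_null(res$report)
  expect_false(is.null(res$notice))
})

test_that("two survey dates of one field pool into a joint validation", {
  zones <- NULL; pooled <- NULL
  for (seed in c(101, 202)) {
    sc <- generate_scene(128, 128, flower_fraction = 0.3, seed = seed)
    zones <- make_zone_grid(sc$truth, 16, side = 0.5)
    pts <- generate_yield_points(sc$truth, zones, noise_cv = 0.05, seed = seed + 1)
    actual <- tibble::tibble(id = pts$id, actual = pts$yield)
    res <- run_flower_yield_pipeline(sc$raster, zones, actual = actual)
    pooled <- dplyr::bind_rows(pooled, res$samples)
  }
  expect_equal(nrow(pooled), 32)
  ok <- !pooled$excluded & !is.na(pooled$actual)
  rep <- validation_report(pooled$estimated[ok], pooled$actual[ok])
  expect_gt(rep$r2, 0.9)
})
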