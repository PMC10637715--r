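test_that("raster constructors enforce their invariants", {
  expect_s3_class(const_raster(), "multispectral_raster")
  expect_error(multispectral_raster(list(matrix(1, 2, 2)), 0.1), "named")
  expect_error(
    multispectral_raster(list(a = matrix(1, 2, 2), b = matrix(1, 3, 2)), 0.1),
    "grid")
  expect_error(multispectral_raster(list(a = matrix(1, 2, 2)), -1), "resolution")
  # non-finite values outside the declared mask are rejected; by default the
  # mask absorbs them
  m <- matrix(1, 2, 2); m[1, 1] <- Inf
  expect_error(multispectral_raster(list(a = m), 1, mask = matrix(FALSE, 2, 2)),
               "non-finite")
  auto <- multispectral_raster(list(a = m), 1)
  expect_true(auto$mask[1, 1])
  msk <- matrix(FALSE, 2, 2); msk[1, 1] <- TRUE
  expect_silent(multispectral_raster(list(a = m), 1, mask = msk))
  # index values outside [-1, 1] get masked, not kept
  iv <- matrix(c(0.5, -0.5, 1.5, -2), 2, 2)
  ir <- index_raster(iv, 1)
  expect_equal(sum(ir$mask), 2)
  expect_equal(ir$n_out_of_range, 2)
  expect_true(all(valid_values(ir) >= -1 & valid_values(ir) <= 1))
})

test_that("pixel ground area matches the survey resolution", {
  r <- const_raster(res = 0.027)
  expect_equal(pixel_area(r), 0.027^2)
  # valid-pixel count times pixel area reproduces the valid field area
  n_valid <- sum(!r$mask)
  expect_equal(n_valid * pixel_area(r), 8 * 8 * 0.027^2, tolerance = 1e-12)
})

test_that("GeoTIFF round trips are value-identical, masks included", {
  dir <- withr::local_tempdir()
  # multispectral with 3 masked pixels
  r <- const_raster(h = 9, w = 7)
  r$mask[cbind(c(1, 5, 9), c(1, 4, 7))] <- TRUE
  f <- file.path(dir, "ms.tif")
  write_raster(r, f)
  r2 <- read_raster(f)
  expect_s3_class(r2, "multispectral_raster")
  expect_identical(names(r2$bands), names(r$bands))
  expect_identical(r2$mask, r$mask)
  for (b in names(r$bands)) {
    expect_identical(r2$bands[[b]][!r$mask], r$bands[[b]][!r$mask])
  }
  expect_identical(r2$resolution, r$resolution)
  expect_identical(r2$origin, r$origin)

  # index raster with irrational values survives bit-for-bit
  iv <- matrix(sin(seq_len(48)), 6, 8)
  ir <- index_raster(iv, 0.027)
  f2 <- file.path(dir, "ndyi.tif")
  write_raster(ir, f2)
  ir2 <- read_raster(f2, kind = "index")
  expect_identical(ir2$values[!ir2$mask], ir$values[!ir$mask])

  # single-band elevation read back as the requested kind
  ev <- elevation_raster(matrix(100 + sqrt(seq_len(16)), 4, 4), 0.1, kind = "DSM")
  f3 <- file.path(dir, "dsm.tif")
  write_raster(ev, f3)
  ev2 <- read_raster(f3)
  expect_s3_class(ev2, "elevation_raster")
  expect_identical(ev2$kind, "DSM")
  expect_identical(ev2$values, ev$values)
})

test_that("band-count contract violations error", {
  dir <- withr::local_tempdir()
  ev <- elevation_raster(matrix(1, 4, 4), 0.1, kind = "DSM")
  f <- file.path(dir, "one.tif")
  write_raster(ev, f)
  expect_error(read_raster(f, kind = "multispectral",
                           band_names = c("blue", "green")),
               "band")
  r <- const_raster()
  f2 <- file.path(dir, "five.tif")
  write_raster(r, f2)
  expect_error(read_raster(f2, kind = "index"), "one band")
  expect_error(read_raster(file.path(dir, "absent.tif")), "not found")
})

test_that("an independent TIFF reader agrees with the codec", {
  dir <- withr::local_tempdir()
  iv <- matrix(cos(seq_len(30)), 5, 6)
  ir <- index_raster(iv, 0.5)
  f <- file.path(dir, "oracle.tif")
  write_raster(ir, f)
  py <- sprintf(
    "import tifffile, numpy as np; a = tifffile.imread(%s); print(repr(float(a.sum())), a.shape)",
    shQuote(f))
  out <- suppressWarnings(system2("python", c("-c", shQuote(py)),
                                  stdout = TRUE, stderr = TRUE))
  expect_null(attr(out, "status"))
  got <- as.numeric(strsplit(out[length(out)], " ")[[1]][1])
  expect_equal(got, sum(iv), tolerance = 1e-12)
})

test_that("yield point CSVs are parsed and malformed rows rejected by number", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "pts.csv")
  writeLines(c("x,y,yield", "1,2,3.5", "4,5,0", "7,8,2.25"), f)
  pts <- read_yield_points(f)
  expect_equal(nrow(pts), 3)
  expect_equal(pts$yield, c(3.5, 0, 2.25))

  writeLines(c("x,y,yield", "1,2,3.5", "4,5,-1"), f)
  expect_error(read_yield_points(f), "row.*2")
  writeLines(c("x,y,yield", "1,2,abc"), f)
  expect_error(read_yield_points(f), "row.*1")
  writeLines(c("a,b,c", "1,2,3"), f)
  expect_error(read_yield_points(f), "header")
})

test_that("zones GeoJSON round trips squares and polygons with classes", {
  dir <- withr::local_tempdir()
  zones <- dplyr::bind_rows(
    zone_square(5, 5, 2, id = "low", yield_class = "low"),
    zone_square(9, 5, 2, id = "med", yield_class = "medium"),
    zone_polygon(rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3)),
                 id = "high", yield_class = "high"),
    zone_polygon(rbind(c(10, 10), c(14, 10), c(12, 14)),
                 id = "vhigh", yield_class = "very_high"))
  f <- file.path(dir, "zones.geojson")
  write_zones(zones, f)
  z2 <- read_zones(f)
  expect_equal(nrow(z2), 4)
  expect_equal(z2$yield_class, c("low", "medium", "high", "very_high"))
  expect_equal(z2$area_m2, zones$area_m2, tolerance = 1e-12)
  expect_equal(z2$cx, zones$cx, tolerance = 1e-12)
})

test_that("pixel-centre clipping matches brute force and the 10 m window count", {
  # 10 m window at 0.027 m/px owns 370 x 370 pixel centres
  res <- 0.027
  dims <- c(400L, 400L)
  origin <- c(0, dims[1] * res)
  z <- zone_square(5.4, 5.4, 10, id = "w")
  px <- osryield:::zone_pixel_index(z[1, ], dims, res, origin)
  expect_equal(nrow(px), 370L * 370L)

  # brute-force point-in-window over a small grid agrees with the polygon path
  dims2 <- c(40L, 40L)
  origin2 <- c(0, dims2[1] * res)
  tri <- rbind(c(0.1, 0.1), c(0.9, 0.15), c(0.5, 0.95))
  zp <- zone_polygon(tri, id = "tri")
  got <- osryield:::zone_pixel_index(zp[1, ], dims2, res, origin2)
  inside_bf <- function(x, y) {
    # ray casting, written independently
    n <- nrow(tri); cross <- FALSE; j <- n
    for (i in seq_len(n)) {
      if ((tri[i, 2] > y) != (tri[j, 2] > y) &&
          x < (tri[j, 1] - tri[i, 1]) * (y - tri[i, 2]) /
              (tri[j, 2] - tri[i, 2]) + tri[i, 1]) {
        cross <- !cross
      }
      j <- i
    }
    cross
  }
  cnt <- 0L
  for (i in seq_len(dims2[1])) for (j in seq_len(dims2[2])) {
    if (inside_bf(origin2[1] + (j - 0.5) * res, origin2[2] - (i - 0.5) * res)) {
      cnt <- cnt + 1L
    }
  }
  expect_equal(nrow(got), cnt)
})
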