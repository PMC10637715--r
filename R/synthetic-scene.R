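# Synthetic multispectral scenes with known ground truth: a three-class
# field (soil, green vegetation, flowering oilseed-rape canopy) laid out as
# spatially coherent patches, matching DSM/DTM pairs, and zone-level yield
# points coupled to flower density. Everything downstream of photogrammetry
# can be exercised against these with exact truth in hand.

OSR_STAGES <- c("rosette", "bolting", "flowering", "podding", "ripening")

#' Default canopy heights by phenological stage
#'
#' Mean canopy heights (m) used by the scene generator for the five
#' oilseed-rape growth stages, on the scale observed in UAV canopy-height
#' surveys (roughly 0.1-1.35 m, peaking at flowering).
#'
#' @return A tibble with columns `stage` and `height_m`.
#' @export
stage_heights <- function() {
  tibble::tibble(
    stage = OSR_STAGES,
    height_m = c(0.21, 0.53, 0.91, 0.58, 0.62)
  )
}

#' Per-class spectral preset for scene generation
#'
#' Mean and standard deviation of reflectance per class and band. The
#' defaults are synthetic values tuned so that the induced NDYI
#' distributions land in the ranges observed over real oilseed-rape fields:
#' flower pixels almost surely above 0.12, green vegetation within
#' (-0.45, -0.15), soil within (-1, -0.45). They are not physical
#' reflectance spectra.
#'
#' @param tbl Optional replacement tibble with columns `class`, `band`,
#'   `mean`, `sd`.
#' @param sd_scale Multiplier on all standard deviations (a separability
#'   dial: larger values blur the classes together).
#' @return A tibble of class `spectral_preset`.
#' @export
class_spectral_preset <- function(tbl = NULL, sd_scale = 1) {
  if (is.null(tbl)) {
    bands <- c("blue", "green", "red", "rededge", "nir")
    tbl <- dplyr::bind_rows(
      tibble::tibble(class = "soil", band = bands,
                     mean = c(0.400, 0.071, 0.300, 0.320, 0.350),
                     sd   = c(0.015, 0.015, 0.020, 0.020, 0.020)),
      tibble::tibble(class = "vegetation", band = bands,
                     mean = c(0.370, 0.200, 0.060, 0.300, 0.450),
                     sd   = c(0.012, 0.012, 0.010, 0.020, 0.030)),
      tibble::tibble(class = "flower", band = bands,
                     mean = c(0.250, 0.450, 0.300, 0.400, 0.500),
                     sd   = c(0.020, 0.020, 0.020, 0.025, 0.030))
    )
  }
  need <- c("class", "band", "mean", "sd")
  if (!all(need %in% names(tbl))) {
    rlang::abort("preset must have columns class, band, mean, sd")
  }
  tbl$sd <- tbl$sd * sd_scale
  class(tbl) <- c("spectral_preset", class(tbl))
  tbl
}

BAND_WAVELENGTHS <- c(blue = 450, green = 560, red = 668, rededge = 717, nir = 840)

#' Generate a synthetic multispectral scene with ground truth
#'
#' Lays out soil, green vegetation and flowering canopy as spatially
#' coherent patches (a Gaussian-smoothed random field ranked and cut to
#' hit the requested class fractions exactly, up to rounding to whole
#' pixels), then draws per-pixel band reflectances from the class preset.
#' Identical arguments and seed give bit-identical output.
#'
#' @param width,height Scene size in pixels.
#' @param resolution Metres per pixel (default 0.027, a 2.7 cm GSD).
#' @param flower_fraction Target fraction of flower pixels in `[0, 1]`.
#' @param vegetation_fraction Target vegetation fraction; default half of
#'   the non-flower area. `flower_fraction + vegetation_fraction` must not
#'   exceed 1; the remainder is soil.
#' @param preset A [class_spectral_preset()].
#' @param patch_scale Gaussian smoothing radius (pixels) of the patch
#'   field; larger values give larger coherent patches.
#' @param stage Phenological stage label recorded in the truth (default
#'   `"flowering"`).
#' @param stage_height Mean canopy height (m) recorded in the truth;
#'   defaults to the [stage_heights()] value for `stage`.
#' @param kappa_true Area-to-mass coefficient (t per m^2 of flower area)
#'   recorded in the truth and used by [generate_yield_points()]. The
#'   default 0.0045 puts zone yields on the 3-5 t/ha scale of harvester
#'   yield maps.
#' @param seed Integer RNG seed; recorded in the truth.
#' @return A list with elements `raster` (a [multispectral_raster()]) and
#'   `truth` (class `scene_truth`: the per-pixel class grid, realized
#'   fractions, stage, stage height, `kappa_true` and the seed).
#' @export
generate_scene <- function(width, height, resolution = 0.027,
                           flower_fraction = 0.3,
                           vegetation_fraction = NULL,
                           preset = class_spectral_preset(),
                           patch_scale = 8, stage = "flowering",
                           stage_height = NULL, kappa_true = 0.0045,
                           seed = 1L) {
  if (flower_fraction < 0 || flower_fraction > 1) {
    rlang::abort("`flower_fraction` must lie in [0, 1]")
  }
  vegetation_fraction <- vegetation_fraction %||% ((1 - flower_fraction) / 2)
  if (flower_fraction + vegetation_fraction > 1 + 1e-12) {
    rlang::abort("flower and vegetation fractions must not sum above 1")
  }
  stage <- match.arg(stage, OSR_STAGES)
  stage_height <- stage_height %||%
    stage_heights()$height_m[match(stage, OSR_STAGES)]
  if (stage_height < 0 || stage_height > 3) {
    rlang::abort("`stage_height` must lie in [0, 3] m")
  }
  if (kappa_true <= 0) rlang::abort("`kappa_true` must be > 0")

  n <- width * height
  with_seed(seed, {
    field <- gauss_blur(matrix(stats::rnorm(n), height, width), patch_scale)
    # rank-cut the field: top n_f pixels flower, next n_v vegetation, rest soil
    n_f <- round(flower_fraction * n)
    n_v <- round(vegetation_fraction * n)
    ord <- order(field, decreasing = TRUE)
    class_grid <- matrix(1L, height, width)       # 1 = soil
    if (n_v > 0) class_grid[ord[seq_len(min(n, n_f + n_v))[-seq_len(n_f)]]] <- 2L
    if (n_f > 0) class_grid[ord[seq_len(n_f)]] <- 3L

    bands <- lapply(stats::setNames(nm = names(BAND_WAVELENGTHS)), function(bn) {
      m <- matrix(NA_real_, height, width)
      for (ci in seq_along(c("soil", "vegetation", "flower"))) {
        cls <- c("soil", "vegetation", "flower")[ci]
        row <- preset[preset$class == cls & preset$band == bn, ]
        idx <- which(class_grid == ci)
        m[idx] <- stats::rnorm(length(idx), mean = row$mean, sd = row$sd)
      }
      m
    })
    raster <- multispectral_raster(bands, resolution,
                                   wavelengths = BAND_WAVELENGTHS,
                                   crs = "synthetic-local")
    truth <- structure(
      list(class_grid = class_grid,
           class_levels = c("soil", "vegetation", "flower"),
           flower_fraction = sum(class_grid == 3L) / n,
           vegetation_fraction = sum(class_grid == 2L) / n,
           stage = stage, stage_height = stage_height,
           kappa_true = kappa_true, seed = as.integer(seed),
           resolution = resolution, origin = raster$origin),
      class = "scene_truth")
    list(raster = raster, truth = truth)
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d x %d px, flower %.3f, vegetation %.3f, stage %s (%.2f m), kappa %g, seed %d\n",
    nrow(x$class_grid), ncol(x$class_grid), x$flower_fraction,
    x$vegetation_fraction, x$stage, x$stage_height, x$kappa_true, x$seed))
  invisible(x)
}

#' Generate matched DSM and DTM rasters for a scene
#'
#' The terrain (DTM) is a smooth random surface with total relief about
#' `terrain_relief`; the surface model (DSM) adds the stage canopy height
#' over vegetation and flower pixels plus Gaussian measurement noise on
#' every pixel, so soil pixels have DSM approximately equal to DTM and the
#' canopy height model recovers `stage_height` over the canopy.
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @param terrain_relief Approximate peak-to-peak terrain variation (m).
#' @param noise_sd Standard deviation (m) of DSM measurement noise; 0 gives
#'   an exact surface.
#' @param base_elevation Mean terrain elevation (m).
#' @param seed Integer RNG seed.
#' @return A list with `dsm` and `dtm`, both [elevation_raster()]s.
#' @export
generate_elevation <- function(truth, terrain_relief = 0.5, noise_sd = 0.02,
                               base_elevation = 100, seed = 1L) {
  if (noise_sd < 0) rlang::abort("`noise_sd` must be >= 0")
  h <- nrow(truth$class_grid); w <- ncol(truth$class_grid)
  with_seed(seed, {
    rough <- gauss_blur(matrix(stats::rnorm(h * w), h, w), max(h, w) / 8)
    rng <- diff(range(rough))
    dtm_vals <- base_elevation +
      if (rng > 0) (rough - mean(rough)) * (terrain_relief / rng) else 0
    canopy <- truth$class_grid >= 2L
    dsm_vals <- dtm_vals + truth$stage_height * canopy
    if (noise_sd > 0) {
      dsm_vals <- dsm_vals + matrix(stats::rnorm(h * w, sd = noise_sd), h, w)
    }
    list(
      dsm = elevation_raster(dsm_vals, truth$resolution, kind = "DSM",
                             crs = "synthetic-local", origin = truth$origin),
      dtm = elevation_raster(dtm_vals, truth$resolution, kind = "DTM",
                             crs = "synthetic-local", origin = truth$origin)
    )
  })
}

#' Generate zone-level yield points coupled to flower density
#'
#' For each zone the noise-free actual yield is the pixel-fraction yield
#' estimator evaluated on the *true* flower pixels with `kappa_true`, and
#' the recorded yield multiplies it by `(1 + eps)`,
#' `eps ~ Normal(0, noise_cv)` — multiplicative harvester noise. Points are
#' placed at zone centres.
#'
#' @param truth A `scene_truth`.
#' @param zones A zones tibble ([zone_square()] / [read_zones()]).
#' @param kappa_true Area-to-mass coefficient; defaults to the one recorded
#'   in `truth`.
#' @param noise_cv Coefficient of variation of the multiplicative yield
#'   noise (0 = noise-free).
#' @param flower_to_pod Flower-to-pod conversion used for the truth yields
#'   (default 1).
#' @param seed Integer RNG seed.
#' @return A tibble with one row per zone: `id`, `x`, `y`, `yield` (t/ha),
#'   `yield_noise_free`, `flower_pixels`, `total_pixels`.
#' @export
generate_yield_points <- function(truth, zones, kappa_true = NULL,
                                  noise_cv = 0.05, flower_to_pod = 1,
                                  seed = 1L) {
  if (noise_cv < 0) rlang::abort("`noise_cv` must be >= 0")
  kappa_true <- kappa_true %||% truth$kappa_true
  dims <- dim(truth$class_grid)
  ext_x <- c(truth$origin[1], truth$origin[1] + dims[2] * truth$resolution)
  ext_y <- c(truth$origin[2] - dims[1] * truth$resolution, truth$origin[2])
  rows <- purrr::map(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    if (z$cx < ext_x[1] || z$cx > ext_x[2] || z$cy < ext_y[1] || z$cy > ext_y[2]) {
      rlang::abort(sprintf("zone '%s' lies outside the raster extent", z$id))
    }
    px <- zone_pixel_index(z, dims, truth$resolution, truth$origin)
    total <- nrow(px)
    flower <- if (total) sum(truth$class_grid[px] == 3L) else 0L
    y0 <- if (total == 0L || flower == 0L) 0 else {
      est <- estimate_yield(flower, total, truth$resolution,
                            area_ha = z$area_m2 / 1e4,
                            config = yield_config(kappa = kappa_true,
                                                  flower_to_pod = flower_to_pod))
      est$estimated
    }
    tibble::tibble(id = z$id, x = z$cx, y = z$cy,
                   yield_noise_free = y0,
                   flower_pixels = flower, total_pixels = total)
  })
  out <- dplyr::bind_rows(rows)
  with_seed(seed, {
    eps <- if (noise_cv > 0) stats::rnorm(nrow(out), sd = noise_cv) else rep(0, nrow(out))
    out$yield <- pmax(0, out$yield_noise_free * (1 + eps))
  })
  dplyr::relocate(out, id, x, y, yield, yield_noise_free)
}

#' Lay out a regular grid of square sampling zones over a raster
#'
#' @param raster Any raster of this package (or a `scene_truth`).
#' @param n Number of zones (rounded up to a full grid if not a perfect
#'   square count per row).
#' @param side Zone side length in metres.
#' @param margin Clearance from the raster edge in metres.
#' @return A zones tibble with `n` rows.
#' @export
make_zone_grid <- function(raster, n, side, margin = side / 2) {
  dims <- dim(if (inherits(raster, "scene_truth")) raster$class_grid else raster)
  res <- raster$resolution
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  ext_w <- dims[2] * res; ext_h <- dims[1] * res
  ncol_z <- ceiling(sqrt(n))
  nrow_z <- ceiling(n / ncol_z)
  usable_w <- ext_w - 2 * margin
  usable_h <- ext_h - 2 * margin
  if (usable_w < side * ncol_z || usable_h < side * nrow_z) {
    rlang::abort("zones do not fit: reduce `n`, `side` or `margin`")
  }
  cxs <- x0 + margin + (seq_len(ncol_z) - 0.5) * usable_w / ncol_z
  cys <- y0 - margin - (seq_len(nrow_z) - 0.5) * usable_h / nrow_z
  grid <- expand.grid(cx = cxs, cy = cys)[seq_len(n), ]
  dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    zone_square(grid$cx[i], grid$cy[i], side, id = sprintf("zone_%03d", i))
  }))
}
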