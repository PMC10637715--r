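#' Yield model configuration
#'
#' The pixel-fraction seed-yield estimator is
#' `estimated (t/ha) = F * P / A` with `F` the flower-pixel fraction,
#' `P = flower_area_m2 * kappa * flower_to_pod` the flower-derived mass
#' term in tonnes, and `A` the zone (or field) area in hectares. The
#' area-to-mass coefficient `kappa` (t per m^2 of classified flower area)
#' makes the heuristic "approximate flower area to a seed mass" explicit
#' and calibratable; it is never hard-wired to 1, and [calibrate_kappa()]
#' fits it against yield-monitor ground truth.
#'
#' @param kappa Tonnes of seed per square metre of classified flower area.
#' @param flower_to_pod Flower-to-pod conversion fraction in `(0, 1]`.
#'   Default 1 (every flower pixel contributes fully); 0.75 reflects
#'   ground-truth flower-to-pod conversion reported for oilseed rape.
#' @param window_side Default side (m) of square sampling windows.
#' @return A list of class `yield_config`.
#' @export
yield_config <- function(kappa = 0.0045, flower_to_pod = 1, window_side = 10) {
  if (kappa <= 0) rlang::abort("`kappa` must be > 0")
  if (flower_to_pod <= 0 || flower_to_pod > 1) {
    rlang::abort("`flower_to_pod` must lie in (0, 1]")
  }
  stopifnot_scalar_number(window_side, "window_side", positive = TRUE)
  structure(list(kappa = kappa, flower_to_pod = flower_to_pod,
                 window_side = window_side),
            class = "yield_config")
}

#' Pixel-fraction seed-yield estimate
#'
#' @param flower_pixels Number of pixels classified as flowering canopy.
#' @param total_pixels Total valid pixels in the zone or field.
#' @param resolution Metres per pixel side (flower area is
#'   `flower_pixels * resolution^2`).
#' @param area_ha Zone or field area in hectares.
#' @param config A [yield_config()].
#' @param id Optional zone identifier.
#' @return A one-row tibble (a yield sample): `id`, `F` (flower fraction),
#'   `flower_area_m2`, `P` (mass term, t), `A_ha`, `estimated` (t/ha).
#' @export
estimate_yield <- function(flower_pixels, total_pixels, resolution, area_ha,
                           config = yield_config(), id = NA_character_) {
  if (total_pixels <= 0) rlang::abort("`total_pixels` must be > 0")
  if (flower_pixels < 0 || flower_pixels > total_pixels) {
    rlang::abort("`flower_pixels` must lie in [0, total_pixels]")
  }
  if (area_ha <= 0) rlang::abort("`area_ha` must be > 0")
  f <- flower_pixels / total_pixels
  flower_area_m2 <- flower_pixels * resolution^2
  p <- flower_area_m2 * config$kappa * config$flower_to_pod
  tibble::tibble(id = id, F = f, flower_area_m2 = flower_area_m2,
                 P = p, A_ha = area_ha, estimated = f * p / area_ha)
}

#' Zonal yield estimation over a classified map
#'
#' Applies the pixel-fraction estimator per zone: pixels are clipped to
#' the zone by the pixel-centre rule, flower and total valid pixels
#' counted, and the estimator evaluated with the zone's own area. Zones
#' containing no valid pixels are flagged `excluded` and carry NA
#' estimates (they are dropped from validation statistics).
#'
#' @param class_map A `class_map` from [assign_classes()].
#' @param zones A zones tibble.
#' @param config A [yield_config()].
#' @return A tibble of yield samples, one row per zone, with columns of
#'   [estimate_yield()] plus `yield_class`, `flower_pixels`,
#'   `total_pixels`, `excluded`.
#' @export
estimate_yield_zones <- function(class_map, zones, config = yield_config()) {
  if (!inherits(class_map, "class_map")) rlang::abort("`class_map` must be a class_map")
  dims <- dim(class_map$labels)
  flower_code <- match("flower", class_map$class_levels)
  rows <- purrr::map(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    px <- zone_pixel_index(z, dims, class_map$resolution, class_map$origin)
    labs <- if (nrow(px)) class_map$labels[px] else integer(0)
    labs <- labs[!is.na(labs)]
    total <- length(labs)
    if (total == 0L) {
      return(tibble::tibble(id = z$id, F = NA_real_, flower_area_m2 = NA_real_,
                            P = NA_real_, A_ha = z$area_m2 / 1e4,
                            estimated = NA_real_, yield_class = z$yield_class,
                            flower_pixels = 0L, total_pixels = 0L,
                            excluded = TRUE))
    }
    flower <- sum(labs == flower_code)
    est <- estimate_yield(flower, total, class_map$resolution,
                          area_ha = z$area_m2 / 1e4, config = config, id = z$id)
    dplyr::mutate(est, yield_class = z$yield_class,
                  flower_pixels = flower, total_pixels = total,
                  excluded = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Calibrate the area-to-mass coefficient against actual yields
#'
#' Least-squares through the origin of actual yield on the estimator
#' prediction at `kappa = 1`: with `x = F * flower_area_m2 *
#' flower_to_pod / A_ha`, the fitted slope `sum(x * actual) / sum(x^2)` is
#' the kappa under which estimated yield best matches the ground truth.
#'
#' @param samples A yield-sample tibble (from [estimate_yield_zones()])
#'   with an `actual` column of ground-truth yields (t/ha). Excluded or
#'   NA rows are dropped.
#' @param flower_to_pod Conversion fraction used in the predictions.
#' @return Fitted `kappa` (t per m^2 of flower area).
#' @export
calibrate_kappa <- function(samples, flower_to_pod = 1) {
  if (!"actual" %in% names(samples)) {
    rlang::abort("`samples` must have an `actual` column of ground-truth yields")
  }
  s <- samples[!is.na(samples$actual) & !is.na(samples$F), ]
  if ("excluded" %in% names(s)) s <- s[!s$excluded, ]
  if (nrow(s) < 1L) rlang::abort("need at least one sample with an actual yield")
  x <- s$F * s$flower_area_m2 * flower_to_pod / s$A_ha
  if (all(x == 0)) rlang::abort("all predictions are zero; cannot calibrate kappa")
  sum(x * s$actual) / sum(x^2)
}

#' Full flower-to-yield pipeline on a multispectral raster
#'
#' NDYI computation, iso-cluster classification, cluster-to-class
#' grouping, zonal yield estimation, and — when actual yields are
#' supplied — validation statistics (Pearson r/R^2, RMSE, least-squares
#' fit). When `calibrate = TRUE` (default) kappa is fitted on the supplied
#' actual yields before the final estimates are produced; otherwise the
#' kappa in `config` is used as-is.
#'
#' @param raster A [multispectral_raster()] with `green` and `blue` bands.
#' @param zones A zones tibble.
#' @param params An [iso_params()].
#' @param config A [yield_config()].
#' @param actual Optional tibble `id`, `actual` of ground-truth zone
#'   yields (t/ha), e.g. from [generate_yield_points()] (column `yield`
#'   renamed) or a yield-monitor export aggregated to zones.
#' @param thresholds A [class_thresholds()].
#' @param calibrate Fit kappa on the actual yields before estimating?
#' @return A list of class `flower_yield_result`: `ndyi`, `clusters`,
#'   `class_map`, `samples` (tibble), `kappa`, `report` (a
#'   `validation_report` or NULL), `notice`.
#' @export
run_flower_yield_pipeline <- function(raster, zones, params = iso_params(),
                                      config = yield_config(), actual = NULL,
                                      thresholds = class_thresholds(),
                                      calibrate = !is.null(actual)) {
  ndyi <- compute_ndyi(raster)
  clusters <- isodata_classify(ndyi, params)
  class_map <- assign_classes(clusters, thresholds)
  samples <- estimate_yield_zones(class_map, zones, config)
  if (!is.null(actual)) {
    samples <- dplyr::left_join(samples, actual[, c("id", "actual")], by = "id")
  }
  kappa <- config$kappa
  notice <- NULL
  if (calibrate) {
    if (is.null(actual)) rlang::abort("`calibrate = TRUE` needs `actual` yields")
    ok <- !samples$excluded & !is.na(samples$actual)
    if (!any(ok) || all(samples$F[ok] * samples$flower_pixels[ok] == 0)) {
      notice <- "no flowering pixels in any zone; calibration and validation skipped"
      rlang::inform(notice)
    } else {
      kappa <- calibrate_kappa(samples, flower_to_pod = config$flower_to_pod)
      scale <- kappa / config$kappa
      samples$P <- samples$P * scale
      samples$estimated <- samples$estimated * scale
    }
  }
  report <- NULL
  if (!is.null(actual) && is.null(notice)) {
    ok <- !samples$excluded & !is.na(samples$actual)
    if (sum(ok) >= 3L && stats::sd(samples$estimated[ok]) > 0 &&
        stats::sd(samples$actual[ok]) > 0) {
      report <- validation_report(samples$estimated[ok], samples$actual[ok])
    } else {
      notice <- "too few (or degenerate) validation pairs; validation skipped"
      rlang::inform(notice)
    }
  }
  structure(list(ndyi = ndyi, clusters = clusters, class_map = class_map,
                 samples = samples, kappa = kappa, report = report,
                 notice = notice),
            class = "flower_yield_result")
}

#' @export
print.flower_yield_result <- function(x, ...) {
  cat(sprintf("<flower_yield_result> %d zones, kappa = %.6g\n",
              nrow(x$samples), x$kappa))
  print(x$class_map)
  if (!is.null(x$report)) print(x$report)
  if (!is.null(x$notice)) cat("note:", x$notice, "\n")
  invisible(x)
}
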