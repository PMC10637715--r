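#' Generic normalized-difference index
#'
#' Computes `(A - B) / (A + B)` per pixel for two named bands. Pixels are
#' masked where either band is nodata, where `A + B = 0` (the ratio is
#' undefined), or where the result falls outside `[-1, 1]` (possible only
#' when a calibrated product contains negative reflectances; such pixels
#' are counted and reported rather than clamped).
#'
#' @param raster A [multispectral_raster()].
#' @param band_a,band_b Band names; the index is positive where `band_a`
#'   dominates.
#' @return An [index_raster()] named `"nd_<a>_<b>"`.
#' @export
compute_normalized_difference <- function(raster, band_a, band_b) {
  if (!inherits(raster, "multispectral_raster")) {
    rlang::abort("`raster` must be a multispectral_raster")
  }
  for (b in c(band_a, band_b)) {
    if (!b %in% names(raster$bands)) {
      rlang::abort(sprintf("raster has no band named '%s' (bands: %s)",
                           b, paste(names(raster$bands), collapse = ", ")))
    }
  }
  if (identical(band_a, band_b)) {
    rlang::warn("band_a and band_b are the same band; the index is identically zero")
  }
  a <- raster$bands[[band_a]]
  b <- raster$bands[[band_b]]
  denom <- a + b
  vals <- (a - b) / denom
  mask <- raster$mask | denom == 0 | !is.finite(vals)
  vals[mask] <- NA_real_
  neg_inputs <- sum(!raster$mask & (a < 0 | b < 0))
  if (neg_inputs > 0) {
    rlang::inform(sprintf(
      "%d valid pixel(s) have negative input reflectance; out-of-range index values are masked",
      neg_inputs))
  }
  index_raster(vals, raster$resolution, mask = mask,
               index = sprintf("nd_%s_%s", band_a, band_b),
               crs = raster$crs, origin = raster$origin)
}

#' Normalized difference yellowness index (NDYI)
#'
#' NDYI = (Green - Blue) / (Green + Blue). Yellow oilseed-rape petals
#' reflect strongly in green and absorb in blue (carotenoids), so flowering
#' canopy pushes the index positive while green vegetation and bare soil
#' stay negative.
#'
#' @param raster A [multispectral_raster()] with bands named `green` and
#'   `blue`.
#' @return An [index_raster()] with `index = "ndyi"`.
#' @export
compute_ndyi <- function(raster) {
  out <- compute_normalized_difference(raster, "green", "blue")
  out$index <- "ndyi"
  out
}
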