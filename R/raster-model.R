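#' Multispectral raster
#'
#' An in-memory multispectral orthomosaic: named reflectance bands on a
#' common grid, a nodata mask, the ground sampling distance and an opaque
#' CRS tag. Grids are row-major with pixel `[1, 1]` at the top-left map
#' corner; a pixel covers the half-open square `[x, x + res) x (y - res, y]`
#' in map units, and the `origin` is the map coordinate of the top-left
#' corner (default `c(0, nrow * resolution)` so the extent sits in the
#' positive quadrant).
#'
#' @param bands Named list of numeric matrices, all with identical
#'   dimensions. Typical names: `blue`, `green`, `red`, `rededge`, `nir`.
#' @param resolution Ground size of one pixel side in metres (e.g. 0.027 m
#'   for the 2.7 cm ground sampling distance of a low-altitude UAV survey).
#' @param wavelengths Optional named numeric vector of band centre
#'   wavelengths in nm.
#' @param mask Optional logical matrix, `TRUE` where a pixel carries no data.
#'   Defaults to the union of non-finite values across bands.
#' @param crs Opaque coordinate reference system tag (pass-through only; the
#'   package never reprojects).
#' @param origin Map coordinate `c(x, y)` of the top-left raster corner.
#' @return An object of class `multispectral_raster`.
#' @export
multispectral_raster <- function(bands, resolution, wavelengths = NULL,
                                 mask = NULL, crs = "local", origin = NULL) {
  if (!is.list(bands) || length(bands) == 0L || is.null(names(bands)) ||
      any(!nzchar(names(bands)))) {
    rlang::abort("`bands` must be a non-empty named list of matrices.")
  }
  dims <- dim(bands[[1]])
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b) || !identical(dim(b), dims)) {
      rlang::abort(sprintf("band '%s' does not match the grid of the first band", nm))
    }
    storage.mode(bands[[nm]]) <- "double"
  }
  stopifnot_scalar_number(resolution, "resolution", positive = TRUE)
  if (is.null(mask)) {
    mask <- Reduce(`|`, lapply(bands, function(b) !is.finite(b)))
  }
  if (!is.logical(mask) || !identical(dim(mask), dims)) {
    rlang::abort("`mask` must be a logical matrix matching the band grid.")
  }
  for (nm in names(bands)) {
    if (any(!is.finite(bands[[nm]][!mask]))) {
      rlang::abort(sprintf("band '%s' has non-finite values outside the nodata mask", nm))
    }
  }
  origin <- origin %||% c(0, dims[1] * resolution)
  structure(
    list(bands = bands, resolution = resolution,
         wavelengths = wavelengths, mask = mask, crs = crs,
         origin = as.numeric(origin)),
    class = c("multispectral_raster", "osr_raster")
  )
}

#' Single-band index raster
#'
#' Holds per-pixel values of a normalized-difference index, constrained to
#' `[-1, 1]` on valid pixels; out-of-range or undefined pixels are masked.
#'
#' @param values Numeric matrix of index values.
#' @param resolution Metres per pixel side.
#' @param mask Logical nodata matrix (`TRUE` = nodata).
#' @param index Short name of the index (e.g. `"ndyi"`).
#' @inheritParams multispectral_raster
#' @return An object of class `index_raster`.
#' @export
index_raster <- function(values, resolution, mask = NULL, index = "ndyi",
                         crs = "local", origin = NULL) {
  if (!is.matrix(values)) rlang::abort("`values` must be a matrix.")
  storage.mode(values) <- "double"
  stopifnot_scalar_number(resolution, "resolution", positive = TRUE)
  mask <- mask %||% !is.finite(values)
  bad <- !mask & (!is.finite(values) | values < -1 | values > 1)
  mask <- mask | bad
  origin <- origin %||% c(0, nrow(values) * resolution)
  structure(
    list(values = values, mask = mask, resolution = resolution,
         index = index, crs = crs, origin = as.numeric(origin),
         n_out_of_range = sum(bad)),
    class = c("index_raster", "osr_raster")
  )
}

#' Elevation raster (DSM, DTM or CHM)
#'
#' @param values Numeric matrix of elevations in metres.
#' @param kind One of `"DSM"` (digital surface model), `"DTM"` (digital
#'   terrain model) or `"CHM"` (canopy height model).
#' @param provenance For a CHM, a character note recording the DSM and DTM
#'   it was derived from.
#' @inheritParams index_raster
#' @return An object of class `elevation_raster`.
#' @export
elevation_raster <- function(values, resolution, kind = c("DSM", "DTM", "CHM"),
                             mask = NULL, crs = "local", origin = NULL,
                             provenance = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) rlang::abort("`values` must be a matrix.")
  storage.mode(values) <- "double"
  stopifnot_scalar_number(resolution, "resolution", positive = TRUE)
  mask <- mask %||% !is.finite(values)
  if (any(!is.finite(values[!mask]))) {
    rlang::abort("elevation values outside the nodata mask must be finite")
  }
  origin <- origin %||% c(0, nrow(values) * resolution)
  structure(
    list(values = values, mask = mask, resolution = resolution,
         kind = kind, crs = crs, origin = as.numeric(origin),
         provenance = provenance),
    class = c("elevation_raster", "osr_raster")
  )
}

#' @export
dim.osr_raster <- function(x) {
  if (!is.null(x$values)) dim(x$values) else dim(x$bands[[1]])
}

#' @export
print.osr_raster <- function(x, ...) {
  d <- dim(x)
  kind <- if (inherits(x, "multispectral_raster")) {
    sprintf("multispectral (%s)", paste(names(x$bands), collapse = ", "))
  } else if (inherits(x, "index_raster")) {
    sprintf("index [%s]", x$index)
  } else {
    sprintf("elevation [%s]", x$kind)
  }
  cat(sprintf("<osr_raster> %s, %d x %d px @ %g m/px, %d nodata px, crs '%s'\n",
              kind, d[1], d[2], x$resolution, sum(x$mask), x$crs))
  invisible(x)
}

#' Ground area of one pixel in square metres
#' @param raster Any raster object of this package.
#' @return Scalar area in m^2 (resolution squared).
#' @export
pixel_area <- function(raster) raster$resolution^2

#' Valid (unmasked) values of a single-band raster
#' @param raster An `index_raster` or `elevation_raster`.
#' @return Numeric vector of valid pixel values.
#' @export
valid_values <- function(raster) raster$values[!raster$mask]

# --- GeoTIFF I/O ------------------------------------------------------------

raster_meta <- function(raster) {
  if (inherits(raster, "multispectral_raster")) {
    list(osryield = 1L, kind = "multispectral",
         band_names = names(raster$bands),
         wavelengths = raster$wavelengths,
         resolution = raster$resolution, crs = raster$crs,
         origin = raster$origin)
  } else if (inherits(raster, "index_raster")) {
    list(osryield = 1L, kind = "index", index = raster$index,
         resolution = raster$resolution, crs = raster$crs,
         origin = raster$origin)
  } else {
    list(osryield = 1L, kind = raster$kind,
         resolution = raster$resolution, crs = raster$crs,
         origin = raster$origin, provenance = raster$provenance)
  }
}

#' Write a raster to a GeoTIFF file
#'
#' Bands are stored as uncompressed 64-bit IEEE floats, one TIFF page per
#' band, so `read_raster(write_raster(r, path))` reproduces valid pixel
#' values bit-for-bit. Nodata pixels are written as NaN; band names,
#' wavelengths, resolution, raster kind and the CRS tag travel in the
#' ImageDescription metadata, and the pixel size additionally in the GeoTIFF
#' ModelPixelScale tag.
#'
#' @param raster A `multispectral_raster`, `index_raster` or
#'   `elevation_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  if (!inherits(raster, "osr_raster")) rlang::abort("not a raster object")
  dir <- dirname(path)
  if (!dir.exists(dir)) rlang::abort(sprintf("directory does not exist: %s", dir))
  pages <- if (inherits(raster, "multispectral_raster")) raster$bands else list(raster$values)
  pages <- lapply(pages, function(p) { p[raster$mask] <- NaN; p })
  desc <- jsonlite::toJSON(raster_meta(raster), auto_unbox = TRUE, digits = NA, null = "null")
  tiff_write_pages(path, pages, as.character(desc), raster$resolution)
  invisible(path)
}

DEFAULT_BAND_NAMES <- c("blue", "green", "red", "rededge", "nir")

#' Read a raster from a GeoTIFF file
#'
#' @param path Path to a GeoTIFF. Files written by [write_raster()] carry
#'   full metadata; plain single/multi-page float TIFFs from other tools are
#'   accepted with positional default band names
#'   (blue, green, red, rededge, nir).
#' @param kind What to construct: `"multispectral"` (default for multi-band
#'   files), `"index"`, `"DSM"`, `"DTM"` or `"CHM"`. Defaults to the kind
#'   recorded in the file metadata.
#' @param band_names Override band names for multispectral files.
#' @return A raster object of the requested kind.
#' @export
read_raster <- function(path, kind = NULL, band_names = NULL) {
  tf <- tiff_read_pages(path)
  meta <- NULL
  if (!is.null(tf$description) && grepl("osryield", tf$description, fixed = TRUE)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  }
  kind <- kind %||% meta$kind %||% if (length(tf$pages) > 1L) "multispectral" else "index"
  res <- meta$resolution %||% tf$pixel_scale[1] %||% 1
  crs <- meta$crs %||% "unknown"
  origin <- meta$origin
  n_bands <- length(tf$pages)
  mask_of <- function(m) !is.finite(m)

  if (identical(kind, "multispectral")) {
    nms <- band_names %||% meta$band_names %||% DEFAULT_BAND_NAMES[seq_len(n_bands)]
    if (length(nms) != n_bands) {
      rlang::abort(sprintf(
        "file has %d band(s) but %d band name(s) were requested", n_bands, length(nms)))
    }
    bands <- stats::setNames(tf$pages, nms)
    mask <- Reduce(`|`, lapply(bands, mask_of))
    wl <- meta$wavelengths
    if (!is.null(wl)) wl <- stats::setNames(as.numeric(wl), nms)
    multispectral_raster(bands, res, wavelengths = wl, mask = mask,
                         crs = crs, origin = origin)
  } else if (identical(kind, "index")) {
    if (n_bands != 1L) rlang::abort("index raster file must have exactly one band")
    index_raster(tf$pages[[1]], res, mask = mask_of(tf$pages[[1]]),
                 index = meta$index %||% "index", crs = crs, origin = origin)
  } else if (kind %in% c("DSM", "DTM", "CHM")) {
    if (n_bands != 1L) rlang::abort(sprintf("%s file must have exactly one band", kind))
    elevation_raster(tf$pages[[1]], res, kind = kind,
                     mask = mask_of(tf$pages[[1]]), crs = crs, origin = origin,
                     provenance = meta$provenance)
  } else {
    rlang::abort(sprintf("unknown raster kind '%s'", kind))
  }
}

# --- Yield points and zones -------------------------------------------------

#' Read harvester-style yield points from CSV
#'
#' Expects a header `x,y,yield` with coordinates in metres and yield in
#' t/ha, the format a combine-mounted yield monitor export reduces to.
#' Malformed or negative rows are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return A tibble with columns `x`, `y`, `yield`.
#' @export
read_yield_points <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "yield")
  if (!all(need %in% names(df))) {
    rlang::abort("yield CSV must have header columns x, y, yield")
  }
  df <- df[need]
  num <- vapply(df, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(NULL, need))
  bad <- which(apply(num, 1, function(r) any(!is.finite(r))) | num[, "yield"] < 0)
  if (length(bad)) {
    rlang::abort(sprintf(
      "invalid yield rows (non-numeric or negative yield) at data row(s): %s",
      paste(bad, collapse = ", ")))
  }
  tibble::tibble(x = num[, "x"], y = num[, "y"], yield = num[, "yield"])
}

#' Write yield points to CSV
#' @param points Tibble with columns `x`, `y`, `yield`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yield_points <- function(points, path) {
  utils::write.csv(points[, c("x", "y", "yield")], path, row.names = FALSE)
  invisible(path)
}

#' Construct sampling zones
#'
#' Zones are the sampling footprints over which flower pixels are counted
#' and the yield estimator evaluated: either square windows (centre plus
#' side length, the default sampling design) or arbitrary polygons.
#'
#' @param cx,cy Window centre in map metres.
#' @param side Window side length in metres.
#' @param id Zone identifier.
#' @param yield_class Optional label: `low`, `medium`, `high`, `very_high`.
#' @return A one-row zones tibble; bind rows to build a zone set.
#' @export
zone_square <- function(cx, cy, side, id = NULL, yield_class = NA_character_) {
  stopifnot_scalar_number(side, "side", positive = TRUE)
  tibble::tibble(
    id = as.character(id %||% sprintf("z_%g_%g", cx, cy)),
    yield_class = yield_class, kind = "square",
    cx = cx, cy = cy, side = side,
    poly = list(NULL),
    area_m2 = side^2
  )
}

#' @rdname zone_square
#' @param coords Two-column matrix of polygon vertices (x, y in metres).
#' @export
zone_polygon <- function(coords, id, yield_class = NA_character_) {
  coords <- as.matrix(coords)
  a <- polygon_area(coords)
  if (a <= 0) rlang::abort("zone polygon must have positive area")
  tibble::tibble(
    id = as.character(id), yield_class = yield_class, kind = "polygon",
    cx = mean(coords[, 1]), cy = mean(coords[, 2]), side = NA_real_,
    poly = list(coords), area_m2 = a
  )
}

#' Read zones from a GeoJSON feature collection
#'
#' Polygon features become polygon zones; Point features with a `side`
#' property become square windows. Feature properties `id` and
#' `yield_class` are carried through.
#'
#' @param path GeoJSON file path.
#' @return A zones tibble (one row per zone).
#' @export
read_zones <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    rlang::abort("zones file must be a GeoJSON FeatureCollection")
  }
  rows <- purrr::imap(gj$features, function(f, i) {
    props <- f$properties %||% list()
    id <- as.character(props$id %||% sprintf("zone_%03d", i))
    yc <- props$yield_class %||% NA_character_
    geom <- f$geometry
    if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      n <- nrow(coords)
      if (n > 1L && all(coords[1, ] == coords[n, ])) {
        coords <- coords[-n, , drop = FALSE]
      }
      zone_polygon(coords, id = id, yield_class = yc)
    } else if (identical(geom$type, "Point")) {
      side <- props$side
      if (is.null(side)) rlang::abort(sprintf(
        "Point zone feature %d needs a 'side' property (window side, m)", i))
      zone_square(geom$coordinates[[1]], geom$coordinates[[2]],
                  as.numeric(side), id = id, yield_class = yc)
    } else {
      rlang::abort(sprintf("unsupported zone geometry '%s' in feature %d",
                           geom$type %||% "?", i))
    }
  })
  dplyr::bind_rows(rows)
}

#' Write zones to GeoJSON
#' @param zones A zones tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones <- function(zones, path) {
  feats <- purrr::pmap(zones, function(id, yield_class, kind, cx, cy, side, poly,
                                       area_m2, ...) {
    props <- list(id = id)
    if (!is.na(yield_class)) props$yield_class <- yield_class
    if (identical(kind, "square")) {
      props$side <- side
      list(type = "Feature", properties = props,
           geometry = list(type = "Point", coordinates = c(cx, cy)))
    } else {
      ring <- lapply(seq_len(nrow(poly)), function(i) as.numeric(poly[i, ]))
      if (!identical(ring[[1]], ring[[length(ring)]])) ring <- c(ring, ring[1])
      list(type = "Feature", properties = props,
           geometry = list(type = "Polygon", coordinates = list(ring)))
    }
  })
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Row/col indices of pixels whose centre falls inside a zone, under the
# half-open pixel model: centre of pixel (i, j) is
# (x0 + (j - 0.5) res, y0 - (i - 0.5) res); a square window of side s at
# centre (cx, cy) owns centres in [cx - s/2, cx + s/2) x (cy - s/2, cy + s/2].
zone_pixel_index <- function(zone, dims, resolution, origin) {
  h <- dims[1]; w <- dims[2]
  x0 <- origin[1]; y0 <- origin[2]
  if (identical(zone$kind, "square")) {
    xmin <- zone$cx - zone$side / 2; xmax <- zone$cx + zone$side / 2
    ymin <- zone$cy - zone$side / 2; ymax <- zone$cy + zone$side / 2
    j <- seq_len(w); i <- seq_len(h)
    xc <- x0 + (j - 0.5) * resolution
    yc <- y0 - (i - 0.5) * resolution
    jj <- j[xc >= xmin & xc < xmax]
    ii <- i[yc > ymin & yc <= ymax]
    if (!length(ii) || !length(jj)) return(cbind(row = integer(0), col = integer(0)))
    cbind(row = rep(ii, times = length(jj)), col = rep(jj, each = length(ii)))
  } else {
    poly <- zone$poly[[1]]
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    j <- seq_len(w); i <- seq_len(h)
    xc <- x0 + (j - 0.5) * resolution
    yc <- y0 - (i - 0.5) * resolution
    jj <- j[xc >= xr[1] & xc <= xr[2]]
    ii <- i[yc >= yr[1] & yc <= yr[2]]
    if (!length(ii) || !length(jj)) return(cbind(row = integer(0), col = integer(0)))
    grid <- cbind(x = rep(xc[match(jj, j)], each = length(ii)),
                  y = rep(yc[match(ii, i)], times = length(jj)))
    bnd <- poly
    if (any(bnd[1, ] != bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
    inside <- mgcv::in.out(bnd, grid)
    sel <- which(inside)
    cbind(row = rep(ii, times = length(jj))[sel],
          col = rep(jj, each = length(ii))[sel])
  }
}
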