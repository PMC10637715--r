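# Minimal GeoTIFF codec for floating-point raster pages.
#
# Rasters here are IEEE-float grids (reflectance, index values, metres) with
# an NaN nodata sentinel, which rules out the 8/16-bit image-oriented TIFF
# writers: values must survive a round trip bit-for-bit. This codec writes
# classic little-endian TIFF, one IFD per band, uncompressed 64-bit float
# samples, a JSON sidecar payload in ImageDescription (band names,
# wavelengths, resolution, CRS tag, raster kind, origin) and the GeoTIFF
# ModelPixelScale tag. The reader also accepts 32-bit float and unsigned
# integer samples and multi-strip layouts produced by other tools.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 1L, 4L, 8L, 4L, 8L)

# pages: list of numeric matrices (all same dim); description: scalar string.
tiff_write_pages <- function(path, pages, description, resolution) {
  stopifnot(is.list(pages), length(pages) >= 1L)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  for (p in pages) {
    if (nrow(p) != h || ncol(p) != w) rlang::abort("all pages must share one grid")
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  desc_raw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  n_pages <- length(pages)
  page_bytes <- as.double(w) * h * 8

  # layout: header | page data ... | description | pixel-scale doubles | IFDs
  off_data <- 8
  off_desc <- off_data + n_pages * page_bytes
  off_scale <- off_desc + length(desc_raw)
  off_ifd1 <- off_scale + 24
  n_tags <- function(first) if (first) 12L else 10L
  ifd_size <- function(first) 2 + 12 * n_tags(first) + 4
  ifd_offsets <- numeric(n_pages)
  o <- off_ifd1
  for (i in seq_len(n_pages)) {
    ifd_offsets[i] <- o
    o <- o + ifd_size(i == 1L)
  }
  if (o > 2^31 - 1) rlang::abort("raster too large for classic TIFF offsets")

  # header
  writeBin(charToRaw("II"), con)
  wr2(42L)
  wr4(ifd_offsets[1])
  # pixel data, row-major strips
  for (p in pages) {
    v <- as.vector(t(p))
    writeBin(as.double(v), con, size = 8, endian = "little")
  }
  writeBin(desc_raw, con)
  writeBin(as.double(c(resolution, resolution, 0)), con, size = 8, endian = "little")

  tag <- function(id, type, count, value) list(id = id, type = type, count = count, value = value)
  for (i in seq_len(n_pages)) {
    first <- i == 1L
    tags <- list(
      tag(256L, 4L, 1L, w),                               # ImageWidth
      tag(257L, 4L, 1L, h),                               # ImageLength
      tag(258L, 3L, 1L, 64L),                             # BitsPerSample
      tag(259L, 3L, 1L, 1L),                              # Compression: none
      tag(262L, 3L, 1L, 1L)                               # Photometric: min-is-black
    )
    if (first) {
      tags <- c(tags, list(tag(270L, 2L, length(desc_raw), off_desc)))
    }
    tags <- c(tags, list(
      tag(273L, 4L, 1L, off_data + (i - 1L) * page_bytes), # StripOffsets
      tag(277L, 3L, 1L, 1L),                               # SamplesPerPixel
      tag(278L, 4L, 1L, h),                                # RowsPerStrip
      tag(279L, 4L, 1L, page_bytes),                       # StripByteCounts
      tag(339L, 3L, 1L, 3L)                                # SampleFormat: IEEE float
    ))
    if (first) {
      tags <- c(tags, list(tag(33550L, 12L, 3L, off_scale))) # ModelPixelScale
    }
    wr2(length(tags))
    for (tg in tags) {
      wr2(tg$id); wr2(tg$type); wr4(tg$count)
      if (tg$type == 3L && tg$count == 1L) {
        wr2(tg$value); wr2(0L)          # SHORT packed into low bytes
      } else {
        wr4(tg$value)
      }
    }
    wr4(if (i < n_pages) ifd_offsets[i + 1L] else 0L)
  }
  invisible(path)
}

# Returns list(pages = list of matrices, description = chr, pixel_scale = num).
tiff_read_pages <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) rlang::abort("not a TIFF file (truncated header)")
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   rlang::abort("not a TIFF file (bad byte-order mark)"))
  rd_int <- function(off, size, n = 1L) {
    readBin(raw_all[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  }
  rd_dbl <- function(off, size, n = 1L) {
    readBin(raw_all[(off + 1):(off + size * n)], "double", n = n, size = size,
            endian = endian)
  }
  if (rd_int(2, 2) != 42L) rlang::abort("not a TIFF file (bad magic)")

  pages <- list(); description <- NULL; pixel_scale <- NULL
  ifd_off <- rd_int(4, 4)
  while (ifd_off != 0L) {
    n_tags <- rd_int(ifd_off, 2)
    tags <- list()
    for (ti in seq_len(n_tags)) {
      base <- ifd_off + 2 + (ti - 1L) * 12
      id <- rd_int(base, 2); type <- rd_int(base + 2, 2); count <- rd_int(base + 4, 4)
      tsz <- if (type >= 1L && type <= 12L) TIFF_TYPE_SIZES[type] else 1L
      val_off <- if (tsz * count <= 4L) base + 8 else rd_int(base + 8, 4)
      value <- switch(as.character(type),
        `2`  = {
          ch <- raw_all[(val_off + 1):(val_off + count)]
          rawToChar(ch[ch != as.raw(0L)])
        },
        `3`  = rd_int(val_off, 2, count),
        `4`  = rd_int(val_off, 4, count),
        `11` = rd_dbl(val_off, 4, count),
        `12` = rd_dbl(val_off, 8, count),
        rd_int(val_off, 1, min(count, 4L))
      )
      tags[[as.character(id)]] <- value
    }
    gt <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- gt(256); h <- gt(257)
    if (is.null(w) || is.null(h)) rlang::abort("TIFF IFD lacks image dimensions")
    bits <- gt(258, 1L)[1]
    if ((gt(259, 1L))[1] != 1L) rlang::abort("compressed TIFF not supported")
    if ((gt(277, 1L))[1] != 1L) rlang::abort("only one sample per pixel supported")
    fmt <- gt(339, 1L)[1]
    strip_off <- gt(273); strip_cnt <- gt(279)
    if (is.null(strip_off) || is.null(strip_cnt)) rlang::abort("TIFF IFD lacks strip layout")
    bytes_per <- bits / 8L
    vals <- numeric(0)
    for (si in seq_along(strip_off)) {
      n_here <- strip_cnt[si] / bytes_per
      vals <- c(vals, if (fmt == 3L) rd_dbl(strip_off[si], bytes_per, n_here)
                      else rd_int(strip_off[si], bytes_per, n_here))
    }
    if (length(vals) != w * h) rlang::abort("TIFF strip data does not match dimensions")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    if (is.null(description)) description <- gt(270)
    if (is.null(pixel_scale)) pixel_scale <- gt(33550)
    ifd_off <- rd_int(ifd_off + 2 + n_tags * 12, 4)
  }
  list(pages = pages, description = description, pixel_scale = pixel_scale)
}
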