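#' Canopy height model from surface and terrain models
#'
#' `CHM = DSM - DTM`, per pixel, masked wherever either input is masked.
#' Negative heights (terrain-model overshoot) are retained, not clamped;
#' their count is recorded in the result so quality problems stay visible.
#'
#' @param dsm An [elevation_raster()] of kind `"DSM"`.
#' @param dtm An [elevation_raster()] of kind `"DTM"` on the same grid.
#' @return An [elevation_raster()] of kind `"CHM"` with a
#'   `n_negative` field and a provenance note naming its inputs.
#' @export
compute_chm <- function(dsm, dtm) {
  if (!inherits(dsm, "elevation_raster") || dsm$kind != "DSM") {
    rlang::abort("`dsm` must be an elevation_raster of kind DSM")
  }
  if (!inherits(dtm, "elevation_raster") || dtm$kind != "DTM") {
    rlang::abort("`dtm` must be an elevation_raster of kind DTM")
  }
  if (!identical(dim(dsm$values), dim(dtm$values)) ||
      dsm$resolution != dtm$resolution) {
    rlang::abort("DSM and DTM must share grid dimensions and resolution")
  }
  vals <- dsm$values - dtm$values
  mask <- dsm$mask | dtm$mask
  vals[mask] <- NA_real_
  out <- elevation_raster(vals, dsm$resolution, kind = "CHM", mask = mask,
                          crs = dsm$crs, origin = dsm$origin,
                          provenance = "CHM = DSM - DTM (this session)")
  out$n_negative <- sum(vals[!mask] < 0)
  out
}

#' Height distribution summary for one growth stage
#'
#' Order statistics and the mean of the canopy height model over valid
#' pixels, after excluding values below `mask_below` (default 0, which
#' drops negative-height artefacts from the summary while
#' [compute_chm()] keeps them in the raster). Quartiles use linear
#' interpolation between order statistics.
#'
#' @param chm An [elevation_raster()] of kind `"CHM"`.
#' @param stage_label Phenological stage label for the summary row.
#' @param mask_below Exclude pixels with height below this value (m).
#' @return A one-row tibble: `stage`, `n`, `min`, `q1`, `median`, `mean`,
#'   `q3`, `max` (metres).
#' @export
summarize_heights <- function(chm, stage_label, mask_below = 0) {
  if (!inherits(chm, "elevation_raster") || chm$kind != "CHM") {
    rlang::abort("`chm` must be an elevation_raster of kind CHM")
  }
  v <- valid_values(chm)
  v <- v[v >= mask_below]
  if (length(v) < 1L) {
    rlang::abort("no valid pixels remain after masking; nothing to summarize")
  }
  q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(stage = stage_label, n = length(v),
                 min = min(v), q1 = q[1], median = q[2], mean = mean(v),
                 q3 = q[3], max = max(v))
}

#' Growth-stage height series
#'
#' Orders per-stage height summaries by phenological stage (rosette,
#' bolting, flowering, podding, ripening) and flags the stage with the
#' maximum mean canopy height.
#'
#' @param summaries A tibble of [summarize_heights()] rows, one per stage.
#' @return The ordered tibble with a logical `is_max_mean` column.
#' @export
stage_series <- function(summaries) {
  if (nrow(summaries) < 2L) {
    rlang::abort("a stage series needs at least 2 stages")
  }
  if (anyDuplicated(summaries$stage)) {
    rlang::abort("duplicate stage labels in the series")
  }
  unknown <- setdiff(summaries$stage, OSR_STAGES)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown stage label(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- summaries[order(match(summaries$stage, OSR_STAGES)), ]
  out$is_max_mean <- seq_len(nrow(out)) == which.max(out$mean)
  out
}
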