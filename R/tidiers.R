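#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster map
#'
#' @param x A `cluster_map`.
#' @param ... Unused.
#' @return A tibble with one row per cluster: `cluster`, `mean`, `size`.
#' @method tidy cluster_map
#' @export
tidy.cluster_map <- function(x, ...) {
  tibble::tibble(cluster = seq_along(x$means), mean = x$means, size = x$sizes)
}

#' @rdname tidy.cluster_map
#' @method glance cluster_map
#' @export
glance.cluster_map <- function(x, ...) {
  tibble::tibble(k = length(x$means), iterations = x$iterations,
                 converged = x$converged, degenerate = x$degenerate,
                 wss = x$wss)
}

#' Tidy a class map
#'
#' @param x A `class_map`.
#' @param ... Unused.
#' @return The cluster table: `cluster`, `mean`, `size`, `class`.
#' @method tidy class_map
#' @export
tidy.class_map <- function(x, ...) x$cluster_table

#' @rdname tidy.class_map
#' @method glance class_map
#' @export
glance.class_map <- function(x, ...) {
  cc <- as.list(x$class_counts)
  tibble::tibble(soil = cc$soil, vegetation = cc$vegetation,
                 flower = cc$flower, unclassified = cc$unclassified,
                 flower_fraction = cc$flower / max(1L, sum(x$class_counts)))
}

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A tibble of the paired observations: `estimated`, `actual`,
#'   `residual`.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  tibble::tibble(estimated = x$estimated, actual = x$actual,
                 residual = x$actual - x$estimated)
}

#' @rdname tidy.validation_report
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(n = x$n, r = x$r, r2 = x$r2, rmse = x$rmse,
                 slope = x$slope, intercept = x$intercept)
}

#' Tidy a pipeline result
#'
#' @param x A `flower_yield_result` from [run_flower_yield_pipeline()].
#' @param ... Unused.
#' @return The per-zone yield-sample tibble.
#' @method tidy flower_yield_result
#' @export
tidy.flower_yield_result <- function(x, ...) x$samples

#' @rdname tidy.flower_yield_result
#' @method glance flower_yield_result
#' @export
glance.flower_yield_result <- function(x, ...) {
  base <- tibble::tibble(
    n_zones = nrow(x$samples), kappa = x$kappa,
    flower_pixels = count_class_pixels(x$class_map, "flower"))
  if (!is.null(x$report)) {
    dplyr::bind_cols(base, glance(x$report))
  } else {
    base
  }
}
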