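#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-component table of a
#' fitted or derived object (fitted bands, phase assignments, trajectory
#' fields), `glance()` a one-row summary (fit quality, conservation
#' report).
#'
#' @param x A `band_fit`, `indexing_result` or `depot_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @name depotmap-tidiers
NULL

#' @rdname depotmap-tidiers
#' @export
tidy.band_fit <- function(x, ...) {
  x$bands
}

#' @rdname depotmap-tidiers
#' @export
glance.band_fit <- function(x, ...) {
  tibble::tibble(n_bands = nrow(x$bands), rss = x$rss,
                 converged = x$converged,
                 n_flags = length(x$flags))
}

#' @rdname depotmap-tidiers
#' @export
tidy.indexing_result <- function(x, ...) {
  dplyr::mutate(x$assignments,
                peak_q = purrr::map(.data$peak_q, identity))
}

#' @rdname depotmap-tidiers
#' @export
glance.indexing_result <- function(x, ...) {
  tibble::tibble(
    n_phases = sum(x$assignments$phase != "isotropic"),
    n_unassigned = nrow(x$unassigned),
    isotropic = any(x$assignments$phase == "isotropic")
  )
}

#' @rdname depotmap-tidiers
#' @export
tidy.depot_trajectory <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname depotmap-tidiers
#' @export
glance.depot_trajectory <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_checkpoints = length(unique(x$time_days)),
                   horizon_days = max(x$time_days)),
    attr(x, "conservation")
  )
}
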