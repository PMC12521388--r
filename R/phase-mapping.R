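#' Scattering invariant
#'
#' Porod invariant `Q = integral of q^2 I(q) dq` over the measured
#' q-range by trapezoidal quadrature. `Q` is independent of the
#' structural arrangement and proportional to the scattering volume in
#' the beam, which makes it the per-pixel mass proxy used to mask depot
#' pixels against buffer.
#'
#' @param curve Data frame with columns `q` and `intensity`.
#' @return Scalar invariant (intensity times 1/Angstrom cubed).
#' @examples
#' cur <- tibble::tibble(q = seq(0, 0.3, 1e-3), intensity = 2)
#' saxs_invariant(cur) # 2 * 0.3^3 / 3 = 0.018
#' @export
saxs_invariant <- function(curve) {
  if (!all(c("q", "intensity") %in% names(curve))) {
    abort("a scattering curve needs columns `q` and `intensity`")
  }
  if (nrow(curve) < 2) abort("need at least two points to integrate")
  pracma::trapz(curve$q, curve$q^2 * curve$intensity)
}

# share of the (111) reflection in the peak invariant of a pure Fd3m
# pattern with geometric intensity decay, truncated to the q-range;
# inverse of the fraction normalisation constant
fd3m_111_share <- function(lattice_a, q_max, decay = 0.5) {
  ratios <- phase_library()$ratios[[1]]
  q1 <- first_reflection_q("Fd3m", lattice_a)
  keep <- q1 * ratios <= q_max
  1 / sum(ratios[keep]^2 * decay^(seq_along(ratios)[keep] - 1))
}

#' Cubic-phase fraction of a scattering curve
#'
#' Invariant-normalised Fd3m content: the (111) reflection is selected
#' as the highest peak inside the search window, and the numerator
#' integrates `q^2 I_cub` over that peak's region (three FWHM to either
#' side), where `I_cub` is the baseline-subtracted intensity with a
#' local linear pedestal (connecting the region edges) removed; the
#' denominator integrates `q^2 I` over the whole baseline-subtracted
#' curve, i.e. the total Bragg invariant. The ratio is rescaled by the
#' analytic (111) share of a pure-Fd3m pattern at the recovered lattice
#' parameter (so a single-phase Fd3m curve reads 1) and clipped to
#' `[0, 1]`. Without a peak in the window the fraction is 0; without any
#' peaks the result carries an `"isotropic"` flag.
#'
#' @param curve Baseline-subtracted curve (see [subtract_baseline()]).
#' @param window (111) search window in 1/Angstrom.
#' @param peaks Optional pre-computed [detect_peaks()] result.
#' @param decay Reflection-intensity decay convention of the
#'   normalisation (matching the generator's default).
#' @return Fraction in `[0, 1]`, possibly with attribute `flag`.
#' @export
cubic_fraction <- function(curve, window = c(0.058, 0.085), peaks = NULL,
                           decay = 0.5) {
  check_curve(curve)
  peaks <- peaks %||% detect_peaks(curve)
  y <- pmax(curve$intensity, 0)
  # total Bragg invariant: integrate only over detected-peak regions so
  # residual baseline error outside the peaks does not dilute the ratio
  in_peak <- rep(FALSE, length(y))
  for (i in seq_len(nrow(peaks))) {
    hw <- 3 * max(peaks$fwhm[i], 2 * median(diff(curve$q)))
    in_peak <- in_peak | abs(curve$q - peaks$q[i]) <= hw
  }
  denom <- pracma::trapz(curve$q, curve$q^2 * y * in_peak)
  if (denom <= 0 || nrow(peaks) == 0) {
    out <- 0
    attr(out, "flag") <- "isotropic"
    return(out)
  }
  a <- fd3m_lattice(peaks, window)
  if (is.na(a)) return(0)
  # the window selects the (111); its invariant is integrated over the
  # full peak region so a peak near a window edge is not truncated
  q111 <- first_reflection_q("Fd3m", as.numeric(a))
  i111 <- which.min(abs(peaks$q - q111))
  hw <- 3 * max(peaks$fwhm[i111], 2 * median(diff(curve$q)))
  inw <- abs(curve$q - q111) <= hw
  if (sum(inw) < 3) return(0)
  qw <- curve$q[inw]
  yw <- y[inw]
  pedestal <- yw[1] + (yw[length(yw)] - yw[1]) *
    (qw - qw[1]) / (qw[length(qw)] - qw[1])
  icub <- pmax(yw - pedestal, 0)
  num <- pracma::trapz(qw, qw^2 * icub)
  share <- fd3m_111_share(a, max(curve$q), decay = decay)
  min(1, max(0, (num / denom) / share))
}

#' Assemble a per-pixel phase-fraction map from a raster scan
#'
#' Runs the single-curve chain (baseline subtraction, peak detection,
#' invariant, cubic fraction, Fd3m lattice) on every pixel of a raster
#' scan and returns a tidy map. Pixels are masked as in-depot when their
#' total invariant exceeds `mask_mult` times the buffer level, estimated
#' as the median invariant of the outermost pixel ring (the scan frames
#' the depot, so the border is buffer).
#'
#' @param scan A `raster_scan` (see [generate_raster()]) or a tibble with
#'   columns `pixel_x_mm`, `pixel_y_mm` and a `curve` list column.
#' @param window Fd3m (111) window in 1/Angstrom.
#' @param mask_mult Invariant multiple over buffer level for the mask.
#' @param min_prominence Passed to [detect_peaks()].
#' @return A `phase_map` tibble with columns `pixel_x_mm`, `pixel_y_mm`,
#'   `invariant`, `fraction`, `lattice_a`, `mask`.
#' @export
assemble_map <- function(scan, window = c(0.058, 0.085), mask_mult = 5,
                         min_prominence = 0.05) {
  need <- c("pixel_x_mm", "pixel_y_mm", "curve")
  if (!all(need %in% names(scan))) {
    abort("`scan` needs columns pixel_x_mm, pixel_y_mm and curve")
  }
  if (anyDuplicated(scan[, c("pixel_x_mm", "pixel_y_mm")])) {
    abort("duplicate pixel coordinates in the raster manifest")
  }
  res <- purrr::map(scan$curve, function(cur) {
    qtot <- saxs_invariant(cur)
    sub <- subtract_baseline(cur)
    pk <- detect_peaks(sub, min_prominence = min_prominence)
    list(invariant = qtot,
         fraction = as.numeric(cubic_fraction(sub, window, peaks = pk)),
         lattice_a = as.numeric(fd3m_lattice(pk, window)))
  })
  out <- tibble::tibble(
    pixel_x_mm = scan$pixel_x_mm, pixel_y_mm = scan$pixel_y_mm,
    invariant = purrr::map_dbl(res, "invariant"),
    fraction = purrr::map_dbl(res, "fraction"),
    lattice_a = purrr::map_dbl(res, "lattice_a")
  )
  border <- out$pixel_x_mm %in% range(out$pixel_x_mm) |
    out$pixel_y_mm %in% range(out$pixel_y_mm)
  buffer_level <- median(out$invariant[border])
  out$mask <- out$invariant > mask_mult * buffer_level
  attr(out, "pixel_pitch_mm") <- attr(scan, "pixel_pitch_mm") %||%
    median(diff(sort(unique(out$pixel_x_mm))))
  attr(out, "buffer_level") <- buffer_level
  class(out) <- c("phase_map", class(out))
  out
}

#' Azimuthally averaged radial profile of a phase map
#'
#' Averages fraction and lattice parameter in concentric annuli of width
#' equal to the pixel pitch around a centre (default: centroid of the
#' masked pixels).
#'
#' @param map A `phase_map` from [assemble_map()].
#' @param center Length-2 numeric `(x, y)` in mm, or `NULL` for the mask
#'   centroid.
#' @param bin_width_mm Annulus width; defaults to the pixel pitch.
#' @return A `radial_profile` tibble with columns `r_mid_mm`,
#'   `mean_fraction`, `mean_lattice_a`, `n`.
#' @export
radial_profile <- function(map, center = NULL, bin_width_mm = NULL) {
  if (!any(map$mask)) abort("the map has no in-depot pixels")
  pitch <- attr(map, "pixel_pitch_mm") %||%
    median(diff(sort(unique(map$pixel_x_mm))))
  bin_width_mm <- bin_width_mm %||% pitch
  if (is.null(center)) {
    center <- c(mean(map$pixel_x_mm[map$mask]),
                mean(map$pixel_y_mm[map$mask]))
  }
  inside <- map$mask[
    which.min((map$pixel_x_mm - center[1])^2 +
                (map$pixel_y_mm - center[2])^2)]
  if (!isTRUE(inside)) abort("`center` lies outside the depot mask")
  d <- map[map$mask, , drop = FALSE]
  r <- sqrt((d$pixel_x_mm - center[1])^2 + (d$pixel_y_mm - center[2])^2)
  bin <- floor(r / bin_width_mm)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, fraction = d$fraction,
                                   lattice_a = d$lattice_a), .data$bin),
    mean_fraction = mean(.data$fraction),
    mean_lattice_a = if (all(is.na(.data$lattice_a))) NA_real_ else
      mean(.data$lattice_a, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::mutate(out, r_mid_mm = (.data$bin + 0.5) * bin_width_mm)
  out <- dplyr::arrange(dplyr::select(out, "r_mid_mm", "mean_fraction",
                                      "mean_lattice_a", "n"), .data$r_mid_mm)
  attr(out, "center_mm") <- center
  attr(out, "bin_width_mm") <- bin_width_mm
  class(out) <- c("radial_profile", class(out))
  out
}

#' Segment a radial profile into cubic-bearing and cubic-free layers
#'
#' Thresholds the mean cubic fraction per annulus and merges contiguous
#' runs into layers, reproducing the visual layer count of fraction maps
#' (for example cubic-free rim / cubic annulus / cubic-free core at one
#' day of hydration).
#'
#' @param profile A `radial_profile`.
#' @param fraction_threshold Fraction at or above which an annulus counts
#'   as cubic-bearing, in `(0, 1)`.
#' @return Tibble with one row per layer: `layer`, `cubic`, `r_inner_mm`,
#'   `r_outer_mm`, `n_bins`.
#' @export
segment_layers <- function(profile, fraction_threshold = 0.2) {
  if (nrow(profile) == 0) abort("empty radial profile")
  if (fraction_threshold <= 0 || fraction_threshold >= 1) {
    abort("`fraction_threshold` must lie in (0, 1)")
  }
  cubic <- profile$mean_fraction >= fraction_threshold
  runs <- rle(cubic)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  half <- (attr(profile, "bin_width_mm") %||%
             median(diff(profile$r_mid_mm))) / 2
  tibble::tibble(
    layer = seq_along(runs$values),
    cubic = runs$values,
    r_inner_mm = profile$r_mid_mm[starts] - half,
    r_outer_mm = profile$r_mid_mm[ends] + half,
    n_bins = runs$lengths
  )
}
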