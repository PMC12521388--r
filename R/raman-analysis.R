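#' Fit pseudo-Voigt bands to a Raman spectrum
#'
#' Least-squares band fitting against a list of target centres from the
#' band library. Targets are grouped into clusters of mutually
#' overlapping bands (gap below `cluster_gap`); each cluster is fitted in
#' its own window with a linear local baseline plus one pseudo-Voigt per
#' target, using Levenberg-Marquardt with box constraints (centres within
#' `center_window` of their targets, non-negative heights, width and
#' Lorentzian-fraction bounds). A cluster that fails to converge falls
#' back to window-maximum heights and is flagged.
#'
#' @param spectrum Data frame with columns `wavenumber` and `intensity`.
#' @param targets Numeric vector of target band centres (1/cm). Defaults
#'   to the mixture-relevant centres of [raman_band_library()].
#' @param center_window Allowed centre shift from target (1/cm).
#' @param cluster_gap Minimum gap (1/cm) separating fit windows.
#' @param pad Window padding beyond extreme cluster centres (1/cm).
#' @return A `band_fit` object: list with `bands` (tibble of `target`,
#'   `center`, `height`, `fwhm`, `eta`), `rss`, `converged`, `flags`.
#' @examples
#' sp <- generate_raman(1, 0)
#' fit <- fit_bands(sp, targets = c(1264, 1301))
#' tidy(fit)
#' @export
fit_bands <- function(spectrum, targets = c(715, 874, 1063, 1097, 1264,
                                            1301, 1439, 1659, 1738),
                      center_window = 8, cluster_gap = 70, pad = 45) {
  if (!all(c("wavenumber", "intensity") %in% names(spectrum))) {
    abort("a spectrum needs columns `wavenumber` and `intensity`")
  }
  if (any(diff(spectrum$wavenumber) <= 0)) {
    abort("`wavenumber` must be strictly increasing")
  }
  targets <- sort(targets)
  cluster_id <- cumsum(c(1, diff(targets) > cluster_gap))
  flags <- character()
  rows <- list()
  rss <- 0
  converged <- TRUE
  for (cid in unique(cluster_id)) {
    tg <- targets[cluster_id == cid]
    lo <- min(tg) - pad
    hi <- max(tg) + pad
    sel <- spectrum$wavenumber >= lo & spectrum$wavenumber <= hi
    x <- spectrum$wavenumber[sel]
    y <- spectrum$intensity[sel]
    if (length(x) < 5 * length(tg) + 2) {
      abort("spectrum does not cover the fit window around targets")
    }
    fit <- fit_band_cluster(x, y, tg, center_window)
    if (is.null(fit)) {
      converged <- FALSE
      flags <- c(flags, paste0("fallback_cluster_", cid))
      rows[[cid]] <- tibble::tibble(
        target = tg,
        center = tg,
        height = vapply(tg, function(t0) {
          w <- abs(x - t0) <= center_window
          max(y[w]) - min(y)
        }, numeric(1)),
        fwhm = NA_real_, eta = NA_real_
      )
    } else {
      rows[[cid]] <- fit$bands
      rss <- rss + fit$rss
    }
  }
  structure(list(bands = dplyr::arrange(dplyr::bind_rows(rows),
                                        .data$target),
                 rss = rss, converged = converged, flags = flags),
            class = "band_fit")
}

fit_band_cluster <- function(x, y, targets, center_window) {
  nb <- length(targets)
  ymin <- min(y)
  start <- c(
    vapply(targets, function(t0) {
      max(y[abs(x - t0) <= center_window]) - ymin
    }, numeric(1)),
    targets, rep(12, nb), rep(0.5, nb), ymin, 0
  )
  lower <- c(rep(0, nb), targets - center_window, rep(3, nb), rep(0, nb),
             -Inf, -Inf)
  upper <- c(rep(Inf, nb), targets + center_window, rep(45, nb), rep(1, nb),
             Inf, Inf)
  model <- function(p) {
    h <- p[seq_len(nb)]
    c0 <- p[nb + seq_len(nb)]
    f <- p[2 * nb + seq_len(nb)]
    e <- p[3 * nb + seq_len(nb)]
    out <- p[4 * nb + 1] + p[4 * nb + 2] * (x - mean(x))
    for (i in seq_len(nb)) {
      out <- out + pseudo_voigt(x, c0[i], h[i], f[i], e[i])
    }
    out
  }
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) y - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(res) || res$info %in% c(0, 9)) return(NULL)
  p <- res$par
  list(
    bands = tibble::tibble(
      target = targets,
      center = p[nb + seq_len(nb)],
      height = p[seq_len(nb)],
      fwhm = p[2 * nb + seq_len(nb)],
      eta = p[3 * nb + seq_len(nb)]
    ),
    rss = sum(res$fvec^2)
  )
}

#' Band-height intensity ratios
#'
#' The two diagnostic ratios of the depot analysis, both referenced to
#' the composition-insensitive 1301 1/cm CH2 twist: `r715 = I(715)/I(1301)`
#' (SPC amount and hydration) and `r1264 = I(1264)/I(1301)` (SPC/GDO
#' composition). Heights, not areas, are used.
#'
#' @param fit A `band_fit` containing the 1301 band and at least one of
#'   715 and 1264.
#' @return Tibble with one row: `r715`, `r1264`. A missing 715 band
#'   yields `r715 = 0` (the band is absent in pure GDO).
#' @export
intensity_ratios <- function(fit) {
  b <- if (inherits(fit, "band_fit")) fit$bands else tibble::as_tibble(fit)
  h <- function(t0) {
    i <- which(abs(b$target - t0) < 1)
    if (length(i) == 0) return(NA_real_)
    b$height[i[1]]
  }
  h1301 <- h(1301)
  if (is.na(h1301) || h1301 <= 0) {
    abort("the 1301 1/cm reference band is missing or empty")
  }
  h715 <- h(715)
  tibble::tibble(
    r715 = if (is.na(h715)) 0 else h715 / h1301,
    r1264 = h(1264) / h1301
  )
}

#' Difference between two Raman spectra
#'
#' Interpolates both spectra onto their shared wavenumber grid,
#' normalises each to its fitted 1439 1/cm CH2-scissoring band height
#' (an internal standard present in both lipids), and subtracts the
#' reference pointwise.
#'
#' @param spec,reference Data frames with `wavenumber` and `intensity`.
#' @param normalize Normalisation: `"band1439"` (default) or `"none"`.
#' @return A `raman_spectrum` tibble of the difference, with the pair's
#'   metadata in attributes.
#' @export
difference_spectrum <- function(spec, reference,
                                normalize = c("band1439", "none")) {
  normalize <- match.arg(normalize)
  lo <- max(min(spec$wavenumber), min(reference$wavenumber))
  hi <- min(max(spec$wavenumber), max(reference$wavenumber))
  if (lo >= hi) abort("the two spectra have disjoint wavenumber ranges")
  grid <- spec$wavenumber[spec$wavenumber >= lo & spec$wavenumber <= hi]
  ya <- approx(spec$wavenumber, spec$intensity, xout = grid)$y
  yb <- approx(reference$wavenumber, reference$intensity, xout = grid)$y
  if (normalize == "band1439") {
    na <- fit_bands(spec, targets = 1439)$bands$height[1]
    nb <- fit_bands(reference, targets = 1439)$bands$height[1]
    ya <- ya / na
    yb <- yb / nb
  }
  out <- tibble::tibble(wavenumber = grid, intensity = ya - yb)
  attr(out, "pair") <- list(position_mm = attr(spec, "position_mm"),
                            reference_mm = attr(reference, "position_mm"),
                            normalize = normalize)
  class(out) <- c("raman_spectrum", class(out))
  out
}

#' Estimate SPC mass fraction from the 1264/1301 ratio
#'
#' Inverts the two-endmember mixing model
#' `r = (x w_S r_S + (1 - x) w_G r_G) / (x w_S + (1 - x) w_G)` with the
#' endmember ratios `r_S = 0.95`, `r_G = 0.56` and the relative 1301-band
#' weights of the calibration; the result is clipped to `[0, 1]`.
#'
#' @param r1264 Observed 1264/1301 height ratio.
#' @param cal Calibration list, see [raman_calibration()].
#' @return SPC mass fraction of the lipid, attribute `flag = "clipped"`
#'   when the ratio falls outside the calibrated interval.
#' @examples
#' estimate_composition(0.755) # 0.5 with equal weights
#' @export
estimate_composition <- function(r1264, cal = raman_calibration()) {
  lo <- cal$r1264_gdo - 0.05
  hi <- cal$r1264_spc + 0.05
  flag <- r1264 < lo | r1264 > hi
  num <- cal$w1301_gdo * (r1264 - cal$r1264_gdo)
  den <- num + cal$w1301_spc * (cal$r1264_spc - r1264)
  x <- pmin(1, pmax(0, num / den))
  if (any(flag)) attr(x, "flag") <- "clipped"
  x
}

#' Estimate water mass fraction from the 715/1301 ratio
#'
#' Linear inversion of the 50/50-mixture hydration calibration (715/1301
#' from 0.61 at 0 % to 0.68 at 40 % water), after rescaling the observed
#' ratio to the 50/50 composition by the SPC content (the 715 1/cm band
#' scales with the amount of SPC and is absent in pure GDO). Estimates at
#' compositions away from 50/50 carry an `"extrapolated"` flag since the
#' hydration response is calibrated for the 50/50 mixture only. The
#' result is clipped to `[0, 0.40]`.
#'
#' @param r715 Observed 715/1301 height ratio.
#' @param x_spc SPC mass fraction of the lipid (> 0).
#' @param cal Calibration list, see [raman_calibration()].
#' @return Water mass fraction; `NA_real_` with flag `"undefined"` when
#'   `x_spc` is 0.
#' @examples
#' estimate_hydration(0.645, 0.5) # 0.20
#' @export
estimate_hydration <- function(r715, x_spc, cal = raman_calibration()) {
  if (any(x_spc <= 0)) {
    out <- rep(NA_real_, max(length(r715), length(x_spc)))
    attr(out, "flag") <- "undefined"
    return(out)
  }
  r50 <- r715 * 0.5 / x_spc
  slope <- (cal$r715_wet - cal$r715_dry) / cal$water_at_wet
  w <- pmin(cal$water_at_wet, pmax(0, (r50 - cal$r715_dry) / slope))
  if (any(abs(x_spc - 0.5) > 0.05)) attr(w, "flag") <- "extrapolated"
  w
}

#' @export
print.band_fit <- function(x, ...) {
  cat("<band_fit>", nrow(x$bands), "bands, rss =", signif(x$rss, 4),
      if (!x$converged) "(fallback heights used)", "\n")
  print(x$bands)
  invisible(x)
}
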