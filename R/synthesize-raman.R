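#' Raman band library for SPC, GDO and their mixtures
#'
#' Band centres and assignments of the lipid Raman modes used by the
#' generator and the fitting pipeline. Centres are given for the pure
#' lipids; the mixture centre of a shared band is the composition-weighted
#' mean. The 715 1/cm symmetric trimethylamine stretch is unique to SPC
#' (its choline headgroup) and doubles as a hydration probe; the
#' 1264 1/cm =C-H deformation tracks the higher C=C count of SPC; the
#' 1301 1/cm CH2 twist and 1439 1/cm CH2 scissoring are shared
#' backbone modes used as internal references. The residual-ethanol band
#' near 884 1/cm seen in very young depots is deliberately excluded.
#'
#' @return Tibble with columns `center_spc`, `center_gdo` (1/cm, `NA`
#'   where absent), `assignment`, `source` (`"SPC"`, `"GDO"` or
#'   `"both"`), `fwhm` (1/cm) and `eta` (Lorentzian fraction).
#' @export
raman_band_library <- function() {
  tibble::tribble(
    ~center_spc, ~center_gdo, ~assignment,                          ~source, ~fwhm, ~eta,
    715,  NA,   "nu_s(N+(CH3)3) choline",                           "SPC",  12, 0.5,
    844,  859,  "nu(C-O-C) glycerol backbone",                      "both", 14, 0.5,
    874,  NA,   "nu_as(N+(CH3)3)",                                  "SPC",  12, 0.5,
    969,  971,  "delta(CH2)",                                       "both", 14, 0.5,
    1018, 1033, "nu(C-C)",                                          "both", 14, 0.5,
    1063, 1066, "nu(C-C) trans",                                    "both", 13, 0.5,
    1097, 1085, "nu(C-C) gauche / nu_s(PO2) in SPC",                "both", 18, 0.5,
    NA,   1119, "nu(C-C) trans, nu(C-O-C)",                         "GDO",  14, 0.5,
    1264, 1264, "delta(=C-H) cis / nu_as(PO2) in SPC",              "both", 13, 0.5,
    1301, 1303, "t(CH2)",                                           "both", 14, 0.5,
    1439, 1439, "delta(CH2) scissoring",                            "both", 16, 0.5,
    1659, 1656, "nu(C=C) cis",                                      "both", 16, 0.5,
    1738, 1742, "nu(C=O) ester",                                    "both", 18, 0.5
  )
}

#' Raman ratio calibration constants
#'
#' Endmember and hydration anchors of the two band-height ratios used for
#' composition and hydration estimation: 1264/1301 is 0.95 for pure SPC
#' and 0.56 for pure GDO; for the 50/50 SPC/GDO mixture 715/1301 rises
#' linearly from 0.61 at 0 % water to 0.68 at 40 % water; the 50/50
#' mixture reaches its full-hydration limit at 16 % water. `w1301_spc`
#' and `w1301_gdo` are the relative weights of the 1301 reference band in
#' the two lipids (default 1:1) entering the mixing model of
#' [estimate_composition()].
#'
#' @return A list of calibration constants.
#' @export
raman_calibration <- function() {
  list(
    r1264_spc = 0.95, r1264_gdo = 0.56,
    r715_dry = 0.61, r715_wet = 0.68, water_at_wet = 0.40,
    hydration_limit = 0.16,
    w1301_spc = 1, w1301_gdo = 1
  )
}

#' Ground-truth band-height ratios of a generated spectrum
#'
#' The conventions the generator enforces: 1264/1301 interpolates
#' linearly in SPC fraction between the GDO (0.56) and SPC (0.95)
#' endmembers; 715/1301 equals the 50/50 hydration calibration
#' (0.61 at 0 % to 0.68 at 40 % water) scaled by SPC content relative to
#' the 50/50 mixture, and vanishes for pure GDO.
#'
#' @param spc_fraction SPC mass fraction of the lipid, in `[0, 1]`.
#' @param water_fraction Water mass fraction, in `[0, 1]`.
#' @param cal Calibration constants, see [raman_calibration()].
#' @return List with elements `r1264` and `r715`.
#' @export
raman_truth_ratios <- function(spc_fraction, water_fraction,
                               cal = raman_calibration()) {
  stopifnot(spc_fraction >= 0, spc_fraction <= 1,
            water_fraction >= 0, water_fraction <= 1)
  r1264 <- cal$r1264_gdo + (cal$r1264_spc - cal$r1264_gdo) * spc_fraction
  slope <- (cal$r715_wet - cal$r715_dry) / cal$water_at_wet
  r715 <- (spc_fraction / 0.5) * (cal$r715_dry + slope * water_fraction)
  list(r1264 = r1264, r715 = r715)
}

#' Generate a synthetic Raman spectrum
#'
#' Sum of pseudo-Voigt bands from [raman_band_library()] on a weak smooth
#' polynomial baseline (at most 5 % of the tallest band), with band
#' heights tied to composition and hydration so that the generated
#' 1264/1301 and 715/1301 height ratios equal [raman_truth_ratios()].
#' Shared-band centres interpolate linearly between the pure-lipid
#' centres with SPC fraction.
#'
#' @inheritParams raman_truth_ratios
#' @param wavenumber Spectral grid in 1/cm (must cover 650--1800).
#' @param noise_sd Gaussian noise standard deviation relative to the
#'   tallest band (0 for a noiseless spectrum).
#' @param noise_seed Integer seed for the noise.
#' @param position_mm,age_days Optional sampling metadata stored as
#'   attributes.
#' @return A `raman_spectrum` tibble with columns `wavenumber` and
#'   `intensity`; ground truth (band table and target ratios) in the
#'   `truth` attribute.
#' @examples
#' sp <- generate_raman(spc_fraction = 1, water_fraction = 0)
#' attr(sp, "truth")$ratios$r1264 # 0.95
#' @export
generate_raman <- function(spc_fraction, water_fraction,
                           wavenumber = seq(600, 1800, by = 1),
                           noise_sd = 0, noise_seed = 1L,
                           position_mm = NA_real_, age_days = NA_real_) {
  stopifnot(spc_fraction >= 0, spc_fraction <= 1,
            water_fraction >= 0, water_fraction <= 1)
  if (min(wavenumber) > 650 || max(wavenumber) < 1800) {
    abort("wavenumber grid must cover 650-1800 1/cm")
  }
  lib <- raman_band_library()
  x <- spc_fraction
  tr <- raman_truth_ratios(x, water_fraction)
  center <- ifelse(
    lib$source == "both",
    ifelse(is.na(lib$center_spc), lib$center_gdo,
           ifelse(is.na(lib$center_gdo), lib$center_spc,
                  x * lib$center_spc + (1 - x) * lib$center_gdo)),
    ifelse(lib$source == "SPC", lib$center_spc, lib$center_gdo)
  )
  # composition-weighted heights for the minor bands; the marker bands
  # (715, 1264) are pinned to the target ratios against 1301 = 1
  base_height <- c(
    `715` = tr$r715,
    `844` = 0.16 * (1 - x),
    `874` = 0.14 * x,
    `969` = 0.12,
    `1018` = 0.10 * x + 0.12 * (1 - x),
    `1063` = 0.28,
    `1097` = 0.30 + 0.08 * x,
    `1119` = 0.18 * (1 - x),
    `1264` = tr$r1264,
    `1301` = 1,
    `1439` = 0.90,
    `1659` = 0.40 + 0.08 * x,
    `1738` = 0.30
  )
  key <- as.character(round(ifelse(is.na(lib$center_spc), lib$center_gdo,
                                   lib$center_spc)))
  height <- unname(base_height[key])
  keep <- height > 0 & !is.na(center)
  bands <- tibble::tibble(center = center[keep], height = height[keep],
                          fwhm = lib$fwhm[keep], eta = lib$eta[keep],
                          assignment = lib$assignment[keep],
                          source = lib$source[keep])
  hmax <- max(bands$height)
  nu0 <- (wavenumber - 600) / 1200
  baseline <- hmax * (0.02 + 0.03 * nu0 * (1 - 0.5 * nu0))
  intensity <- baseline
  for (i in seq_len(nrow(bands))) {
    intensity <- intensity + pseudo_voigt(wavenumber, bands$center[i],
                                          bands$height[i], bands$fwhm[i],
                                          bands$eta[i])
  }
  if (noise_sd > 0) {
    intensity <- intensity + withr::with_seed(
      as.integer(noise_seed),
      stats::rnorm(length(intensity), sd = noise_sd * hmax)
    )
  }
  out <- tibble::tibble(wavenumber = wavenumber, intensity = intensity)
  attr(out, "position_mm") <- position_mm
  attr(out, "age_days") <- age_days
  attr(out, "truth") <- list(bands = bands, ratios = tr,
                             spc_fraction = x,
                             water_fraction = water_fraction)
  class(out) <- c("raman_spectrum", class(out))
  out
}
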