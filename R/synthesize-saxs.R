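#' Default momentum-transfer grid
#'
#' Uniform q-grid spanning the instrument range 0.016--0.85 1/Angstrom.
#' The default step of 5e-4 resolves the default Bragg-peak width
#' (0.0025 1/Angstrom FWHM) with five points per FWHM.
#'
#' @param step Grid spacing in 1/Angstrom.
#' @return Numeric vector of q values.
#' @export
default_q_grid <- function(step = 5e-4) {
  seq(0.016, 0.85, by = step)
}

new_saxs_curve <- function(df, pixel_x = NA_real_, pixel_y = NA_real_,
                           truth = NULL, flags = character()) {
  out <- tibble::as_tibble(df)
  attr(out, "pixel_x_mm") <- pixel_x
  attr(out, "pixel_y_mm") <- pixel_y
  attr(out, "truth") <- truth
  attr(out, "flags") <- flags
  class(out) <- c("saxs_curve", class(out))
  out
}

check_curve <- function(curve) {
  if (!all(c("q", "intensity") %in% names(curve))) {
    abort("a scattering curve needs columns `q` and `intensity`")
  }
  if (any(diff(curve$q) <= 0)) abort("`q` must be strictly increasing")
  if (any(!is.finite(curve$intensity))) abort("intensities must be finite")
  invisible(curve)
}

#' Analytic Bragg-peak table for a phase mixture
#'
#' Expands a mixture specification into the per-reflection peak list the
#' forward model sums over. Relative intensities within a phase follow a
#' geometric decay (factor `decay` per successive allowed reflection),
#' which keeps the first reflection dominant as observed in depot
#' patterns; reflections falling outside `q_range` are dropped.
#'
#' @param phases Tibble/data frame with columns `phase`, `lattice_a`
#'   (Angstrom) and `weight` (height of the first reflection).
#' @param q_range Length-2 numeric, the covered q interval.
#' @param fwhm Peak full width at half maximum (1/Angstrom).
#' @param eta Lorentzian fraction of the pseudo-Voigt.
#' @param decay Height ratio between successive reflections.
#' @return Tibble with columns `phase`, `hkl`, `q`, `height`, `fwhm`, `eta`.
#' @export
peak_table <- function(phases, q_range = c(0.016, 0.85), fwhm = 0.0025,
                       eta = 0.5, decay = 0.5) {
  lib <- phase_library()
  rows <- purrr::pmap(
    list(phases$phase, phases$lattice_a, phases$weight),
    function(ph, a, w) {
      i <- match(ph, lib$phase)
      if (is.na(i)) {
        if (identical(ph, "isotropic")) return(NULL)
        abort(paste0("unknown phase '", ph, "'"))
      }
      if (a <= 0) abort("lattice parameters must be positive")
      if (w < 0) abort("phase weights must be non-negative")
      q1 <- lib$lattice_k[i] / a
      qs <- q1 * lib$ratios[[i]]
      tibble::tibble(
        phase = ph, hkl = lib$labels[[i]], q = qs,
        height = w * decay^(seq_along(qs) - 1), fwhm = fwhm, eta = eta
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(phase = character(), hkl = character(),
                          q = double(), height = double(),
                          fwhm = double(), eta = double()))
  }
  dplyr::filter(out, .data$q >= q_range[1], .data$q <= q_range[2],
                .data$height > 0)
}

#' Generate a synthetic 1D scattering curve
#'
#' Forward model for a background-bearing powder pattern: a smooth
#' power-law-plus-constant background `b * q^-p + c` plus one pseudo-Voigt
#' peak per allowed reflection of each phase in the mixture, with optional
#' Poisson counting noise. The full analytic ground truth (peak table and
#' background parameters) is retained in the `truth` attribute.
#'
#' @param phases Tibble with columns `phase`, `lattice_a`, `weight`; may
#'   have zero rows for a background-only (buffer) pixel.
#' @param q_grid Strictly increasing q values within `[0.016, 0.85]`
#'   1/Angstrom; must resolve the narrowest peak with at least five points
#'   per FWHM.
#' @param background List with elements `b`, `p`, `c` of the background
#'   model `b * q^-p + c`.
#' @param fwhm,eta,decay Peak-shape conventions, see [peak_table()].
#' @param noise_seed Integer seed for Poisson noise, or `NULL` for a
#'   noiseless curve.
#' @param counts_scale Counts per intensity unit used when Poisson noise
#'   is requested.
#' @param pixel_x,pixel_y Optional raster coordinates (mm) stored as
#'   attributes.
#' @return A `saxs_curve` tibble with columns `q` and `intensity`.
#' @examples
#' cur <- generate_curve(
#'   tibble::tibble(phase = "Fd3m", lattice_a = 172, weight = 1)
#' )
#' cur$q[which.max(cur$intensity)] # close to 0.0633 1/A
#' @export
generate_curve <- function(phases = tibble::tibble(phase = character(),
                                                   lattice_a = double(),
                                                   weight = double()),
                           q_grid = default_q_grid(),
                           background = list(b = 1e-4, p = 2, c = 0.01),
                           fwhm = 0.0025, eta = 0.5, decay = 0.5,
                           noise_seed = NULL, counts_scale = 5e4,
                           pixel_x = NA_real_, pixel_y = NA_real_) {
  if (any(diff(q_grid) <= 0)) abort("`q_grid` must be strictly increasing")
  if (min(q_grid) < 0.016 - 1e-12 || max(q_grid) > 0.85 + 1e-12) {
    abort("`q_grid` must lie within [0.016, 0.85] 1/Angstrom")
  }
  bg <- background$b * q_grid^(-background$p) + background$c
  pt <- peak_table(phases, range(q_grid), fwhm = fwhm, eta = eta,
                   decay = decay)
  no_signal <- nrow(pt) == 0 || all(pt$height == 0)
  if (no_signal && background$b == 0 && background$c == 0) {
    abort("empty phase list with zero background: nothing to generate")
  }
  if (nrow(pt) > 0) {
    step <- max(diff(q_grid))
    if (min(pt$fwhm) / step < 5 * (1 - 1e-9)) {
      abort("`q_grid` too coarse: fewer than 5 points per peak FWHM")
    }
  }
  intensity <- bg
  for (i in seq_len(nrow(pt))) {
    intensity <- intensity +
      pseudo_voigt(q_grid, pt$q[i], pt$height[i], pt$fwhm[i], pt$eta[i])
  }
  if (!is.null(noise_seed)) {
    intensity <- withr::with_seed(
      as.integer(noise_seed),
      stats::rpois(length(intensity), intensity * counts_scale) / counts_scale
    )
  }
  new_saxs_curve(
    tibble::tibble(q = q_grid, intensity = intensity),
    pixel_x = pixel_x, pixel_y = pixel_y,
    truth = list(peaks = pt, background = background,
                 phases = tibble::as_tibble(phases))
  )
}

#' Depot hydration scenario
#'
#' Ground-truth description of a radially layered depot at a given
#' hydration age: an ordered list of concentric layers (phase, outer
#' radius, lattice parameter at the layer's inner and outer edge, Bragg
#' weight) plus smooth radial composition and hydration profiles. Layer
#' boundaries are sharp; within-layer lattice gradients are linear in
#' radius.
#'
#' @param hydration_age_days Depot age in days.
#' @param depot_radius_mm Depot radius in mm.
#' @param layers Tibble with columns `phase`, `r_outer_mm`,
#'   `lattice_inner_a`, `lattice_outer_a`, `weight`, ordered from the
#'   centre outwards; outer radii strictly increasing, the last equal to
#'   `depot_radius_mm`.
#' @param spc_profile Function of radius (mm) returning the SPC mass
#'   fraction of the lipid (SPC + GDO sums to one).
#' @param water_profile Function of radius (mm) returning the water mass
#'   fraction.
#' @param noise_seed Integer seed used when rasters generated from the
#'   scenario carry noise.
#' @return A `depot_scenario` object.
#' @export
depot_scenario <- function(hydration_age_days, depot_radius_mm, layers,
                           spc_profile = function(r) rep(0.5, length(r)),
                           water_profile = function(r) rep(0.1, length(r)),
                           noise_seed = 1L) {
  layers <- tibble::as_tibble(layers)
  need <- c("phase", "r_outer_mm", "lattice_inner_a", "lattice_outer_a",
            "weight")
  if (!all(need %in% names(layers))) {
    abort(paste("scenario layers need columns:", paste(need, collapse = ", ")))
  }
  if (any(diff(layers$r_outer_mm) <= 0)) {
    abort("layer outer radii must be strictly increasing")
  }
  if (abs(tail(layers$r_outer_mm, 1) - depot_radius_mm) > 1e-9) {
    abort("the outermost layer must end at the depot radius")
  }
  rr <- seq(0, depot_radius_mm, length.out = 64)
  if (any(spc_profile(rr) < 0 | spc_profile(rr) > 1) ||
      any(water_profile(rr) < 0 | water_profile(rr) > 1)) {
    abort("composition and hydration profiles must lie in [0, 1]")
  }
  structure(
    list(hydration_age_days = hydration_age_days,
         depot_radius_mm = depot_radius_mm, layers = layers,
         spc_profile = spc_profile, water_profile = water_profile,
         noise_seed = as.integer(noise_seed)),
    class = "depot_scenario"
  )
}

#' @export
print.depot_scenario <- function(x, ...) {
  cat("<depot_scenario> age", x$hydration_age_days, "days, radius",
      x$depot_radius_mm, "mm\n")
  print(x$layers)
  invisible(x)
}

#' Preset scenarios
#'
#' Canned hydration states matching the depot phenomenology at key ages:
#'
#' * `scenario_one_day()`: three layers -- isotropic micellar core (no
#'   Bragg peaks), an Fd3m annulus in the early-hydration lattice range,
#'   and a reverse hexagonal rim.
#' * `scenario_four_week()`: two layers -- an Fd3m core with lattice
#'   parameter rising 157 to 172 Angstrom from centre to edge (smaller
#'   micelles in the centre) and an H2 rim.
#' * `scenario_one_week(spc_fraction)`: cubic phase throughout the
#'   interior with an H2 rim whose thickness grows with the SPC content
#'   of the starting mixture; at 56:44 SPC/GDO a Pm3n core region is
#'   included.
#'
#' @param noise_seed Integer seed stored with the scenario.
#' @param spc_fraction Starting SPC mass fraction of the lipid mixture.
#' @return A `depot_scenario`.
#' @export
scenario_one_day <- function(noise_seed = 1L) {
  depot_scenario(
    hydration_age_days = 1, depot_radius_mm = 4,
    layers = tibble::tibble(
      phase = c("isotropic", "Fd3m", "H2"),
      r_outer_mm = c(2.2, 3.2, 4),
      lattice_inner_a = c(NA, 131, 55),
      lattice_outer_a = c(NA, 145, 55),
      weight = c(0, 1, 1)
    ),
    spc_profile = function(r) 0.5 - 0.06 * exp(-((r - 2.7) / 0.6)^2) +
      0.1 * exp(-((r - 4) / 0.5)^2),
    water_profile = function(r) 0.16 * pmin(1, pmax(0, (r - 2) / 2)),
    noise_seed = noise_seed
  )
}

#' @rdname scenario_one_day
#' @export
scenario_four_week <- function(noise_seed = 1L) {
  depot_scenario(
    hydration_age_days = 28, depot_radius_mm = 4,
    layers = tibble::tibble(
      phase = c("Fd3m", "H2"),
      r_outer_mm = c(3.2, 4),
      lattice_inner_a = c(157, 60),
      lattice_outer_a = c(172, 60),
      weight = c(1, 1)
    ),
    spc_profile = function(r) 0.44 + 0.14 * pmin(1, pmax(0, (r - 2.5) / 1.5)),
    water_profile = function(r) 0.12 + 0.08 * r / 4,
    noise_seed = noise_seed
  )
}

#' @rdname scenario_one_day
#' @export
scenario_one_week <- function(spc_fraction = 0.5, noise_seed = 1L) {
  stopifnot(spc_fraction >= 0.4, spc_fraction <= 0.7)
  rim_start <- 3.0 - 10 * (spc_fraction - 0.5)
  layers <- tibble::tibble(
    phase = c("Fd3m", "H2"),
    r_outer_mm = c(rim_start, 4),
    lattice_inner_a = c(140, 58),
    lattice_outer_a = c(155, 58),
    weight = c(1, 1)
  )
  if (spc_fraction > 0.53) {
    layers <- dplyr::bind_rows(
      tibble::tibble(phase = "Pm3n", r_outer_mm = 1.0,
                     lattice_inner_a = 105, lattice_outer_a = 105,
                     weight = 1),
      layers
    )
  }
  depot_scenario(
    hydration_age_days = 7, depot_radius_mm = 4, layers = layers,
    spc_profile = function(r) pmin(1, spc_fraction +
                                     0.1 * exp(-((r - 4) / 0.6)^2)),
    water_profile = function(r) 0.10 + 0.06 * r / 4,
    noise_seed = noise_seed
  )
}

#' Generate a raster scan of a depot scenario
#'
#' Lays a square pixel grid (pitch `pixel_pitch_mm`) over the depot with a
#' small buffer margin and generates one scattering curve per pixel. A
#' pixel at radius r receives the phase, weight and (radially
#' interpolated) lattice parameter of the layer containing r; pixels
#' outside the depot receive the weak buffer background only. Ground
#' truth per pixel (layer phase, lattice parameter, in-depot flag) is
#' returned alongside the curves.
#'
#' @param scenario A [depot_scenario()].
#' @param pixel_pitch_mm Raster pitch in mm (the beamline used 0.05 mm).
#' @param q_grid q-grid passed to [generate_curve()].
#' @param margin_mm Buffer margin added around the depot.
#' @param noise Logical; add Poisson noise using per-pixel seeds derived
#'   from the scenario seed.
#' @param depot_background,buffer_background Background models inside and
#'   outside the depot. The buffer scatters far less, so the total
#'   invariant separates depot from buffer pixels.
#' @return A `raster_scan` tibble with columns `pixel_x_mm`, `pixel_y_mm`,
#'   `in_depot`, `truth_phase`, `truth_lattice_a`, `curve` (list column of
#'   `saxs_curve`).
#' @export
generate_raster <- function(scenario, pixel_pitch_mm = 0.2,
                            q_grid = default_q_grid(), margin_mm = NULL,
                            noise = FALSE,
                            depot_background = list(b = 1e-4, p = 2, c = 0.01),
                            buffer_background = list(b = 0, p = 2, c = 2e-4)) {
  stopifnot(inherits(scenario, "depot_scenario"))
  if (pixel_pitch_mm <= 0) abort("`pixel_pitch_mm` must be positive")
  if (pixel_pitch_mm > scenario$depot_radius_mm) {
    abort("pixel pitch larger than the depot radius")
  }
  margin_mm <- margin_mm %||% (2 * pixel_pitch_mm)
  half <- scenario$depot_radius_mm + margin_mm
  ax <- seq(-half, half, by = pixel_pitch_mm)
  grid <- tidyr::expand_grid(pixel_x_mm = ax, pixel_y_mm = ax)
  lay <- scenario$layers
  r <- sqrt(grid$pixel_x_mm^2 + grid$pixel_y_mm^2)
  in_depot <- r <= scenario$depot_radius_mm + 1e-12
  idx <- pmin(findInterval(r, lay$r_outer_mm, left.open = TRUE) + 1L,
              nrow(lay))
  idx[!in_depot] <- NA_integer_
  r_inner <- c(0, head(lay$r_outer_mm, -1))
  frac <- (r - r_inner[idx]) / (lay$r_outer_mm[idx] - r_inner[idx])
  lattice <- lay$lattice_inner_a[idx] +
    frac * (lay$lattice_outer_a[idx] - lay$lattice_inner_a[idx])
  phase <- lay$phase[idx]
  weight <- lay$weight[idx]
  curves <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (isTRUE(in_depot[i]) && weight[i] > 0 &&
        !identical(phase[i], "isotropic")) {
      ph <- tibble::tibble(phase = phase[i], lattice_a = lattice[i],
                           weight = weight[i])
      bg <- depot_background
    } else if (isTRUE(in_depot[i])) {
      ph <- tibble::tibble(phase = character(), lattice_a = double(),
                           weight = double())
      bg <- depot_background
    } else {
      ph <- tibble::tibble(phase = character(), lattice_a = double(),
                           weight = double())
      bg <- buffer_background
    }
    curves[[i]] <- generate_curve(
      ph, q_grid = q_grid, background = bg,
      noise_seed = if (noise) scenario$noise_seed + i else NULL,
      pixel_x = grid$pixel_x_mm[i], pixel_y = grid$pixel_y_mm[i]
    )
  }
  out <- tibble::tibble(
    pixel_x_mm = grid$pixel_x_mm, pixel_y_mm = grid$pixel_y_mm,
    in_depot = in_depot,
    truth_phase = ifelse(in_depot, phase, "buffer"),
    truth_lattice_a = ifelse(in_depot, lattice, NA_real_),
    curve = curves
  )
  attr(out, "pixel_pitch_mm") <- pixel_pitch_mm
  attr(out, "scenario") <- scenario
  class(out) <- c("raster_scan", class(out))
  out
}
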