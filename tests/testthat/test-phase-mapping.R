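test_that("the invariant matches closed forms and scales with intensity", {
  # I = 2 on [0, 0.3]: Q = 2 * 0.3^3 / 3
  cur <- tibble::tibble(q = seq(0, 0.3, by = 1e-4), intensity = 2)
  expect_equal(saxs_invariant(cur), 0.018, tolerance = 1e-6)
  cur$intensity <- 0
  expect_equal(saxs_invariant(cur), 0)
  expect_error(saxs_invariant(cur[1, ]), "two points")
  # doubling intensity doubles Q exactly
  gen <- fd3m_curve(160)
  q1 <- saxs_invariant(gen)
  gen2 <- gen
  gen2$intensity <- 2 * gen2$intensity
  expect_identical(saxs_invariant(gen2), 2 * q1)
  # generated curve invariant vs analytic background + peak integrals
  truth <- attr(gen, "truth")
  bg <- truth$background
  qq <- gen$q
  bg_q2 <- pracma::trapz(qq, qq^2 * (bg$b * qq^(-bg$p) + bg$c))
  pk_q2 <- sum(purrr::pmap_dbl(
    truth$peaks[, c("q", "height", "fwhm", "eta")],
    function(q, height, fwhm, eta) {
      pv_q2_integral(min(qq), max(qq), q, height, fwhm, eta)
    }))
  expect_equal(q1, bg_q2 + pk_q2, tolerance = 0.005)
})

test_that("cubic fraction hits the single-phase, mixture and empty limits", {
  # pure Fd3m: fraction 1 by the normalisation convention
  sub <- subtract_baseline(fd3m_curve(160))
  expect_equal(as.numeric(cubic_fraction(sub)), 1, tolerance = 0.05)
  # invariance under global intensity scaling
  sub2 <- sub
  sub2$intensity <- 3.7 * sub2$intensity
  expect_equal(as.numeric(cubic_fraction(sub2)),
               as.numeric(cubic_fraction(sub)), tolerance = 1e-6)
  # peak-free curve: 0 with isotropic flag
  f <- cubic_fraction(subtract_baseline(generate_curve()))
  expect_equal(as.numeric(f), 0)
  # mixture built so the Fd3m phase carries 30% of the Bragg invariant
  lib <- phase_library()
  winv <- function(ratios, q1, decay = 0.5) {
    qk <- q1 * ratios
    keep <- qk <= 0.85
    sum(qk[keep]^2 * decay^(which(keep) - 1))
  }
  qf <- first_reflection_q("Fd3m", 160)
  wh <- (0.70 / 0.30) * winv(lib$ratios[[1]], qf) /
    winv(lib$ratios[[3]], 0.110)
  cur <- generate_curve(tibble::tibble(
    phase = c("Fd3m", "H2"),
    lattice_a = c(160, lattice_from_q("H2", 0.110)),
    weight = c(1, wh)))
  expect_equal(as.numeric(cubic_fraction(subtract_baseline(cur))), 0.30,
               tolerance = 0.02)
})

test_that("cubic fraction is monotone in the generator's Fd3m weight", {
  prev <- -1
  for (w in c(0.2, 0.5, 1, 2)) {
    cur <- generate_curve(tibble::tibble(phase = c("Fd3m", "H2"),
                                         lattice_a = c(160, 60),
                                         weight = c(w, 1)))
    f <- as.numeric(cubic_fraction(subtract_baseline(cur)))
    expect_gt(f, prev)
    prev <- f
  }
})

test_that("maps, profiles and layers recover the scenario structure", {
  scan <- generate_raster(scenario_one_day(), pixel_pitch_mm = 0.4)
  map <- assemble_map(scan)
  # mask identifies exactly the in-depot pixels
  expect_identical(map$mask, scan$in_depot)
  expect_true(all(map$fraction >= 0 & map$fraction <= 1))
  # determinism: identical scan gives identical map
  map2 <- assemble_map(scan)
  expect_identical(tibble::as_tibble(map), tibble::as_tibble(map2))
  prof <- radial_profile(map)
  layers <- segment_layers(prof)
  # 1-day depot: cubic-free core, cubic annulus, cubic-free rim
  expect_identical(layers$cubic, c(FALSE, TRUE, FALSE))
  expect_equal(layers$r_outer_mm[1], 2.2, tolerance = 0.15)
  expect_equal(layers$r_outer_mm[2], 3.2, tolerance = 0.15)
  # duplicate pixels rejected
  bad <- dplyr::bind_rows(scan[1, ], scan[1, ])
  expect_error(assemble_map(bad), "duplicate")
  # degenerate profile guards
  expect_error(segment_layers(prof, fraction_threshold = 0), "threshold")
  expect_error(radial_profile(map, center = c(20, 20)), "outside")
})

test_that("the 4-week depot shows a cubic core and a centre-to-edge lattice rise", {
  scan <- generate_raster(scenario_four_week(), pixel_pitch_mm = 0.4)
  map <- assemble_map(scan)
  prof <- radial_profile(map)
  layers <- segment_layers(prof)
  expect_identical(layers$cubic, c(TRUE, FALSE))
  # central region dominated by cubic phase
  expect_gt(mean(prof$mean_fraction[prof$r_mid_mm < 2]), 0.8)
  # recovered lattice increases from centre to edge of the cubic core
  lat <- prof$mean_lattice_a[prof$r_mid_mm < 3]
  expect_true(all(diff(lat[!is.na(lat)]) > -0.5))
  expect_gt(tail(lat[!is.na(lat)], 1) - lat[!is.na(lat)][1], 8)
  # radial ground truth recovered within bin discretisation
  truth_at <- function(r) 157 + (172 - 157) * r / 3.2
  mid <- prof$r_mid_mm < 2.8
  expect_equal(prof$mean_lattice_a[mid], truth_at(prof$r_mid_mm[mid]),
               tolerance = 0.02)
})

test_that("higher-SPC depots grow a thicker cubic-free rim", {
  th <- function(spc) {
    scan <- generate_raster(scenario_one_week(spc), pixel_pitch_mm = 0.4)
    layers <- segment_layers(radial_profile(assemble_map(scan)))
    rim <- layers[nrow(layers), ]
    expect_false(rim$cubic)
    rim$r_outer_mm - rim$r_inner_mm
  }
  expect_gt(th(0.56), th(0.50))
})

test_that("an all-buffer raster yields an empty mask", {
  sc <- depot_scenario(
    hydration_age_days = 1, depot_radius_mm = 0.2,
    layers = tibble::tibble(phase = "isotropic", r_outer_mm = 0.2,
                            lattice_inner_a = NA, lattice_outer_a = NA,
                            weight = 0))
  scan <- generate_raster(sc, pixel_pitch_mm = 0.2, margin_mm = 0.6,
                          depot_background = list(b = 0, p = 2, c = 2e-4))
  map <- assemble_map(scan)
  expect_false(any(map$mask))
})
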