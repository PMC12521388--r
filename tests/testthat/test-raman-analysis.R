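test_that("band fitting recovers centres and heights of synthetic spectra", {
  sp <- generate_raman(1, 0)
  fit <- fit_bands(sp)
  expect_true(fit$converged)
  bands <- tidy(fit)
  for (c0 in c(715, 1264, 1301, 1439, 1659)) {
    i <- which.min(abs(bands$target - c0))
    expect_lt(abs(bands$center[i] - c0), 1)
  }
  # isolated single band: height recovered within 0.5%
  nu <- seq(600, 1800, by = 1)
  one <- tibble::tibble(wavenumber = nu,
                        intensity = pseudo_voigt(nu, 1439, 2.5, 14))
  fit <- fit_bands(one, targets = 1439)
  expect_equal(fit$bands$height, 2.5, tolerance = 0.005)
  # overlapping 1264/1301 pair: both heights within 1%
  two <- tibble::tibble(wavenumber = nu,
                        intensity = pseudo_voigt(nu, 1264, 0.8, 13) +
                          pseudo_voigt(nu, 1301, 1.0, 14))
  fit <- fit_bands(two, targets = c(1264, 1301))
  expect_equal(fit$bands$height, c(0.8, 1.0), tolerance = 0.01)
  expect_equal(glance(fit)$n_bands, 2L)
})

test_that("intensity ratios hit the printed calibration anchors", {
  r_spc <- intensity_ratios(fit_bands(generate_raman(1, 0)))
  expect_equal(r_spc$r1264, 0.95, tolerance = 0.011)
  r_gdo <- intensity_ratios(fit_bands(generate_raman(0, 0)))
  expect_equal(r_gdo$r1264, 0.56, tolerance = 0.011)
  expect_lt(r_gdo$r715, 0.02)
  r_wet <- intensity_ratios(fit_bands(generate_raman(0.5, 0.40)))
  expect_equal(r_wet$r715, 0.68, tolerance = 0.011)
  # ratios invariant under global intensity scaling
  sp <- generate_raman(0.5, 0.2)
  sp2 <- sp
  sp2$intensity <- 5 * sp2$intensity
  expect_equal(intensity_ratios(fit_bands(sp2)),
               intensity_ratios(fit_bands(sp)), tolerance = 1e-4)
  # equal 715/1301 heights give ratio one
  nu <- seq(600, 1800, by = 1)
  eq <- tibble::tibble(wavenumber = nu,
                       intensity = pseudo_voigt(nu, 715, 1, 12) +
                         pseudo_voigt(nu, 1301, 1, 14) +
                         pseudo_voigt(nu, 1264, 0.5, 13))
  expect_equal(intensity_ratios(fit_bands(eq,
    targets = c(715, 1264, 1301)))$r715, 1, tolerance = 0.01)
})

test_that("ratios move monotonically with composition and hydration", {
  r64 <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(x) {
    intensity_ratios(fit_bands(generate_raman(x, 0.1)))$r1264
  }, numeric(1))
  expect_true(all(diff(r64) > 0))
  r15 <- vapply(c(0, 0.1, 0.25, 0.4), function(w) {
    intensity_ratios(fit_bands(generate_raman(0.5, w)))$r715
  }, numeric(1))
  expect_true(all(diff(r15) > 0))
})

test_that("difference spectra are antisymmetric and show the expected features", {
  a <- generate_raman(0.6, 0.15, position_mm = 4)
  b <- generate_raman(0.5, 0.05, position_mm = 0)
  d1 <- difference_spectrum(a, b)
  d2 <- difference_spectrum(b, a)
  expect_equal(d1$intensity, -d2$intensity, tolerance = 1e-9)
  expect_equal(nrow(difference_spectrum(a, a)), nrow(a))
  expect_lt(max(abs(difference_spectrum(a, a)$intensity)), 1e-9)
  # SPC-rich minus reference: positive phosphate/olefin region near 1265
  at <- function(d, nu) d$intensity[which.min(abs(d$wavenumber - nu))]
  expect_gt(at(d1, 1265), 0)
  # pure SPC minus pure GDO: positive choline 715 feature
  d <- difference_spectrum(generate_raman(1, 0), generate_raman(0, 0))
  expect_gt(at(d, 715), 0.1)
  disjoint <- tibble::tibble(wavenumber = 1:10 + 3000, intensity = 1)
  expect_error(difference_spectrum(a, disjoint), "disjoint")
})

test_that("composition estimation inverts the mixing model", {
  expect_equal(as.numeric(estimate_composition(0.95)), 1)
  expect_equal(as.numeric(estimate_composition(0.56)), 0)
  expect_equal(as.numeric(estimate_composition(0.755)), 0.5)
  # out-of-range ratios clip with a flag
  x <- estimate_composition(1.05)
  expect_equal(as.numeric(x), 1)
  expect_identical(attr(x, "flag"), "clipped")
  # unequal 1301 weights shift the midpoint
  cal <- raman_calibration()
  cal$w1301_spc <- 2
  expect_lt(as.numeric(estimate_composition(0.755, cal)), 0.5)
})

test_that("composition recovery across mixtures with noise stays accurate", {
  xs <- c(0, 0.25, 0.5, 0.75, 1)
  err <- vapply(seq_along(xs), function(i) {
    sp <- generate_raman(xs[i], 0.1, noise_sd = 0.01, noise_seed = 100 + i)
    r <- intensity_ratios(fit_bands(sp))$r1264
    abs(as.numeric(estimate_composition(r)) - xs[i])
  }, numeric(1))
  expect_lt(mean(err), 0.03)
})

test_that("hydration estimation inverts the 50/50 calibration", {
  expect_equal(as.numeric(estimate_hydration(0.61, 0.5)), 0)
  expect_equal(as.numeric(estimate_hydration(0.68, 0.5)), 0.40)
  expect_equal(as.numeric(estimate_hydration(0.645, 0.5)), 0.20)
  # SPC-content scaling: the same water reads the same after rescaling
  tr <- raman_truth_ratios(0.8, 0.25)
  w <- estimate_hydration(tr$r715, 0.8)
  expect_equal(as.numeric(w), 0.25, tolerance = 1e-9)
  expect_identical(attr(w, "flag"), "extrapolated")
  und <- estimate_hydration(0.5, 0)
  expect_true(is.na(und))
  expect_identical(attr(und, "flag"), "undefined")
})
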