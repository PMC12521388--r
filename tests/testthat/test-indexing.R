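test_that("reflection ladders carry the exact cubic and hexagonal ratios", {
  lib <- phase_library()
  fd3m <- lib$ratios[[match("Fd3m", lib$phase)]]
  # q220 / q111 = sqrt(8/3)
  expect_identical(fd3m[2] / fd3m[1], sqrt(8 / 3))
  expect_identical(fd3m[1], 1)
  h2 <- lib$ratios[[match("H2", lib$phase)]]
  expect_identical(h2, c(1, sqrt(3), 2, sqrt(7)))
  expect_identical(lib$ratios[[match("Pm3n", lib$phase)]][1:3],
                   sqrt(c(2, 4, 5) / 2))
  # lattice rules invert the first reflection
  expect_equal(lattice_from_q("Fd3m", first_reflection_q("Fd3m", 172)), 172)
  expect_equal(lattice_from_q("H2", 0.110), 4 * pi / (sqrt(3) * 0.110))
})

test_that("known peak lists index to the right phase and lattice", {
  # Fd3m ladder at a = 172 A
  pk <- tibble::tibble(q = 2 * pi * sqrt(3) / 172 * sqrt(c(3, 8, 11, 12) / 3),
                       height = c(1, .5, .25, .125), fwhm = 0.0025,
                       prominence = c(1, .5, .25, .125))
  res <- index_phases(pk)
  expect_equal(res$assignments$phase[1], "Fd3m")
  expect_equal(res$assignments$lattice_a[1], 172, tolerance = 1e-6)
  expect_equal(res$assignments$n_matched[1], 4L)
  # H2 ladder anchored at 0.110
  pk <- tibble::tibble(q = c(0.110, 0.1905, 0.220), height = c(1, .5, .25),
                       fwhm = 0.0025, prominence = c(1, .5, .25))
  res <- index_phases(pk)
  expect_equal(res$assignments$phase[1], "H2")
  expect_equal(res$assignments$lattice_a[1], 65.96, tolerance = 1e-3)
  # empty list: isotropic fallback with a low-confidence flag
  res <- index_phases(detect_peaks(tibble::tibble(q = default_q_grid(),
                                                  intensity = 0)))
  expect_equal(res$assignments$phase, "isotropic")
  expect_true("low_confidence_isotropic" %in% res$flags)
  expect_error(index_phases(pk, rel_tol = 0.2), "rel_tol")
})

test_that("two-phase curves resolve into both constituents", {
  cur <- generate_curve(tibble::tibble(phase = c("Fd3m", "H2"),
                                       lattice_a = c(165, 60),
                                       weight = c(1, 0.7)))
  res <- index_phases(detect_peaks(subtract_baseline(cur)))
  expect_setequal(res$assignments$phase, c("Fd3m", "H2"))
  a <- res$assignments
  expect_equal(a$lattice_a[a$phase == "Fd3m"], 165, tolerance = 0.005)
  expect_equal(a$lattice_a[a$phase == "H2"], 60, tolerance = 0.005)
})

test_that("lattice recovery round-trips within 0.5% across the swelling range", {
  for (a in seq(120, 180, by = 12)) {
    pk <- detect_peaks(subtract_baseline(fd3m_curve(a)))
    res <- index_phases(pk)
    got <- res$assignments$lattice_a[res$assignments$phase == "Fd3m"]
    expect_equal(got, a, tolerance = 0.005)
  }
  for (a in seq(50, 70, by = 5)) {
    cur <- generate_curve(tibble::tibble(phase = "H2", lattice_a = a,
                                         weight = 1))
    res <- index_phases(detect_peaks(subtract_baseline(cur)))
    got <- res$assignments$lattice_a[res$assignments$phase == "H2"]
    expect_equal(got, a, tolerance = 0.005)
  }
})

test_that("greedy indexing agrees with exhaustive hypothesis enumeration", {
  withr::with_seed(7, {
    lib <- phase_library()
    for (rep in 1:25) {
      i <- sample(nrow(lib), 1)
      a <- stats::runif(1, 60, 180)
      q1 <- lib$lattice_k[i] / a
      ratios <- lib$ratios[[i]]
      n <- sample(2:min(6, length(ratios)), 1)
      qs <- sort(q1 * ratios[sort(sample(seq_along(ratios), n))])
      qs <- qs[qs <= 0.85]
      if (length(qs) < 2) next
      qs <- qs * (1 + stats::runif(length(qs), -0.002, 0.002))
      pk <- tibble::tibble(q = qs, height = seq(1, 0.3, length.out = length(qs)),
                           fwhm = 0.0025, prominence = 1)
      got <- index_phases(pk)$assignments[1, ]
      want <- brute_force_best_hypothesis(qs)
      if (is.null(want)) {
        expect_equal(got$phase, "isotropic")
      } else {
        expect_equal(got$n_matched, want$n)
        expect_equal(got$residual, want$resid, tolerance = 1e-9)
      }
    }
  })
})

test_that("fd3m_lattice picks the strongest in-window peak", {
  pk <- tibble::tibble(q = c(0.0633, 0.1034), height = c(1, 0.5),
                       fwhm = 0.0025, prominence = c(1, 0.5))
  expect_equal(as.numeric(fd3m_lattice(pk)), 172.0, tolerance = 0.003)
  expect_equal(as.numeric(fd3m_lattice(
    tibble::tibble(q = 0.0700, height = 1, fwhm = 0.0025, prominence = 1))),
    2 * pi * sqrt(3) / 0.0700)
  # no peak in window: absence marker
  expect_true(is.na(fd3m_lattice(
    tibble::tibble(q = 0.2, height = 1, fwhm = 0.0025, prominence = 1))))
  # equal-height tie: lowest q wins, ambiguity flagged
  pk <- tibble::tibble(q = c(0.060, 0.080), height = c(1, 1),
                       fwhm = 0.0025, prominence = c(1, 1))
  a <- fd3m_lattice(pk)
  expect_equal(as.numeric(a), 2 * pi * sqrt(3) / 0.060)
  expect_true(isTRUE(attr(a, "ambiguous")))
  # strictly decreasing in the selected q
  qs <- seq(0.060, 0.084, by = 0.004)
  as <- vapply(qs, function(q) {
    as.numeric(fd3m_lattice(tibble::tibble(q = q, height = 1, fwhm = 0.0025,
                                           prominence = 1)))
  }, numeric(1))
  expect_true(all(diff(as) < 0))
})
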