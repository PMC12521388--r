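test_that("chemical potentials reduce to the ideal form and respect uniformity", {
  prof <- depot_profile(n = 10, water = 0.2, spc = 0.5)
  ideal <- free_energy_model(chi_ws = -1e-12, chi_wg = 0, chi_sg = 0)
  mu <- chemical_potentials(prof, ideal)
  rt <- 8.314462618 * 310
  expect_equal(mu$mu_water, rep(rt * log(0.2), 10), tolerance = 1e-9)
  expect_equal(mu$mu_spc, rep(rt * log(0.4), 10), tolerance = 1e-9)
  # uniform profile: spatially constant potentials for every species
  mu <- chemical_potentials(prof, free_energy_model())
  expect_lt(diff(range(mu$mu_water)), 1e-9)
  expect_lt(diff(range(mu$mu_spc)), 1e-9)
  expect_lt(diff(range(mu$mu_gdo)), 1e-9)
  # water prefers SPC: mu_water lower in the SPC-rich node
  prof2 <- depot_profile(n = 2, radius_mm = 1, water = 0.2,
                         spc = function(r) c(0.9, 0.1))
  mu2 <- chemical_potentials(prof2, free_energy_model())
  expect_lt(mu2$mu_water[1], mu2$mu_water[2])
  # zero fractions are floored and flagged
  prof3 <- depot_profile(n = 4, water = 0, spc = 0.5)
  expect_identical(attr(chemical_potentials(prof3), "flag"), "floored")
})

test_that("the default model is anchored at the 16% hydration limit", {
  m <- free_energy_model()
  expect_lt(m$chi_ws, m$chi_wg)
  # at 16% water and 50/50 lipid, water activity equals the reservoir's
  phi_l <- (1 - 0.16) / 2
  act <- exp(log(0.16) + m$chi_ws * phi_l + m$chi_wg * phi_l -
               m$chi_sg * phi_l^2)
  expect_equal(act, 0.996, tolerance = 1e-9)
  expect_error(free_energy_model(chi_ws = 3, chi_wg = 1), "chi_ws < chi_wg")
})

test_that("a uniform equilibrated profile is a fixed point of the step", {
  m <- free_energy_model()
  prof <- depot_profile(n = 20, water = 0.16, spc = 0.5)
  dt <- 0.25 * (attr(prof, "dr_mm") * 1e-3)^2 / 1e-11
  out <- transport_step(prof, m, dt)
  expect_equal(out$m_water, prof$m_water, tolerance = 1e-7)
  expect_equal(out$m_spc, prof$m_spc, tolerance = 1e-12)
  # stability guard
  expect_error(transport_step(prof, m, dt * 4), "unstable")
  # zero-gradient closed profile unchanged exactly
  out <- transport_step(prof, m, dt, boundary = "closed")
  expect_equal(out$m_water, prof$m_water, tolerance = 1e-15)
})

test_that("the ideal limit reproduces the classical Fick erf solution", {
  # step profile relaxing in a closed slab, all species equal D
  d <- 1e-11
  prof <- depot_profile(n = 100, radius_mm = 2,
                        water = function(r) ifelse(r < 1, 0.3, 0.1),
                        spc = 0.5, d_water = d, d_spc = d, d_gdo = d,
                        geometry = "slab")
  ideal <- free_energy_model(chi_ws = -1e-12, chi_wg = 0, chi_sg = 0)
  t_end <- 5e3 # s: front well clear of both walls
  traj <- transport_run(prof, ideal, horizon_days = t_end / 86400,
                        cadence_days = t_end / 86400, boundary = "closed")
  fin <- dplyr::filter(traj, .data$time_days == max(.data$time_days))
  exact <- 0.1 + 0.1 * pracma::erfc((fin$r_mm - 1) * 1e-3 /
                                      (2 * sqrt(d * t_end)))
  expect_lt(max(abs(fin$c_water - exact)) / 0.2, 0.01)
})

test_that("lipid mass is conserved to 1e-9 while water enters at the rim", {
  prof <- depot_profile(n = 30, radius_mm = 4, water = 0, spc = 0.5)
  traj <- transport_run(prof, horizon_days = 7, cadence_days = 7)
  g <- glance(traj)
  expect_lt(g$lipid_rel_drift, 1e-9)
  expect_lt(g$spc_rel_drift, 1e-9)
  fin <- dplyr::filter(traj, .data$time_days == 7)
  expect_gt(mean(fin$c_water), 0.01)
  # fractions remain a partition of unity
  expect_equal(fin$c_water + fin$c_spc + fin$c_gdo, rep(1, 30),
               tolerance = 1e-12)
})

test_that("water gradients drive uphill lipid diffusion", {
  # equal SPC mass on both sides, different hydration: the SPC chemical
  # potential differs, so SPC flows despite a flat concentration profile
  prof <- depot_profile(n = 2, radius_mm = 1, geometry = "slab",
                        water = function(r) c(0.2, 0.05),
                        spc = function(r) 0.4 / (1 - c(0.2, 0.05)))
  expect_equal(prof$m_spc, c(0.4, 0.4))
  mu <- chemical_potentials(prof, free_energy_model())
  expect_gt(abs(mu$mu_spc[1] - mu$mu_spc[2]), 1)
  dt <- 0.25 * (attr(prof, "dr_mm") * 1e-3)^2 / 1e-11
  out <- transport_step(prof, free_energy_model(), dt, boundary = "closed")
  expect_gt(abs(out$m_spc[1] - prof$m_spc[1]), 0)
})

test_that("horizon zero returns the initial state only", {
  prof <- depot_profile(n = 10, water = 0.1, spc = 0.5)
  traj <- transport_run(prof, horizon_days = 0)
  expect_equal(unique(traj$time_days), 0)
  expect_equal(traj$c_water, rep(0.1, 10))
})

test_that("phase labels follow the composition lookup", {
  expect_identical(classify_phase(c(0.0, 0.16, 0.16, 0.05),
                                  c(0.5, 0.5, 0.6, 0.5)),
                   c("L2", "Fd3m", "H2", "Pm3n"))
})
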