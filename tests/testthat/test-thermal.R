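test_that("geometry labeling matches the analytic ellipsoid", {
  g <- gland_geometry()  # 5.5 x 2.2 x 2.2 mm full axes, 0.5 mm shell
  grid <- sim_grid(spacing = 0.1, gland = g, duration = 1)
  lab <- build_geometry(g, grid)
  vol <- sum(lab$labels == 1L) * grid$spacing^3
  analytic <- 4 / 3 * pi * prod(g$semi)  # 13.94 mm^3
  expect_lt(abs(vol / analytic - 1), 0.05)
  # center voxel is adrenal
  ctr <- (dim(lab$labels) + 1) / 2
  expect_equal(lab$labels[ctr[1], ctr[2], ctr[3]], 1L)
  # zero shell thickness -> no fat voxels
  g0 <- gland_geometry(fat_shell_thickness = 0)
  lab0 <- build_geometry(g0, sim_grid(spacing = 0.2, gland = g0, margin = 1.5,
                                      duration = 1))
  expect_equal(sum(lab0$labels == 2L), 0)
  # coarse grid and tight bounds are rejected
  expect_error(build_geometry(g, sim_grid(spacing = 0.3, gland = g)),
               "too coarse")
  tight <- sim_grid(spacing = 0.2, bounds = rbind(-g$semi - 0.6, g$semi + 0.6))
  expect_error(build_geometry(g, tight), "margin")
})

test_that("injection sources carry the right power density and radius", {
  g <- gland_geometry()
  grid <- sim_grid(spacing = 0.1, gland = g, duration = 1)
  lab <- build_geometry(g, grid)
  src <- build_source(default_injection_sites(g), grid, lab)
  # 600 W/g x 40 mg/ml = 2.4e7 W/m^3
  expect_equal(max(src), 2.4e7)
  # total power: 2 sites x 600 W/g x 0.04 mg Fe = 0.048 W, within 2 %
  expect_equal(attr(src, "total_power"), 0.048)
  expect_lt(abs(attr(src, "integrated_power") / 0.048 - 1), 0.02)
  # 1 ul bolus radius (3V/4pi)^(1/3) = 0.620 mm: no source beyond it
  ax <- magnetoadrenal:::grid_axes(grid)
  a <- (3 / (4 * pi))^(1 / 3)
  d2 <- outer(outer((ax[[1]] - 1)^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  expect_true(all(src[d2 > (a + 0.1)^2 &
                        outer(outer((ax[[1]] + 1)^2, ax[[2]]^2, `+`),
                              ax[[3]]^2, `+`) > (a + 0.1)^2] == 0))
  # zero-SLP control particles give a zero field
  s0 <- build_source(list(injection_spec(c(0, 0, 0), slp = 0)), grid, lab)
  expect_true(all(s0 == 0))
  expect_error(build_source(list(injection_spec(c(5, 0, 0))), grid, lab),
               "outside")
})

test_that("solver preserves equilibrium and conserves energy", {
  lab <- oracle_box(spacing = 0.25, half = 1.5, duration = 5)
  # zero source, To = Tb: exactly constant
  f <- simulate_bioheat(lab, NULL, tissue = same_tissue())
  expect_equal(range(f$final), c(37, 37))
  expect_equal(f$peak, 37)
  # uniform source, insulated, no perfusion: dT/dt = q / (rho C) exactly
  q <- 1e5
  f2 <- simulate_bioheat(lab, array(q, lab$grid$dims),
                         tissue = same_tissue(), perfusion = no_perfusion(),
                         boundary = "insulated")
  expect_lt(abs((mean(f2$final) - 37) / (q / (1020 * 3540) * 5) - 1), 1e-3)
})

test_that("probe temperatures rise monotonically under constant heating", {
  lab <- oracle_box(spacing = 0.25, half = 2, duration = 10)
  src <- build_source(list(injection_spec(c(0, 0, 0))), lab$grid, lab)
  f <- simulate_bioheat(lab, src, tissue = same_tissue(),
                        probe_points = rbind(c(0, 0, 0), c(0.5, 0, 0)))
  for (p in c("probe1", "probe2"))
    expect_true(all(diff(f$probe_traces[[p]]) >= -1e-9))
  # bounded by the no-perfusion steady solution of the same source
  bound <- 37 + sphere_steady_rise(2.4e7, (3 / (4 * pi))^(1 / 3), 0.52)
  expect_lt(f$peak, bound)
})

test_that("stability violations are rejected before stepping", {
  lab <- oracle_box(spacing = 0.25, half = 1.5, duration = 5)
  lab$grid$dt <- 1  # far beyond h^2 / (6 alpha) ~ 0.073 s
  expect_error(simulate_bioheat(lab, NULL, tissue = same_tissue()),
               "stability")
})

test_that("threshold report handles constant fields and boundary thresholds", {
  lab <- oracle_box(spacing = 0.25, half = 1.5, duration = 2)
  f <- simulate_bioheat(lab, NULL, tissue = same_tissue(),
                        probe_points = rbind(c(0, 0, 0)),
                        snapshot_times = 2)
  rep42 <- threshold_report(f, 42, lab)
  expect_true(is.na(rep42$time_to_threshold[1]))
  expect_equal(rep42$volume_above$volume_mm3, 0)
  # >= comparison: at threshold == To the whole tissue counts from t = 0
  rep37 <- threshold_report(f, 37, lab)
  expect_equal(rep37$volume_above$volume_mm3, rep37$tissue_volume_mm3)
  expect_equal(rep37$time_to_threshold[1], 0)
  expect_warning(threshold_report(f, 36, lab), "below")
})

test_that("peak temperature is grid converged", {
  p1 <- simulate_adrenal_heating(spacing = 0.2)$report$peak_temperature
  p2 <- simulate_adrenal_heating(spacing = 0.1)$report$peak_temperature
  expect_lt(abs(p2 / p1 - 1), 0.03)
})

test_that("gland simulation reaches the TRPV1 threshold at coarse spacing", {
  sim <- simulate_adrenal_heating(spacing = 0.2)
  expect_gte(sim$report$peak_temperature, 42)
  expect_true(all(is.finite(sim$field$final)))
  expect_gte(min(sim$field$final), 37)
  # crossing time is interpolated and strictly positive
  expect_true(all(sim$report$time_to_threshold > 0))
})
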