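# Electric-field model: geometry bookkeeping, conduction solver, coverage
# metrics and threshold inversion.

test_that("voltage-to-distance ratio is exact arithmetic with guarded geometry", {
  expect_equal(voltage_to_distance_ratio(600, 4), 1500)
  expect_equal(voltage_to_distance_ratio(500, 3), 1666.6667, tolerance = 1e-6)
  expect_equal(voltage_to_distance_ratio(0, 4), 0)
  expect_error(voltage_to_distance_ratio(600, 0), "spacing")
  expect_error(voltage_to_distance_ratio(600, -4), "spacing")
})

test_that("burst schedule arithmetic matches the 2-5-2-5 protocol", {
  s <- burst_schedule(2, 5, 2, 5, energized_per_burst_us = 100,
                      n_bursts = 200, rate_hz = 1)
  expect_equal(s$cycles_per_burst, 25)
  expect_equal(s$total_energized_us, 20000)
  expect_equal(s$total_duration_s, 200)
  one <- burst_schedule(2, 5, 2, 5, energized_per_burst_us = 4)
  expect_equal(one$cycles_per_burst, 1)
  expect_error(burst_schedule(2, 5, 2, 5, energized_per_burst_us = 101),
               "inconsistent waveform")
})

test_that("electrode and domain invariants are enforced", {
  expect_error(electrode_pair(spacing = 0.3, diameter = 0.4), "spacing > diameter")
  expect_error(electrode_pair(exposure = 0), "exposure")
  expect_error(electrode_pair(applied_voltage = -1), "applied_voltage")
  expect_error(tissue_domain(grid_step = 0.3), "resolved")
  expect_error(tissue_domain(c(6, 6)), "3 x spacing")
  expect_error(tissue_domain(conductivity = -1), "conductivities")
})

test_that("zero applied voltage yields an identically zero field", {
  el <- electrode_pair(applied_voltage = 0)
  dom <- tissue_domain(c(24, 24), grid_step = 0.2, electrodes = el)
  sol <- solve_field(dom, el)
  expect_true(all(sol$e_magnitude == 0))
  expect_true(all(sol$potential == 0))
})

test_that("potential respects the discrete maximum principle and scales linearly", {
  s1 <- small_3d_field(600)
  expect_true(all(s1$potential <= 300 + 1e-9))
  expect_true(all(s1$potential >= -300 - 1e-9))
  expect_true(all(s1$e_magnitude >= 0))
  s2 <- small_3d_field(1200)
  # linearity of the conduction problem: doubling V doubles |E| pointwise
  expect_lt(max(abs(s2$e_magnitude - 2 * s1$e_magnitude)) /
              max(s2$e_magnitude), 1e-3)
})

test_that("2-D solve matches the closed-form two-wire solution away from the conductors", {
  sol <- small_2d_field(100)
  g <- expand.grid(x = sol$axes[[1]], y = sol$axes[[2]])
  ref <- two_wire_field(g$x, g$y, voltage = 100)
  eref <- matrix(ref$e_magnitude, length(sol$axes[[1]]))
  dmin <- matrix(pmin(sqrt((g$x - 2)^2 + g$y^2), sqrt((g$x + 2)^2 + g$y^2)),
                 length(sol$axes[[1]]))
  # one electrode diameter from the conductor surface (radius 0.2 mm)
  far <- dmin >= 0.2 + 0.4
  rel <- abs(sol$e_magnitude - eref) / eref
  expect_lt(max(rel[far]), 0.02)
})

test_that("coverage metrics behave at threshold extremes and are monotone", {
  sol <- small_3d_field(600)
  sph <- tumor_sphere(142)
  expect_equal(ablation_metrics(sol, 0, sph)$coverage, 100)
  big <- max(sol$e_magnitude) + 1
  expect_equal(ablation_metrics(sol, big, sph)$coverage, 0)
  ths <- seq(200, 3000, by = 200)
  cov <- vapply(ths, function(t) ablation_metrics(sol, t, sph)$coverage, 1)
  expect_true(all(diff(cov) <= 0))       # non-increasing in threshold
  m <- ablation_metrics(sol, 1077, sph)
  expect_lte(m$ablated_volume, m$region_volume)
  # a degenerate sphere placed between lattice points covers no cells
  expect_error(ablation_metrics(sol, 500,
                                tumor_sphere(1e-9, center = c(0.13, 0.07, 0.11))),
               "invalid region")
})

test_that("coverage curve is monotone in the ratio, consistent with a direct solve, and saturates", {
  el <- electrode_pair(applied_voltage = 600)
  dom <- tissue_domain(c(24, 24, 24), grid_step = 0.25, electrodes = el,
                       validate = FALSE)
  sph <- tumor_sphere(142)
  cc <- coverage_curve(dom, el, c(500, 1500, 3000, 2e5), 1077, region = sph)
  expect_true(all(diff(cc$coverage_percent) >= 0))
  direct <- ablation_metrics(small_3d_field(600), 1077, sph)
  expect_equal(cc$coverage_percent[cc$ratio_V_per_cm == 1500],
               direct$coverage, tolerance = 1e-6)
  # enormous ratio ablates the whole region
  expect_equal(cc$coverage_percent[cc$ratio_V_per_cm == 2e5], 100)
})

test_that("threshold inversion is the inverse of the forward area within a grid quantile", {
  sol <- small_2d_field(100)
  cell <- sol$grid_step^2
  for (t0 in c(50, 150, 400)) {
    area <- sum(sol$e_magnitude >= t0) * cell
    t_hat <- invert_threshold(sol, area)
    e_sorted <- sort(as.vector(sol$e_magnitude), decreasing = TRUE)
    k <- round(area / cell)
    gap <- abs(e_sorted[max(k - 1, 1)] - e_sorted[min(k + 1, length(e_sorted))])
    expect_lte(abs(t_hat - t0), gap + 1e-9)
  }
  # linearity: doubling the voltage doubles the recovered threshold
  sol2 <- small_2d_field(200)
  area <- sum(sol$e_magnitude >= 150) * cell
  expect_equal(invert_threshold(sol2, area) / invert_threshold(sol, area), 2,
               tolerance = 1e-3)
  # boundary and error cases
  total <- length(sol$e_magnitude) * cell
  expect_equal(invert_threshold(sol, total), min(sol$e_magnitude))
  expect_error(invert_threshold(sol, 0), "out of range")
  expect_error(invert_threshold(sol, total * 2), "out of range")
})

test_that("layered conductivity changes the field while staying within bounds", {
  el <- electrode_pair(applied_voltage = 600)
  dom_h <- tissue_domain(c(24, 24), grid_step = 0.2, electrodes = el)
  dom_l <- tissue_domain(c(24, 24), grid_step = 0.2, electrodes = el,
                         conductivity = 0.2,
                         regions = list(list(shape = "sphere", center = c(0, 0),
                                             radius = 3.23, conductivity = 0.6,
                                             label = "tumor")))
  sh <- solve_field(dom_h, el)
  sl <- solve_field(dom_l, el)
  expect_true(all(sl$potential <= 300 + 1e-9) && all(sl$potential >= -300 - 1e-9))
  expect_gt(max(abs(sl$potential - sh$potential)), 1)  # contrast has an effect
})

test_that("field config round-trips through YAML", {
  cfg <- list(electrodes = list(spacing = 4, diameter = 0.4, exposure = 4,
                                applied_voltage = 600),
              grid = list(bounding_box = c(24, 24), step = 0.2),
              conductivity = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  fc <- read_field_config(path)
  expect_s3_class(fc$electrodes, "electrode_pair")
  expect_equal(fc$domain$grid_step, 0.2)
  expect_equal(fc$electrodes$applied_voltage, 600)
})
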