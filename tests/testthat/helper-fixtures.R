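# Shared fixtures: small field solves are expensive enough to cache across
# test files within a run.

fixture_env <- new.env()

# Coarse 2-D homogeneous solve with analytic far-field boundary, used by the
# solver oracle and inversion tests.
small_2d_field <- function(voltage = 100, step = 0.1) {
  key <- sprintf("f2d_%g_%g", voltage, step)
  if (is.null(fixture_env[[key]])) {
    el <- electrode_pair(applied_voltage = voltage)
    dom <- tissue_domain(c(24, 24), grid_step = step, electrodes = el)
    bp <- function(coords) two_wire_field(coords[, 1], coords[, 2],
                                          voltage = voltage)$phi
    fixture_env[[key]] <- solve_field(dom, el, outer = "dirichlet",
                                      boundary_potential = bp)
  }
  fixture_env[[key]]
}

# Tiny 3-D solve on a coarse grid (fast; used for linearity / metrics tests).
small_3d_field <- function(voltage = 600, step = 0.25) {
  key <- sprintf("f3d_%g_%g", voltage, step)
  if (is.null(fixture_env[[key]])) {
    el <- electrode_pair(applied_voltage = voltage)
    dom <- tissue_domain(c(24, 24, 24), grid_step = step, electrodes = el,
                         validate = FALSE)
    fixture_env[[key]] <- solve_field(dom, el)
  }
  fixture_env[[key]]
}

# Digitized disk mask of radius r px centred in an n x n image.
disk_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix((g$x - cx)^2 + (g$y - cy)^2 <= r^2, n, n)
}
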