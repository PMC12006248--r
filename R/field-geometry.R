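#' Paired needle electrode configuration
#'
#' Describes two parallel monopolar needle electrodes energized at +V/2 and
#' -V/2. The defaults are the in vivo configuration used throughout the
#' package: 0.4 mm diameter needles, 4 mm center-to-center spacing, 4 mm
#' active exposure.
#'
#' @param spacing center-to-center spacing, mm.
#' @param diameter conductor diameter, mm.
#' @param exposure active (conducting) length, mm. In 2-D solves the
#'   electrodes are treated as infinite wires and `exposure` is the assumed
#'   out-of-plane depth.
#' @param applied_voltage total potential difference between the needles, V.
#' @return An object of class `electrode_pair`.
#' @export
#' @examples
#' electrode_pair(applied_voltage = 600)
electrode_pair <- function(spacing = 4, diameter = 0.4, exposure = 4,
                           applied_voltage = 0) {
  if (!(spacing > diameter && diameter > 0))
    stop("invalid electrode geometry: need spacing > diameter > 0", call. = FALSE)
  if (exposure <= 0) stop("invalid electrode geometry: exposure must be > 0", call. = FALSE)
  if (applied_voltage < 0) stop("applied_voltage must be >= 0", call. = FALSE)
  structure(list(spacing = spacing, diameter = diameter, exposure = exposure,
                 applied_voltage = applied_voltage),
            class = "electrode_pair")
}

#' Tissue domain for the conduction solve
#'
#' A rectangular box, centred on the electrode-pair midpoint, optionally
#' partitioned into conductivity regions. The default is a homogeneous
#' domain: in a source-free conduction problem with a single conductivity
#' the potential is independent of its value, so `conductivity` only matters
#' once `regions` introduces contrast.
#'
#' @param bounding_box side lengths of the box in mm; length 2 (2-D) or 3.
#' @param grid_step lattice spacing, mm.
#' @param conductivity background conductivity, S/m.
#' @param regions list of region specs, each a list with `shape`
#'   (`"sphere"`, `"slab"` or `"cylinder"`), `conductivity` (S/m), `label`,
#'   and shape parameters: `center`/`radius` for spheres and cylinders
#'   (cylinder axis along z, optional `height`), `axis`/`from`/`to` for
#'   slabs. Coordinates are mm relative to the domain center.
#' @param validate enforce the sizing invariants (electrode resolved by at
#'   least two cells across its radius; box extending at least three
#'   spacings beyond the electrode midpoint along every axis).
#' @param electrodes electrode pair used for the sizing checks.
#' @return An object of class `tissue_domain`.
#' @export
tissue_domain <- function(bounding_box = c(24, 24, 24), grid_step = 0.1,
                          conductivity = 0.5, regions = list(),
                          electrodes = electrode_pair(), validate = TRUE) {
  dimensionality <- length(bounding_box)
  if (!dimensionality %in% c(2L, 3L)) stop("bounding_box must have length 2 or 3", call. = FALSE)
  if (grid_step <= 0) stop("grid_step must be > 0", call. = FALSE)
  if (conductivity <= 0) stop("conductivities must be > 0", call. = FALSE)
  for (r in regions) {
    if (is.null(r$conductivity) || r$conductivity <= 0)
      stop("conductivities must be > 0", call. = FALSE)
    if (!r$shape %in% c("sphere", "slab", "cylinder"))
      stop("unknown region shape: ", r$shape, call. = FALSE)
  }
  if (validate) {
    if (grid_step > electrodes$diameter / 2)
      stop("grid_step must be <= diameter/2 so the electrode is resolved",
           call. = FALSE)
    if (any(bounding_box / 2 < 3 * electrodes$spacing))
      stop("bounding box must extend >= 3 x spacing beyond the electrode midpoint",
           call. = FALSE)
  }
  structure(list(bounding_box = bounding_box, grid_step = grid_step,
                 conductivity = conductivity, regions = regions,
                 dimensionality = dimensionality),
            class = "tissue_domain")
}

#' Voltage-to-distance ratio
#'
#' The nominal field strength used to label pulse protocols: applied voltage
#' divided by electrode spacing, in V/cm.
#'
#' @param voltage applied voltage, V.
#' @param spacing electrode spacing, mm.
#' @return Ratio in V/cm.
#' @export
#' @examples
#' voltage_to_distance_ratio(600, 4)  # 1500 V/cm
voltage_to_distance_ratio <- function(voltage, spacing) {
  if (any(spacing <= 0)) stop("invalid electrode geometry: spacing must be > 0", call. = FALSE)
  voltage / (spacing / 10)
}

#' Bipolar burst schedule summary
#'
#' Book-keeping for H-FIRE burst delivery: a bipolar cycle is a positive
#' pulse, an inter-phase delay, a negative pulse, and an inter-pulse delay
#' (e.g. the 2-5-2-5 scheme). Only the pulse widths are energized time.
#'
#' @param positive_us,negative_us pulse widths, microseconds.
#' @param interphase_us,interpulse_us delays, microseconds.
#' @param energized_per_burst_us energized time per burst, microseconds;
#'   must be an integer multiple of `positive_us + negative_us`.
#' @param n_bursts number of bursts.
#' @param rate_hz burst repetition rate, Hz.
#' @return List with `cycles_per_burst`, `burst_duration_us`,
#'   `total_energized_us` and `total_duration_s`.
#' @export
#' @examples
#' burst_schedule(2, 5, 2, 5, energized_per_burst_us = 100, n_bursts = 200)
burst_schedule <- function(positive_us = 2, interphase_us = 5, negative_us = 2,
                           interpulse_us = 5, energized_per_burst_us = 100,
                           n_bursts = 1, rate_hz = 1) {
  if (positive_us <= 0 || negative_us <= 0)
    stop("pulse widths must be > 0", call. = FALSE)
  if (energized_per_burst_us <= 0)
    stop("energized_per_burst_us must be > 0", call. = FALSE)
  cyc <- energized_per_burst_us / (positive_us + negative_us)
  if (abs(cyc - round(cyc)) > 1e-9)
    stop("inconsistent waveform: energized time per burst is not a whole ",
         "number of bipolar cycles", call. = FALSE)
  cyc <- round(cyc)
  cycle_us <- positive_us + interphase_us + negative_us + interpulse_us
  list(cycles_per_burst = cyc,
       burst_duration_us = cyc * cycle_us,
       total_energized_us = n_bursts * energized_per_burst_us,
       total_duration_s = n_bursts / rate_hz)
}
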