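# Typed configuration for the architectural model: operating conditions,
# per-block area budget, design variables and design-space bounds.
# Unit discipline: areas are held in um^2 internally (mm^2 accepted at the
# constructor boundary), times in seconds, photon densities in photons/mm^2.

UM2_PER_MM2 <- 1e6

#' Operating conditions of the dSiPM pixel
#'
#' Photophysics and timing constants under which the sensor is evaluated:
#' the SPAD photon detection probability, the peak incident scintillation
#' photon density, the monostable pulse width, the clock period that bounds
#' the scintillation build-up window, and the scintillator decay constant.
#'
#' @param pdp Photon detection probability of a single SPAD, fraction in
#'   (0, 1]. Probability that a photon impinging on active area triggers an
#'   avalanche.
#' @param d_ph Peak incident photon density over the build-up window,
#'   photons/mm^2.
#' @param t_pulse Monostable pulse width, seconds. Each microcell trigger
#'   places a pulse of this width on the subpixel OR-bus.
#' @param t_clk Clock period, seconds. Also the scintillation build-up
#'   window over which `d_ph` accumulates.
#' @param tau_sct Scintillator decay time constant, seconds (40 ns for
#'   LYSO).
#' @param t_dead SPAD dead time, seconds. Metadata: it is quoted for the
#'   DCR characterization conditions and is much longer than a
#'   scintillation event, so detection models treat a triggered microcell
#'   as dead for the remainder of the event.
#'
#' @return An object of class `sipm_operating_conditions` (a named list).
#' @seealso [area_budget()], [architecture()], [detected_density()]
#' @examples
#' operating_conditions()
#' @export
operating_conditions <- function(pdp = 0.30,
                                 d_ph = 450,
                                 t_pulse = 800e-12,
                                 t_clk = 20e-9,
                                 tau_sct = 40e-9,
                                 t_dead = 5e-6) {
  stopifnot(
    is.numeric(pdp), length(pdp) == 1L, pdp > 0, pdp <= 1,
    is.numeric(d_ph), length(d_ph) == 1L, d_ph > 0,
    is.numeric(t_pulse), length(t_pulse) == 1L, t_pulse >= 0,
    is.numeric(t_clk), length(t_clk) == 1L, t_clk > 0,
    is.numeric(tau_sct), length(tau_sct) == 1L, tau_sct > 0,
    is.numeric(t_dead), length(t_dead) == 1L, t_dead > 0
  )
  structure(
    list(pdp = pdp, d_ph = d_ph, t_pulse = t_pulse, t_clk = t_clk,
         tau_sct = tau_sct, t_dead = t_dead),
    class = "sipm_operating_conditions"
  )
}

#' @export
print.sipm_operating_conditions <- function(x, ...) {
  cat("<sipm_operating_conditions>\n")
  cat(sprintf("  PDP      %.3g\n", x$pdp))
  cat(sprintf("  Dph      %.4g photons/mm^2\n", x$d_ph))
  cat(sprintf("  Tpulse   %.4g ns\n", x$t_pulse * 1e9))
  cat(sprintf("  Tclk     %.4g ns\n", x$t_clk * 1e9))
  cat(sprintf("  tau_sct  %.4g ns\n", x$tau_sct * 1e9))
  cat(sprintf("  t_dead   %.4g us\n", x$t_dead * 1e6))
  invisible(x)
}

#' Per-block circuit area budget of the pixel
#'
#' Areas of the circuit blocks that compete with the SPADs for pixel area:
#' the pixel itself, the TDC and FSM (one each per pixel), the counter and
#' adder tree (one per subpixel), and the per-SPAD quenching/recharge
#' circuit and 1b-SRAM plus the reset-and-monostable block shared by the
#' SPADs of a microcell. The SPAD footprint is modelled as a square active
#' area surrounded by a constant-width dead frame (guard ring and cathode
#' connection) of width `guard_width`.
#'
#' All areas are given in mm^2 and stored internally in um^2;
#' `guard_width` is in um. The default `guard_width` is calibrated once so
#' that the SPAD-count bookkeeping reproduces the reference 1 mm^2
#' implementation (762 SPADs at a 512 um^2 active area with the default
#' block areas); see [calibrate_guard_width()].
#'
#' @param a_pxl Pixel area, mm^2.
#' @param a_tdc,a_fsm TDC and FSM block areas, mm^2 (per pixel).
#' @param a_cnt Counter plus adder-tree area, mm^2 (per subpixel).
#' @param a_qrc,a_sram Quenching/recharge circuit and 1b-SRAM areas, mm^2
#'   (per SPAD).
#' @param a_rm Shared reset-and-monostable area, mm^2 (per microcell).
#' @param guard_width Dead-frame width around the square active area, um.
#'
#' @return An object of class `sipm_area_budget`. Areas are stored in um^2
#'   under the same names.
#' @seealso [spads_per_pixel()], [total_spad_area()]
#' @examples
#' area_budget()                # reference 1 mm^2 budget
#' area_budget(a_pxl = 2.25)    # same blocks, larger pixel
#' @export
area_budget <- function(a_pxl = 1,
                        a_tdc = 6.5e-3,
                        a_fsm = 14e-3,
                        a_cnt = 2.6e-3,
                        a_qrc = 72e-6,
                        a_sram = 18e-6,
                        a_rm = 205e-6,
                        guard_width = calibrated_guard_width_um()) {
  areas <- c(a_pxl = a_pxl, a_tdc = a_tdc, a_fsm = a_fsm, a_cnt = a_cnt,
             a_qrc = a_qrc, a_sram = a_sram, a_rm = a_rm)
  if (!all(is.finite(areas)) || any(areas < 0)) {
    stop("all block areas must be finite and non-negative", call. = FALSE)
  }
  if (a_tdc + a_fsm >= a_pxl) {
    stop("TDC + FSM overhead exceeds the pixel area", call. = FALSE)
  }
  stopifnot(is.numeric(guard_width), length(guard_width) == 1L,
            guard_width >= 0)
  structure(
    c(as.list(areas * UM2_PER_MM2), list(guard_width = guard_width)),
    class = "sipm_area_budget"
  )
}

#' @export
print.sipm_area_budget <- function(x, ...) {
  cat("<sipm_area_budget> (um^2)\n")
  for (nm in c("a_pxl", "a_tdc", "a_fsm", "a_cnt", "a_qrc", "a_sram", "a_rm")) {
    cat(sprintf("  %-7s %12.4g\n", nm, x[[nm]]))
  }
  cat(sprintf("  guard_width %.4g um\n", x$guard_width))
  invisible(x)
}

#' Architecture design variables
#'
#' The three variables explored by the optimizer: the number of SPADs
#' sharing a microcell's monostable and reset (`n_uc`), the number of
#' subpixels (OR-bus + counter groups) per pixel (`m_spl`), and the SPAD
#' active area (`a_aspad`, um^2).
#'
#' @param n_uc SPADs per microcell, positive integer.
#' @param m_spl Subpixels per pixel, positive integer.
#' @param a_aspad SPAD active area, um^2.
#' @return An object of class `sipm_architecture`.
#' @examples
#' architecture(n_uc = 4, m_spl = 16, a_aspad = 512)
#' @export
architecture <- function(n_uc, m_spl, a_aspad) {
  stopifnot(
    is.numeric(n_uc), length(n_uc) == 1L, n_uc >= 1, n_uc == round(n_uc),
    is.numeric(m_spl), length(m_spl) == 1L, m_spl >= 1, m_spl == round(m_spl),
    is.numeric(a_aspad), length(a_aspad) == 1L
  )
  if (!is.finite(a_aspad) || a_aspad <= 0) {
    stop("a_aspad must be a positive active area in um^2", call. = FALSE)
  }
  structure(
    list(n_uc = as.integer(n_uc), m_spl = as.integer(m_spl),
         a_aspad = a_aspad),
    class = "sipm_architecture"
  )
}

#' @export
print.sipm_architecture <- function(x, ...) {
  cat(sprintf("<sipm_architecture> n_uc=%d m_spl=%d a_aspad=%.4g um^2\n",
              x$n_uc, x$m_spl, x$a_aspad))
  invisible(x)
}

#' Design-space bounds for the architecture sweep
#'
#' @param n_uc_values Allowed SPADs-per-microcell values. Default 1..16.
#' @param m_spl_values Allowed subpixels-per-pixel values. Default powers
#'   of two up to 256 (power-of-two subpixel counts keep the TDC trigger
#'   path symmetric).
#' @param a_aspad_bounds Interval of SPAD active areas probed by the 1-D
#'   optimizer, um^2. The default brackets both the measured 200 um^2
#'   reference device and all optima encountered in practice.
#' @return An object of class `sipm_design_space`.
#' @examples
#' design_space()
#' @export
design_space <- function(n_uc_values = 1:16,
                         m_spl_values = 2^(0:8),
                         a_aspad_bounds = c(50, 5000)) {
  n_uc_values <- as.integer(n_uc_values)
  m_spl_values <- as.integer(m_spl_values)
  stopifnot(
    length(n_uc_values) >= 1L, all(n_uc_values >= 1L),
    !is.unsorted(n_uc_values, strictly = TRUE),
    length(m_spl_values) >= 1L, all(m_spl_values >= 1L),
    !is.unsorted(m_spl_values, strictly = TRUE),
    length(a_aspad_bounds) == 2L, all(a_aspad_bounds > 0),
    a_aspad_bounds[1] < a_aspad_bounds[2]
  )
  structure(
    list(n_uc_values = n_uc_values, m_spl_values = m_spl_values,
         a_aspad_bounds = as.numeric(a_aspad_bounds)),
    class = "sipm_design_space"
  )
}

#' @export
print.sipm_design_space <- function(x, ...) {
  cat("<sipm_design_space>\n")
  cat("  n_uc:   ", paste(x$n_uc_values, collapse = " "), "\n")
  cat("  m_spl:  ", paste(x$m_spl_values, collapse = " "), "\n")
  cat(sprintf("  a_aspad: [%.4g, %.4g] um^2\n",
              x$a_aspad_bounds[1], x$a_aspad_bounds[2]))
  invisible(x)
}

#' Read or write a flat key-value configuration file
#'
#' The configuration mirrors the reference operating point of the
#' implemented device: pixel and block areas (mm^2), guard width (um),
#' photophysics and timing constants. `read_sipm_config()` returns the
#' typed objects used throughout the package; `default_sipm_config_path()`
#' points at the configuration shipped with the package.
#'
#' @param path Path to a YAML file with keys `a_pxl_mm2, a_tdc_mm2,
#'   a_fsm_mm2, a_cnt_mm2, a_qrc_mm2, a_sram_mm2, a_rm_mm2, guard_width_um,
#'   pdp, d_ph_per_mm2, t_pulse_s, t_clk_s, tau_sct_s, t_dead_s`.
#' @return A list with elements `budget` ([area_budget()]) and `op`
#'   ([operating_conditions()]).
#' @examples
#' cfg <- read_sipm_config(default_sipm_config_path())
#' cfg$op$pdp
#' @export
read_sipm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("a_pxl_mm2", "a_tdc_mm2", "a_fsm_mm2", "a_cnt_mm2", "a_qrc_mm2",
            "a_sram_mm2", "a_rm_mm2", "guard_width_um", "pdp", "d_ph_per_mm2",
            "t_pulse_s", "t_clk_s", "tau_sct_s", "t_dead_s")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  list(
    budget = area_budget(
      a_pxl = raw$a_pxl_mm2, a_tdc = raw$a_tdc_mm2, a_fsm = raw$a_fsm_mm2,
      a_cnt = raw$a_cnt_mm2, a_qrc = raw$a_qrc_mm2, a_sram = raw$a_sram_mm2,
      a_rm = raw$a_rm_mm2, guard_width = raw$guard_width_um
    ),
    op = operating_conditions(
      pdp = raw$pdp, d_ph = raw$d_ph_per_mm2, t_pulse = raw$t_pulse_s,
      t_clk = raw$t_clk_s, tau_sct = raw$tau_sct_s, t_dead = raw$t_dead_s
    )
  )
}

#' @rdname read_sipm_config
#' @export
default_sipm_config_path <- function() {
  system.file("extdata", "default-config.yaml", package = "dsipmopt",
              mustWork = TRUE)
}
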