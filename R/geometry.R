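# Deterministic area bookkeeping: SPAD footprint, SPADs per pixel, fill
# factor, and the one-off guard-width calibration of the footprint model.

#' Total SPAD footprint from its active area
#'
#' The SPAD is modelled as a square active region surrounded by a
#' constant-width dead frame accounting for the guard ring and cathode
#' connection, so the footprint is `(sqrt(a_aspad) + 2 * guard_width)^2`.
#'
#' @param a_aspad SPAD active area, um^2. Must be positive.
#' @param budget An [area_budget()]; only its `guard_width` is used.
#' @return Total SPAD footprint in um^2 (vectorised over `a_aspad`).
#' @examples
#' total_spad_area(512, area_budget(guard_width = 0))   # 512: no dead frame
#' total_spad_area(512, area_budget())                  # ~1089 when calibrated
#' @export
total_spad_area <- function(a_aspad, budget) {
  stopifnot(inherits(budget, "sipm_area_budget"))
  if (!all(is.finite(a_aspad)) || any(a_aspad <= 0)) {
    stop("a_aspad must be positive (um^2)", call. = FALSE)
  }
  (sqrt(a_aspad) + 2 * budget$guard_width)^2
}

#' Number of SPADs fitting in the pixel
#'
#' Divides the pixel area left over by the per-pixel (TDC, FSM) and
#' per-subpixel (counter/adder) blocks by the per-SPAD cost: the SPAD
#' footprint, its quenching/recharge circuit and SRAM bit, plus the
#' microcell-shared reset-and-monostable block amortised over the `n_uc`
#' SPADs that share it. Partial SPADs cannot be laid out, so the quotient
#' is floored; no divisibility by `m_spl * n_uc` is imposed.
#'
#' @param arch An [architecture()].
#' @param budget An [area_budget()].
#' @param strict If `TRUE` (default) an architecture whose overhead exceeds
#'   the pixel raises an error; if `FALSE` it returns `NA_integer_` so
#'   sweeps can mark the cell infeasible.
#' @return Integer SPAD count (vectorised over `arch$a_aspad` if numeric
#'   vectors are supplied via `architecture()` fields).
#' @examples
#' spads_per_pixel(architecture(4, 16, 512), area_budget())  # 762
#' @export
spads_per_pixel <- function(arch, budget, strict = TRUE) {
  stopifnot(inherits(arch, "sipm_architecture"),
            inherits(budget, "sipm_area_budget"))
  num <- budget$a_pxl - (budget$a_tdc + budget$a_fsm +
                           budget$a_cnt * arch$m_spl)
  if (num <= 0) {
    if (strict) {
      stop("infeasible architecture: per-pixel/per-subpixel overhead (",
           format(budget$a_tdc + budget$a_fsm + budget$a_cnt * arch$m_spl),
           " um^2) exceeds the pixel area", call. = FALSE)
    }
    return(NA_integer_)
  }
  den <- total_spad_area(arch$a_aspad, budget) + budget$a_qrc +
    budget$a_sram + budget$a_rm / arch$n_uc
  as.integer(floor(num / den))
}

#' Fill factor of the pixel
#'
#' Fraction of the pixel area that is photosensitive:
#' `n_spad * a_aspad / a_pxl`.
#'
#' @param n_spad Number of SPADs in the pixel.
#' @param a_aspad SPAD active area, um^2.
#' @param a_pxl Pixel area, mm^2.
#' @return Fill factor, a fraction in `[0, 1)`.
#' @examples
#' fill_factor(762, 512, 1)    # 0.390
#' fill_factor(7217, 511, 9)   # 0.410
#' @export
fill_factor <- function(n_spad, a_aspad, a_pxl) {
  stopifnot(all(n_spad >= 0), all(a_aspad > 0), all(a_pxl > 0))
  ff <- n_spad * a_aspad / (a_pxl * UM2_PER_MM2)
  if (any(ff >= 1)) {
    stop("inconsistent geometry: computed fill factor >= 1", call. = FALSE)
  }
  ff
}

#' Calibrate the guard width of the SPAD footprint model
#'
#' The footprint model has one free parameter, the dead-frame width. It is
#' fixed once by requiring that the SPAD-count bookkeeping reproduces a
#' reference implementation: by default 762 SPADs in a 1 mm^2 pixel with
#' `n_uc = 4`, `m_spl = 16` and a 512 um^2 active area. The floored count
#' equals the target over an interval of guard widths; the calibration
#' returns the width at the midpoint of that plateau (continuous quotient
#' equal to `n_spad_target + 1/2`), in closed form.
#'
#' @param n_spad_target Reference SPAD count to reproduce.
#' @param arch Reference [architecture()].
#' @param budget An [area_budget()]; its `guard_width` is ignored.
#' @return Guard width in um (about 5.185 um for the defaults).
#' @examples
#' g <- calibrate_guard_width()
#' spads_per_pixel(architecture(4, 16, 512), area_budget(guard_width = g))
#' @export
calibrate_guard_width <- function(n_spad_target = 762,
                                  arch = architecture(4, 16, 512),
                                  budget = area_budget(guard_width = 0)) {
  stopifnot(inherits(arch, "sipm_architecture"),
            inherits(budget, "sipm_area_budget"),
            n_spad_target >= 1)
  num <- budget$a_pxl - (budget$a_tdc + budget$a_fsm +
                           budget$a_cnt * arch$m_spl)
  if (num <= 0) stop("infeasible reference architecture", call. = FALSE)
  foot <- num / (n_spad_target + 0.5) -
    (budget$a_qrc + budget$a_sram + budget$a_rm / arch$n_uc)
  if (foot <= arch$a_aspad) {
    stop("no non-negative guard width reproduces the target SPAD count",
         call. = FALSE)
  }
  (sqrt(foot) - sqrt(arch$a_aspad)) / 2
}

# Cached default calibration (reference 1 mm^2 device, see
# calibrate_guard_width); used as the area_budget() default.
.guard_cache <- new.env(parent = emptyenv())

calibrated_guard_width_um <- function() {
  if (is.null(.guard_cache$g)) .guard_cache$g <- calibrate_guard_width()
  .guard_cache$g
}
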