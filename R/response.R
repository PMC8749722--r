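# Analytic sensor response: detected photon density, spatial and temporal
# pile-up probabilities, the sensitivity decomposition, and the closed-form
# saturating photon-counting curve.

#' Detected photon density over the build-up window
#'
#' Photons detected per mm^2 of active area during the scintillation
#' build-up window `[0, t_clk]`:
#' `PDP * Dph * (1 - exp(-Tclk / tau_sct))`.
#'
#' @param op An [operating_conditions()].
#' @return Detected photon density, photons/mm^2.
#' @examples
#' detected_density(operating_conditions())   # 53.12 /mm^2
#' @export
detected_density <- function(op) {
  stopifnot(inherits(op, "sipm_operating_conditions"))
  op$pdp * op$d_ph * (1 - exp(-op$t_clk / op$tau_sct))
}

#' Spatial pile-up probability at the microcell
#'
#' A microcell of `n_uc` SPADs fires a single monostable pulse however
#' many of its SPADs detect photons in the window, so it behaves as one
#' larger SPAD of area `n_uc * a_aspad`. Under Poisson illumination the
#' probability that a microcell is hit (equivalently, that one further
#' photon would find its microcell already busy) is
#' `1 - exp(-n_uc * a_aspad * d_det)`.
#'
#' @param n_uc SPADs per microcell.
#' @param a_aspad SPAD active area, um^2.
#' @param d_det Detected photon density, photons/mm^2
#'   (see [detected_density()]).
#' @return Probability in `[0, 1)`; vectorised over any argument.
#' @examples
#' p_spatial(4, 512, detected_density(operating_conditions()))  # 0.1031
#' @export
p_spatial <- function(n_uc, a_aspad, d_det) {
  stopifnot(all(n_uc >= 0), all(a_aspad >= 0), all(d_det >= 0))
  1 - exp(-n_uc * (a_aspad / UM2_PER_MM2) * d_det)
}

#' Temporal pile-up probability at the OR-bus
#'
#' Monostable pulses of width `t_pulse` from the `n_spad * y / m_spl`
#' enabled SPADs of a subpixel merge on the wired-OR bus when they
#' overlap. With pulse arrivals at the window-averaged rate, the
#' probability that the bus is busy (so that one further pulse would be
#' absorbed rather than counted) is
#' `1 - exp(-n_spad * y * a_aspad * d_det * t_pulse / (m_spl * t_clk))`.
#'
#' @param n_spad Total SPADs in the pixel.
#' @param y SPAD yield fraction.
#' @param a_aspad SPAD active area, um^2.
#' @param d_det Detected photon density, photons/mm^2.
#' @param op An [operating_conditions()] (for `t_pulse` and `t_clk`).
#' @param m_spl Subpixels per pixel.
#' @return Probability in `[0, 1)`; vectorised over the numeric arguments.
#' @examples
#' op <- operating_conditions()
#' p_temporal(762, 0.77, 512, detected_density(op), op, 16)   # 0.0391
#' @export
p_temporal <- function(n_spad, y, a_aspad, d_det, op, m_spl) {
  stopifnot(inherits(op, "sipm_operating_conditions"),
            all(n_spad >= 0), all(y >= 0), all(y <= 1), all(a_aspad >= 0),
            all(d_det >= 0), all(m_spl >= 1))
  lam <- n_spad * y * (a_aspad / UM2_PER_MM2) * d_det *
    op$t_pulse / (m_spl * op$t_clk)
  1 - exp(-lam)
}

#' Sensitivity of an architecture and its decomposition
#'
#' Assembles the SPAD count and fill factor from the area budget, the
#' photon detection efficiency `PDE = PDP * FF`, both pile-up
#' probabilities at the peak detected density, and the sensitivity
#' `S = PDE * Y * (1 - Psp) * (1 - Ptp)` -- the marginal counted fraction
#' per incident photon at the operating point.
#'
#' @param arch An [architecture()].
#' @param budget An [area_budget()].
#' @param op An [operating_conditions()].
#' @param y SPAD yield fraction at `arch$a_aspad` (a number), or a yield
#'   model function of active area such as [parametric_yield_model()].
#' @return An object of class `sipm_sensitivity`: a list with elements
#'   `s`, `pde`, `ff`, `y`, `p_sp`, `p_tp`, `n_spad`, `arch`. Use
#'   [tidy()][generics::tidy] for a one-row tibble.
#' @examples
#' s <- sensitivity(architecture(4, 16, 512), area_budget(),
#'                  operating_conditions(), y = 0.77)
#' s$s        # 0.0777
#' tidy(s)
#' @export
sensitivity <- function(arch, budget, op, y) {
  stopifnot(inherits(arch, "sipm_architecture"),
            inherits(budget, "sipm_area_budget"),
            inherits(op, "sipm_operating_conditions"))
  if (is.function(y)) y <- y(arch$a_aspad)
  stopifnot(is.numeric(y), length(y) == 1L, y >= 0, y <= 1)
  n_spad <- spads_per_pixel(arch, budget)   # errors if infeasible
  ff <- fill_factor(n_spad, arch$a_aspad, budget$a_pxl / UM2_PER_MM2)
  pde <- op$pdp * ff
  d_det <- detected_density(op)
  psp <- p_spatial(arch$n_uc, arch$a_aspad, d_det)
  ptp <- p_temporal(n_spad, y, arch$a_aspad, d_det, op, arch$m_spl)
  structure(
    list(s = pde * y * (1 - psp) * (1 - ptp),
         pde = pde, ff = ff, y = y, p_sp = psp, p_tp = ptp,
         n_spad = n_spad, arch = arch),
    class = "sipm_sensitivity"
  )
}

#' @export
print.sipm_sensitivity <- function(x, ...) {
  cat(sprintf(
    paste0("<sipm_sensitivity> S = %.3f%%  (PDE %.3f%%, Y %.1f%%, ",
           "Psp %.2f%%, Ptp %.2f%%, Nspad %d)\n"),
    100 * x$s, 100 * x$pde, 100 * x$y, 100 * x$p_sp, 100 * x$p_tp,
    x$n_spad))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sensitivity decomposition
#'
#' @param x A `sipm_sensitivity` object.
#' @param ... Unused.
#' @return A one-row tibble with the design variables and every component
#'   of the sensitivity decomposition.
#' @exportS3Method generics::tidy
tidy.sipm_sensitivity <- function(x, ...) {
  tibble::tibble(
    n_uc = x$arch$n_uc, m_spl = x$arch$m_spl, a_aspad_um2 = x$arch$a_aspad,
    n_spad = x$n_spad, ff = x$ff, pde = x$pde, y = x$y,
    p_sp = x$p_sp, p_tp = x$p_tp, s = x$s
  )
}

#' @rdname tidy.sipm_sensitivity
#' @exportS3Method generics::glance
glance.sipm_sensitivity <- function(x, ...) {
  tibble::tibble(s = x$s, s_pct = 100 * x$s)
}

#' Pulse-compression constant of the counting response
#'
#' The dimensionless constant
#' `alpha = n_uc + n_spad * y * t_pulse / (m_spl * t_clk)` collects the
#' spatial and temporal compression of the architecture; the counted
#' photon response saturates at `n_spad * y / alpha`.
#'
#' @param arch An [architecture()] (for `n_uc` and `m_spl`).
#' @param n_spad Total SPADs in the pixel.
#' @param y SPAD yield fraction.
#' @param op An [operating_conditions()].
#' @return The compression constant (>= 1).
#' @examples
#' pulse_compression_alpha(architecture(4, 16, 512), 762, 0.77,
#'                         operating_conditions())   # 5.467
#' @export
pulse_compression_alpha <- function(arch, n_spad, y, op) {
  stopifnot(inherits(arch, "sipm_architecture"),
            inherits(op, "sipm_operating_conditions"),
            n_spad >= 0, y >= 0, y <= 1)
  arch$n_uc + n_spad * y * op$t_pulse / (arch$m_spl * op$t_clk)
}

#' Closed-form counted-photon response
#'
#' Integrating the marginal sensitivity over the incident photon count
#' gives the saturating response
#' `n_out = (n_spad * y / alpha) * (1 - exp(-alpha * pde * n_ph / n_spad))`:
#' linear with slope `pde * y` at small signals, concave, and saturating
#' at `n_spad * y / alpha` counted photons.
#'
#' @param n_ph Incident photons on the pixel (vectorised).
#' @param pde Photon detection efficiency (PDP times fill factor).
#' @param n_spad Total SPADs in the pixel.
#' @param y SPAD yield fraction.
#' @param alpha Compression constant, see [pulse_compression_alpha()].
#' @return Expected counted photons for each `n_ph`.
#' @examples
#' counted_photons(450, pde = 0.1170, n_spad = 762, y = 0.77,
#'                 alpha = 5.467)   # ~33.8
#' @export
counted_photons <- function(n_ph, pde, n_spad, y, alpha) {
  stopifnot(all(n_ph >= 0), pde >= 0, pde <= 1, n_spad > 0,
            y >= 0, y <= 1, alpha > 0)
  (n_spad * y / alpha) * (1 - exp(-alpha * pde * n_ph / n_spad))
}

#' Counted-photon response curve of an architecture
#'
#' Evaluates the closed-form response of a feasible architecture over a
#' log-spaced grid of incident photon counts.
#'
#' @inheritParams sensitivity
#' @param n_ph Incident photon grid; default 60 log-spaced points in
#'   `[1, 5000]`.
#' @return A tibble with columns `n_ph`, `n_out`, plus the constants
#'   `pde`, `y`, `alpha`, `n_spad` as attributes `"params"`.
#' @examples
#' rc <- response_curve(architecture(4, 16, 512), area_budget(),
#'                      operating_conditions(), y = 0.77)
#' head(rc)
#' @export
response_curve <- function(arch, budget, op, y,
                           n_ph = round(exp(seq(log(1), log(5000),
                                                length.out = 60)))) {
  sens <- sensitivity(arch, budget, op, y)
  alpha <- pulse_compression_alpha(arch, sens$n_spad, sens$y, op)
  out <- tibble::tibble(
    n_ph = as.numeric(n_ph),
    n_out = counted_photons(n_ph, sens$pde, sens$n_spad, sens$y, alpha)
  )
  attr(out, "params") <- list(pde = sens$pde, y = sens$y, alpha = alpha,
                              n_spad = sens$n_spad)
  out
}
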