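# Design-space optimization: the optimal SPAD active area per
# (n_uc, m_spl) cell, the full sweep over the design space, and the
# per-pixel-size summary report.

# Sensitivity as a function of active area for one cell; -Inf where the
# cell cannot host a single SPAD, NA if the overhead exceeds the pixel.
s_of_area <- function(a, n_uc, m_spl, budget, op, yield_model, d_det) {
  vapply(a, function(aa) {
    n_spad <- spads_per_pixel(architecture(n_uc, m_spl, aa), budget,
                              strict = FALSE)
    if (is.na(n_spad)) return(NA_real_)
    if (n_spad < 1) return(-Inf)
    ff <- n_spad * aa / budget$a_pxl
    if (ff >= 1) return(-Inf)
    y <- yield_model(aa)
    pde <- op$pdp * ff
    pde * y * (1 - p_spatial(n_uc, aa, d_det)) *
      (1 - p_temporal(n_spad, y, aa, d_det, op, m_spl))
  }, numeric(1))
}

#' Optimal SPAD active area for one (n_uc, m_spl) cell
#'
#' Maximizes the sensitivity over the SPAD active area at fixed microcell
#' and subpixel organisation. The stationarity condition is
#' transcendental, so the maximum is located numerically: a coarse
#' log-spaced scan (at least 64 points) brackets the maximum -- valid
#' because the sensitivity is unimodal in the active area -- and the
#' bracketing interval is rescanned at the same resolution until the
#' requested relative tolerance is met. The iterated rescan (rather than
#' a golden-section step) is robust to the small plateaus and jumps that
#' the integer SPAD count imprints on the objective, on which bisection
#' rules can stall.
#'
#' @param n_uc,m_spl The cell's SPADs per microcell and subpixels per
#'   pixel.
#' @param budget An [area_budget()].
#' @param op An [operating_conditions()].
#' @param yield_model Function of active area (um^2) returning a yield
#'   fraction, e.g. [parametric_yield_model()].
#' @param bounds Search interval for the active area, um^2.
#' @param n_scan Number of log-spaced scan points (>= 64).
#' @param rel_tol Relative tolerance on the optimal area.
#' @return A list with `feasible` (logical), `a_opt` (um^2 or `NA`) and
#'   `sens` (a [sensitivity()] result at the optimum, or `NULL`).
#' @examples
#' optimize_active_area(4, 16, area_budget(), operating_conditions(),
#'                      parametric_yield_model())$a_opt
#' @export
optimize_active_area <- function(n_uc, m_spl, budget, op, yield_model,
                                 bounds = c(50, 5000), n_scan = 96,
                                 rel_tol = 1e-3) {
  stopifnot(inherits(budget, "sipm_area_budget"),
            inherits(op, "sipm_operating_conditions"),
            is.function(yield_model), length(bounds) == 2L,
            all(is.finite(bounds)), all(bounds > 0),
            bounds[1] < bounds[2], n_scan >= 64)
  d_det <- detected_density(op)
  f <- function(a) s_of_area(a, n_uc, m_spl, budget, op, yield_model, d_det)
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_scan))
  s <- f(grid)
  if (all(is.na(s)) || all(!is.finite(s))) {
    return(list(feasible = FALSE, a_opt = NA_real_, sens = NULL))
  }
  # iterated rescan of the bracketing interval: each stage shrinks the
  # interval by ~(n_scan - 1) / 2, immune to the floor-step plateaus
  for (stage in 1:8) {
    i <- which.max(s)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    if ((hi - lo) <= rel_tol * lo) break
    grid <- exp(seq(log(lo), log(hi), length.out = n_scan))
    s <- f(grid)
  }
  a_opt <- grid[which.max(s)]
  if (!is.finite(f(a_opt))) {   # degenerate cell: no area hosts a SPAD
    return(list(feasible = FALSE, a_opt = NA_real_, sens = NULL))
  }
  sens <- sensitivity(architecture(n_uc, m_spl, a_opt), budget, op,
                      y = yield_model)
  list(feasible = TRUE, a_opt = a_opt, sens = sens)
}

#' Sweep the architecture design space
#'
#' Runs [optimize_active_area()] for every (n_uc, m_spl) cell of the
#' design space and collects the per-cell optima. The sensitivity surface
#' has a broad plateau, so a bare argmax is unstable: cells within
#' `tie_tol_pp` percentage points of the maximum are treated as ties and
#' the reported best cell is the tied cell with the smallest `m_spl`,
#' then the smallest `n_uc`.
#'
#' @param space A [design_space()].
#' @param budget An [area_budget()].
#' @param op An [operating_conditions()].
#' @param yield_model Function of active area returning a yield fraction.
#' @param tie_tol_pp Plateau tie tolerance, percentage points.
#' @return A tibble of class `sipm_design_sweep` with one row per cell
#'   (`n_uc`, `m_spl`, `feasible`, `a_opt_um2`, `s_opt`, `n_spad`, `ff`,
#'   `y`, `p_sp`, `p_tp`) and attributes `best` (the reported best row),
#'   `near_optimal` (all tied rows) and `s_max`.
#' @examples
#' sw <- sweep_design_space(design_space(n_uc_values = 1:4,
#'                                       m_spl_values = c(8, 16, 32)),
#'                          area_budget(), operating_conditions(),
#'                          parametric_yield_model())
#' glance(sw)
#' @export
sweep_design_space <- function(space, budget, op, yield_model,
                               tie_tol_pp = 0.05) {
  stopifnot(inherits(space, "sipm_design_space"))
  cells <- tidyr::expand_grid(m_spl = space$m_spl_values,
                              n_uc = space$n_uc_values)
  rows <- purrr::pmap_dfr(cells, function(m_spl, n_uc) {
    opt <- optimize_active_area(n_uc, m_spl, budget, op, yield_model,
                                bounds = space$a_aspad_bounds)
    if (!opt$feasible) {
      return(tibble::tibble(
        n_uc = n_uc, m_spl = m_spl, feasible = FALSE,
        a_opt_um2 = NA_real_, s_opt = NA_real_, n_spad = NA_integer_,
        ff = NA_real_, y = NA_real_, p_sp = NA_real_, p_tp = NA_real_))
    }
    s <- opt$sens
    tibble::tibble(
      n_uc = n_uc, m_spl = m_spl, feasible = TRUE,
      a_opt_um2 = opt$a_opt, s_opt = s$s, n_spad = s$n_spad,
      ff = s$ff, y = s$y, p_sp = s$p_sp, p_tp = s$p_tp)
  })
  s_max <- max(rows$s_opt, na.rm = TRUE)
  near <- dplyr::filter(rows, .data$feasible,
                        .data$s_opt >= s_max - tie_tol_pp / 100)
  near <- dplyr::arrange(near, .data$m_spl, .data$n_uc)
  attr(rows, "s_max") <- s_max
  attr(rows, "near_optimal") <- near
  attr(rows, "best") <- near[1, ]
  attr(rows, "tie_tol_pp") <- tie_tol_pp
  class(rows) <- c("sipm_design_sweep", class(rows))
  rows
}

#' @export
print.sipm_design_sweep <- function(x, ...) {
  b <- attr(x, "best")
  cat(sprintf(
    paste0("<sipm_design_sweep> %d cells, S_max = %.3f%%; best cell ",
           "n_uc=%d m_spl=%d (a* = %.0f um^2; %d cells within %.2f pp)\n"),
    nrow(x), 100 * attr(x, "s_max"), b$n_uc, b$m_spl, b$a_opt_um2,
    nrow(attr(x, "near_optimal")), attr(x, "tie_tol_pp")))
  NextMethod()
}

#' Tidy and summarise a design-space sweep
#'
#' `tidy()` returns the per-cell table; `glance()` a one-row summary of
#' the reported best cell.
#'
#' @param x A `sipm_design_sweep`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sipm_design_sweep <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sipm_design_sweep")
  attr(out, "best") <- attr(out, "near_optimal") <- NULL
  attr(out, "s_max") <- attr(out, "tie_tol_pp") <- NULL
  out
}

#' @rdname tidy.sipm_design_sweep
#' @exportS3Method generics::glance
glance.sipm_design_sweep <- function(x, ...) {
  b <- attr(x, "best")
  tibble::tibble(
    n_uc = b$n_uc, m_spl = b$m_spl, a_opt_um2 = b$a_opt_um2,
    s_opt = b$s_opt, s_max = attr(x, "s_max"),
    n_near_optimal = nrow(attr(x, "near_optimal")))
}

#' Optimized-architecture report across pixel sizes
#'
#' Sweeps the design space for each pixel area and reports the best cell
#' and its sensitivity decomposition, one row per pixel size.
#'
#' @param pixel_areas Pixel areas to optimize, mm^2.
#' @param space A [design_space()].
#' @param budget An [area_budget()]; its `a_pxl` is replaced by each
#'   entry of `pixel_areas` in turn.
#' @param op An [operating_conditions()].
#' @param yield_model Function of active area returning a yield fraction.
#' @param tie_tol_pp Plateau tie tolerance, percentage points.
#' @return A tibble with one row per pixel area: `a_pxl_mm2`, `n_uc`,
#'   `m_spl`, `s`, `a_aspad_um2`, `ff`, `y`, `n_spad`.
#' @examples
#' \donttest{
#' architecture_report(c(1, 2.25), design_space(), area_budget(),
#'                     operating_conditions(), parametric_yield_model())
#' }
#' @export
architecture_report <- function(pixel_areas, space, budget, op, yield_model,
                                tie_tol_pp = 0.05) {
  purrr::map_dfr(pixel_areas, function(apx) {
    b <- budget
    b$a_pxl <- apx * UM2_PER_MM2
    sw <- sweep_design_space(space, b, op, yield_model,
                             tie_tol_pp = tie_tol_pp)
    best <- attr(sw, "best")
    tibble::tibble(
      a_pxl_mm2 = apx, n_uc = best$n_uc, m_spl = best$m_spl,
      s = best$s_opt, a_aspad_um2 = best$a_opt_um2, ff = best$ff,
      y = best$y, n_spad = best$n_spad)
  })
}
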