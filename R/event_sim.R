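# Discrete-event Monte-Carlo: a brute-force subpixel simulator that serves
# as an independent oracle for the analytic pile-up and counting formulas,
# and a simplified scintillation-spread simulator for first-photon
# pixel-multiplicity studies.

# Rising edges of the wired-OR of pulses [t, t + t_pulse) starting at
# `starts`: a start is an edge iff the bus is low, i.e. no start within
# the preceding pulse width.
or_bus_edges <- function(starts, t_pulse) {
  if (length(starts) == 0L) return(0L)
  s <- sort(starts)
  1L + sum(diff(s) >= t_pulse)
}

# Occupied time of the pulse union restricted to [from, to].
or_bus_occupancy <- function(starts, t_pulse, from, to) {
  if (length(starts) == 0L) return(0)
  lo <- pmax(sort(starts), from)
  hi <- pmin(sort(starts) + t_pulse, to)
  keep <- hi > lo
  if (!any(keep)) return(0)
  lo <- lo[keep]; hi <- hi[keep]
  occ <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      occ <- occ + cur_hi - cur_lo
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  occ + cur_hi - cur_lo
}

#' Discrete-event simulation of one subpixel window
#'
#' Brute-force model of the subpixel circuit over one clock window. The
#' subpixel holds `n_spad_in_subpixel * y` enabled SPADs regrouped into
#' full microcells of `n_uc`; each incident photon is thinned by the PDP,
#' assigned to a microcell uniformly, and triggers the microcell's
#' monostable unless the microcell has already fired in this window
#' (spatial pile-up; the SPAD dead time far exceeds the window). Each
#' trigger places a `t_pulse`-wide pulse on the OR-bus and the counter
#' registers the rising edges of the bus, so overlapping pulses merge
#' (temporal pile-up).
#'
#' The returned empirical pile-up probabilities are *marginal* estimators,
#' matching the differential definition of the sensitivity: `p_sp` is the
#' fraction of microcells already fired (the probability that one further
#' photon would find its microcell busy) and `p_tp` the OR-bus occupancy
#' over the stationary part of the window `[t_pulse, t_clk]` (the
#' probability that one further pulse would be absorbed). Under Poisson
#' illumination at the operating density they converge exactly to the
#' analytic [p_spatial()] and [p_temporal()].
#'
#' @param arch An [architecture()] (for `n_uc`; `m_spl` is not used at
#'   subpixel level).
#' @param n_spad_in_subpixel Physical SPADs in the subpixel.
#' @param y Yield fraction; `round(y * n_spad_in_subpixel)` SPADs are
#'   enabled.
#' @param photon_times Arrival times (s) of photons impinging on the
#'   enabled active area of the subpixel. Times outside `[0, t_clk]` are
#'   rejected and counted in `n_rejected` with a warning.
#' @param op An [operating_conditions()].
#' @param seed Optional integer seed.
#' @return A list: `counted` (rising edges), `p_sp`, `p_tp` (empirical
#'   marginal pile-up), `n_detected`, `n_triggers`, `n_microcells`,
#'   `occupancy_time` (s), `n_rejected`.
#' @examples
#' op <- operating_conditions()
#' simulate_subpixel(architecture(4, 16, 512), 48, 1,
#'                   photon_times = c(1e-9, 5e-9), op, seed = 1)$counted
#' @export
simulate_subpixel <- function(arch, n_spad_in_subpixel, y, photon_times,
                              op, seed = NULL) {
  stopifnot(inherits(arch, "sipm_architecture"),
            inherits(op, "sipm_operating_conditions"),
            n_spad_in_subpixel >= 1, y >= 0, y <= 1)
  n_en <- round(y * n_spad_in_subpixel)
  n_mc <- max(1L, floor(n_en / arch$n_uc))
  ok <- photon_times >= 0 & photon_times <= op$t_clk
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(n_rejected, " photon(s) outside [0, t_clk] rejected",
            call. = FALSE)
  }
  t <- photon_times[ok]
  with_seed_if(seed, {
    det <- stats::runif(length(t)) < op$pdp
    t <- t[det]
    mc <- if (length(t)) sample.int(n_mc, length(t), replace = TRUE)
          else integer(0)
    o <- order(t)
    first <- !duplicated(mc[o])
    starts <- t[o][first]
    occ <- or_bus_occupancy(starts, op$t_pulse, op$t_pulse, op$t_clk)
    list(
      counted = or_bus_edges(starts, op$t_pulse),
      p_sp = length(starts) / n_mc,
      p_tp = occ / (op$t_clk - op$t_pulse),
      n_detected = length(t),
      n_triggers = length(starts),
      n_microcells = n_mc,
      occupancy_time = occ,
      n_rejected = n_rejected
    )
  })
}

#' Replicated subpixel simulation at the operating illumination
#'
#' Drives [simulate_subpixel()] with Poisson illumination at a chosen
#' incident density (by default the operating-point density `d_ph`
#' accumulated over the build-up window, i.e. the detected density of
#' [detected_density()] before PDP thinning), with arrival times uniform
#' over the window as assumed by the window-averaged temporal pile-up
#' model. Aggregates the marginal pile-up estimators over replicates.
#'
#' @param arch An [architecture()].
#' @param budget An [area_budget()] (for the SPAD count).
#' @param op An [operating_conditions()].
#' @param y Yield fraction.
#' @param replicates Number of independent windows.
#' @param d_ph Incident photon density accumulated over the window,
#'   photons/mm^2. Defaults to the build-up-window value
#'   `op$d_ph * (1 - exp(-t_clk / tau_sct))`.
#' @param seed Optional integer seed.
#' @return A one-row tibble: empirical `p_sp` and `p_tp` with binomial
#'   standard errors (`p_sp_se`, `p_tp_se`), mean `counted` per window,
#'   `n_microcells`, `replicates`.
#' @examples
#' \donttest{
#' simulate_subpixel_ensemble(architecture(4, 16, 512), area_budget(),
#'                            operating_conditions(), y = 0.77,
#'                            replicates = 500, seed = 1)
#' }
#' @export
simulate_subpixel_ensemble <- function(arch, budget, op, y,
                                       replicates = 1e4,
                                       d_ph = op$d_ph *
                                         (1 - exp(-op$t_clk / op$tau_sct)),
                                       seed = NULL) {
  stopifnot(replicates >= 1)
  n_spad <- spads_per_pixel(arch, budget)
  n_sub <- n_spad / arch$m_spl
  n_en <- round(y * n_sub)
  n_mc <- max(1L, floor(n_en / arch$n_uc))
  # incident photons on the enabled active area of one subpixel
  lam <- d_ph * (n_mc * arch$n_uc * arch$a_aspad / UM2_PER_MM2)
  with_seed_if(seed, {
    occ_mc <- 0; tot_mc <- 0; occ_t <- 0; counted <- 0
    for (r in seq_len(replicates)) {
      n <- stats::rpois(1, lam)
      t <- stats::runif(n, 0, op$t_clk)
      det <- t[stats::runif(n) < op$pdp]
      mc <- if (length(det)) sample.int(n_mc, length(det), replace = TRUE)
            else integer(0)
      o <- order(det)
      starts <- det[o][!duplicated(mc[o])]
      occ_mc <- occ_mc + length(starts)
      tot_mc <- tot_mc + n_mc
      occ_t <- occ_t + or_bus_occupancy(starts, op$t_pulse, op$t_pulse,
                                        op$t_clk)
      counted <- counted + or_bus_edges(starts, op$t_pulse)
    }
    p_sp <- occ_mc / tot_mc
    p_tp <- occ_t / (replicates * (op$t_clk - op$t_pulse))
    tibble::tibble(
      p_sp = p_sp,
      p_sp_se = sqrt(p_sp * (1 - p_sp) / tot_mc),
      p_tp = p_tp,
      p_tp_se = sqrt(p_tp * (1 - p_tp) / replicates),
      counted = counted / replicates,
      n_microcells = n_mc,
      replicates = replicates
    )
  })
}

#' Monte-Carlo mean counted photons per scintillation event
#'
#' Full-pixel discrete-event response: per replicate, each of the `n_ph`
#' incident photons is detected with probability `PDE * Y`, receives an
#' exponential scintillation arrival time with constant `tau_sct`, and is
#' routed to a uniformly chosen microcell of a uniformly chosen subpixel;
#' microcells fire once per event (the SPAD dead time exceeds the event)
#' and each subpixel counts the rising edges of its OR-bus. The mean over
#' replicates estimates the counted-photon response; it matches the
#' closed-form [counted_photons()] in the linear and moderate-saturation
#' regimes and runs a few percent above it near saturation, where the
#' closed form evaluates temporal pile-up at the window-averaged rather
#' than the instantaneous scintillation rate.
#'
#' @param n_ph Incident photon counts (vectorised).
#' @param arch An [architecture()].
#' @param budget An [area_budget()].
#' @param op An [operating_conditions()].
#' @param y Yield fraction.
#' @param replicates Events per `n_ph` value.
#' @param seed Optional integer seed.
#' @return A tibble with one row per `n_ph`: `n_ph`, `n_out` (MC mean),
#'   `se` (standard error), `n_out_closed_form`, `replicates`.
#' @examples
#' \donttest{
#' simulate_event_response(c(5, 50), architecture(4, 16, 512),
#'                         area_budget(), operating_conditions(),
#'                         y = 0.77, replicates = 200, seed = 1)
#' }
#' @export
simulate_event_response <- function(n_ph, arch, budget, op, y,
                                    replicates = 1000, seed = NULL) {
  stopifnot(replicates >= 1, all(n_ph >= 0))
  sens <- sensitivity(arch, budget, op, y)
  alpha <- pulse_compression_alpha(arch, sens$n_spad, sens$y, op)
  n_mc_tot <- max(1L, round(sens$n_spad * sens$y / arch$n_uc))
  # enabled microcells spread as evenly as possible over the subpixels
  per_spl <- rep(n_mc_tot %/% arch$m_spl, arch$m_spl)
  extra <- n_mc_tot - sum(per_spl)
  if (extra > 0) per_spl[seq_len(extra)] <- per_spl[seq_len(extra)] + 1L
  p_det <- sens$pde * sens$y
  with_seed_if(seed, {
    purrr::map_dfr(n_ph, function(np) {
      counts <- vapply(seq_len(replicates), function(r) {
        n_det <- stats::rbinom(1, np, p_det)
        if (n_det == 0L) return(0L)
        t <- stats::rexp(n_det, 1 / op$tau_sct)
        spl <- sample.int(arch$m_spl, n_det, replace = TRUE,
                          prob = per_spl / n_mc_tot)
        cnt <- 0L
        for (s in unique(spl)) {
          ts <- t[spl == s]
          mc <- sample.int(per_spl[s], length(ts), replace = TRUE)
          o <- order(ts)
          starts <- ts[o][!duplicated(mc[o])]
          cnt <- cnt + or_bus_edges(starts, op$t_pulse)
        }
        cnt
      }, integer(1))
      tibble::tibble(
        n_ph = np, n_out = mean(counts),
        se = stats::sd(counts) / sqrt(replicates),
        n_out_closed_form = counted_photons(np, sens$pde, sens$n_spad,
                                            sens$y, alpha),
        replicates = replicates)
    })
  })
}

#' Calibrated light yield of the simplified scintillation model
#'
#' The spread simulator transports photons along straight lines from the
#' interaction vertex to the detector plane (no reflection or refraction),
#' so its light yield is a free scale. It is fixed so that an interaction
#' at the typical height `h = crystal_thickness - attenuation_length`
#' above the plane produces a peak incident density of `d_ph` photons/mm^2
#' directly below the vertex: `N = d_ph * 2 * pi * h^2`. Neither the
#' straight-line transport nor this scale is a measured property of any
#' crystal; they reproduce the operating-point photon density only.
#'
#' @param d_ph Target peak photon density, photons/mm^2.
#' @param crystal_thickness Crystal thickness, mm.
#' @param attenuation_length 511 keV attenuation length, mm.
#' @return Photons emitted into the lower hemisphere per event.
#' @export
calibrate_light_yield <- function(d_ph = 450, crystal_thickness = 20,
                                  attenuation_length = 12) {
  stopifnot(crystal_thickness > attenuation_length)
  d_ph * 2 * pi * (crystal_thickness - attenuation_length)^2
}

# Simulate one event's detected photons: returns pixel index (row, col)
# and arrival time per detected photon, plus per-pixel impinging counts.
# Geometry: crystal face [0, Lx] x [0, Ly], detector plane at z = 0,
# vertex at (x0, y0, h); photons isotropic into the lower hemisphere.
project_event <- function(n_photons, x0, y0, h, lx, ly, pixel_size,
                          det_prob) {
  # detection is uniform thinning, independent of geometry: thin first
  n_det <- stats::rbinom(1, n_photons, det_prob)
  n_imp <- n_photons
  sample_hits <- function(n) {
    if (n == 0L) {
      return(tibble::tibble(x = numeric(0), y = numeric(0)))
    }
    cost <- stats::runif(n)            # isotropic: cos(theta) ~ U(0,1)
    phi <- stats::runif(n, 0, 2 * pi)
    r <- h * sqrt(1 - cost^2) / cost   # h * tan(theta)
    x <- x0 + r * cos(phi)
    y <- y0 + r * sin(phi)
    keep <- x >= 0 & x < lx & y >= 0 & y < ly
    tibble::tibble(x = x[keep], y = y[keep])
  }
  hits <- sample_hits(n_det)
  tibble::tibble(
    row = as.integer(hits$y %/% pixel_size) + 1L,
    col = as.integer(hits$x %/% pixel_size) + 1L
  )
}

#' Per-pixel hit record of a single scintillation event
#'
#' Simulates one gamma interaction and tabulates, per pixel of the
#' readout array, the photons impinging on the pixel, the photons
#' detected after uniform thinning with probability `det_prob`, and the
#' first detection time.
#'
#' @param crystal Crystal dimensions `c(x, y, thickness)`, mm.
#' @param pixel_size Pixel pitch, mm; must divide the crystal face.
#' @param depth Interaction height above the detector plane, mm.
#' @param n_photons Photons emitted into the lower hemisphere.
#' @param det_prob Per-photon detection probability (PDE times yield for
#'   the first-photon regime).
#' @param tau_sct Scintillator decay constant, s.
#' @param xy Transverse interaction position, mm; default face centre.
#' @param seed Optional integer seed.
#' @return A tibble with one row per hit pixel: `row`, `col`,
#'   `impinging`, `detected`, `t_first` (s, `NA` if none detected).
#' @examples
#' simulate_scintillation_event(n_photons = 2000, det_prob = 1, seed = 1)
#' @export
simulate_scintillation_event <- function(crystal = c(50, 50, 20),
                                         pixel_size = 1,
                                         depth = 8,
                                         n_photons = 20000,
                                         det_prob = 1,
                                         tau_sct = 40e-9,
                                         xy = crystal[1:2] / 2,
                                         seed = NULL) {
  check_pixelisation(crystal, pixel_size)
  stopifnot(depth > 0, depth <= crystal[3], det_prob >= 0, det_prob <= 1)
  with_seed_if(seed, {
    # impinging = all photons reaching the face (no thinning)
    cost <- stats::runif(n_photons)
    phi <- stats::runif(n_photons, 0, 2 * pi)
    r <- depth * sqrt(1 - cost^2) / cost
    x <- xy[1] + r * cos(phi)
    y <- xy[2] + r * sin(phi)
    keep <- x >= 0 & x < crystal[1] & y >= 0 & y < crystal[2]
    px <- tibble::tibble(
      row = as.integer(y[keep] %/% pixel_size) + 1L,
      col = as.integer(x[keep] %/% pixel_size) + 1L,
      detected = stats::runif(sum(keep)) < det_prob,
      t = stats::rexp(sum(keep), 1 / tau_sct)
    )
    out <- dplyr::summarise(
      dplyr::group_by(px, .data$row, .data$col),
      impinging = dplyr::n(),
      detected = sum(.data$detected),
      t_first = ifelse(any(.data$detected),
                       min(.data$t[.data$detected]), NA_real_),
      .groups = "drop")
    dplyr::arrange(out, .data$row, .data$col)
  })
}

check_pixelisation <- function(crystal, pixel_size) {
  stopifnot(length(crystal) == 3L, all(crystal > 0), pixel_size > 0)
  nx <- crystal[1] / pixel_size
  ny <- crystal[2] / pixel_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("pixel_size must divide the crystal face exactly", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pixel multiplicity of the first detected photons
#'
#' For timestamp-driven PET, the timing information is carried by the
#' first ~10 detected photons, and per-pixel TDCs exploit them only if
#' they land on *different* pixels. This simulator measures the
#' distribution of the number of distinct pixels receiving the first
#' `n_first` detections: per event, the interaction depth is sampled
#' (exponential penetration from the entrance face with the 511 keV
#' attenuation length, truncated to the crystal, or a fixed depth),
#' photons are emitted isotropically into the lower hemisphere, projected
#' along straight lines onto the readout plane, thinned by the per-photon
#' detection probability, and time-ordered with exponential scintillation
#' arrival times.
#'
#' @param crystal Crystal dimensions `c(x, y, thickness)`, mm.
#' @param pixel_size Pixel pitch, mm; must divide the crystal face.
#' @param n_first Number of first detections examined.
#' @param det_prob Per-photon detection probability; use `pde * y` for a
#'   real architecture (first photons are in the linear regime) or 1 for
#'   the ideal-sensor study.
#' @param n_events Number of simulated events.
#' @param depth_model `"exponential"` (penetration from the entrance
#'   face, truncated) or `"fixed"` (all events at `fixed_depth`).
#' @param attenuation_length 511 keV attenuation length in the crystal,
#'   mm (LYSO-like default; not a fitted value).
#' @param fixed_depth Height of the interaction above the detector plane
#'   for `depth_model = "fixed"`, mm.
#' @param light_yield Photons per event into the lower hemisphere;
#'   default [calibrate_light_yield()].
#' @param tau_sct Scintillator decay constant, s.
#' @param seed Optional integer seed.
#' @return An object of class `sipm_multiplicity`: list with `histogram`
#'   (tibble `multiplicity`, `probability` over `1:n_first`, normalised
#'   over events with at least one detection), `events` (per-event tibble
#'   with `depth`, `n_detected`, `multiplicity`), `n_excluded` (events
#'   with zero detections) and `params`.
#' @examples
#' \donttest{
#' m <- simulate_first_n_multiplicity(n_events = 50, light_yield = 5000,
#'                                    det_prob = 0.08, seed = 1)
#' m$histogram
#' }
#' @export
simulate_first_n_multiplicity <- function(crystal = c(50, 50, 20),
                                          pixel_size = 1,
                                          n_first = 10,
                                          det_prob = 1,
                                          n_events = 1000,
                                          depth_model = c("exponential",
                                                          "fixed"),
                                          attenuation_length = 12,
                                          fixed_depth = NULL,
                                          light_yield =
                                            calibrate_light_yield(),
                                          tau_sct = 40e-9,
                                          seed = NULL) {
  check_pixelisation(crystal, pixel_size)
  depth_model <- match.arg(depth_model)
  stopifnot(n_first >= 1, n_events >= 1, det_prob >= 0, det_prob <= 1,
            light_yield >= 1)
  if (depth_model == "fixed") {
    stopifnot(!is.null(fixed_depth), fixed_depth > 0,
              fixed_depth <= crystal[3])
  }
  x0 <- crystal[1] / 2
  y0 <- crystal[2] / 2
  with_seed_if(seed, {
    depths <- if (depth_model == "fixed") {
      rep(fixed_depth, n_events)
    } else {
      # penetration from the entrance (top) face, truncated to the crystal
      pen <- stats::rexp(n_events, 1 / attenuation_length)
      crystal[3] - pmin(pen, crystal[3] * (1 - 1e-9))
    }
    ev <- purrr::map_dfr(seq_len(n_events), function(i) {
      hits <- project_event(stats::rpois(1, light_yield), x0, y0,
                            depths[i], crystal[1], crystal[2],
                            pixel_size, det_prob)
      n_det <- nrow(hits)
      if (n_det == 0L) {
        return(tibble::tibble(event = i, depth = depths[i],
                              n_detected = 0L,
                              multiplicity = NA_integer_))
      }
      t <- stats::rexp(n_det, 1 / tau_sct)
      first <- order(t)[seq_len(min(n_first, n_det))]
      mult <- nrow(dplyr::distinct(hits[first, c("row", "col")]))
      tibble::tibble(event = i, depth = depths[i], n_detected = n_det,
                     multiplicity = as.integer(mult))
    })
    included <- dplyr::filter(ev, .data$n_detected > 0L)
    counts <- tabulate(included$multiplicity, nbins = n_first)
    hist <- tibble::tibble(
      multiplicity = seq_len(n_first),
      probability = if (nrow(included)) counts / nrow(included)
                    else rep(NA_real_, n_first))
    structure(
      list(histogram = hist, events = ev,
           n_excluded = sum(ev$n_detected == 0L),
           params = list(crystal = crystal, pixel_size = pixel_size,
                         n_first = n_first, det_prob = det_prob,
                         n_events = n_events, depth_model = depth_model,
                         attenuation_length = attenuation_length,
                         fixed_depth = fixed_depth,
                         light_yield = light_yield, tau_sct = tau_sct,
                         seed = seed)),
      class = "sipm_multiplicity")
  })
}

#' @export
print.sipm_multiplicity <- function(x, ...) {
  p <- x$params
  mean_mult <- sum(x$histogram$multiplicity * x$histogram$probability)
  cat(sprintf(
    paste0("<sipm_multiplicity> %g mm pixels, first %d photons, %d ",
           "events (%d excluded): mean multiplicity %.2f\n"),
    p$pixel_size, p$n_first, p$n_events, x$n_excluded, mean_mult))
  print(x$histogram)
  invisible(x)
}
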