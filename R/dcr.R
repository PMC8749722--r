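# Dark-count-rate populations: synthetic generation, composition of larger
# SPADs from measured smaller ones, defect classification, and yield versus
# active area.

#' Construct a per-SPAD dark-count-rate population
#'
#' A DCR population is a tibble with one row per SPAD and a `rate_hz`
#' column, carrying the active area of the measured SPADs and free-form
#' measurement metadata (bias, dead time, generator seed) as attributes.
#'
#' @param rates Per-SPAD dark count rates, Hz. All must be non-negative.
#' @param a_aspad Active area of the measured SPADs, um^2.
#' @param meta Named list of annotations (e.g. `excess_bias_v`,
#'   `dead_time_s`, `seed`).
#' @return A tibble of class `sipm_dcr_population`.
#' @seealso [generate_dcr_population()], [compose_dcr()],
#'   [classify_defective()]
#' @export
dcr_population <- function(rates, a_aspad, meta = list()) {
  stopifnot(is.numeric(rates), length(rates) >= 1L, all(is.finite(rates)),
            all(rates >= 0), is.numeric(a_aspad), length(a_aspad) == 1L,
            a_aspad > 0, is.list(meta))
  out <- tibble::tibble(rate_hz = as.numeric(rates))
  attr(out, "a_aspad") <- a_aspad
  attr(out, "meta") <- meta
  class(out) <- c("sipm_dcr_population", class(out))
  out
}

#' @export
print.sipm_dcr_population <- function(x, ...) {
  cat(sprintf(
    "<sipm_dcr_population> n=%d SPADs at %.4g um^2, median DCR %.4g Hz\n",
    nrow(x), attr(x, "a_aspad"), stats::median(x$rate_hz)))
  NextMethod()
}

#' Generate a synthetic per-SPAD DCR population
#'
#' Emulates the measured DCR distribution of a CMOS SPAD array: a
#' log-normal "plateau" of healthy SPADs (essentially all below 100 Hz for
#' the default 50 Hz median) and a heavy defective tail orders of magnitude
#' above it, drawn log-uniformly over `[defect_scale, 100 * defect_scale]`.
#' Sorted by rate, the population shows a flat plateau followed by an
#' abrupt rise at the defective fraction.
#'
#' @param n Number of SPADs.
#' @param a_aspad Active area of the generated SPADs, um^2.
#' @param defective_fraction Expected fraction of defective SPADs in
#'   `[0, 1)`. Each SPAD is defective independently with this probability.
#' @param plateau_median Median of the healthy log-normal plateau, Hz.
#' @param plateau_sdlog Log-sd of the plateau; the default 0.25 keeps
#'   ~99.7% of healthy SPADs below twice the median.
#' @param defect_scale Lower edge of the defective band, Hz. Must exceed
#'   `plateau_median`; default 100x the plateau median.
#' @param seed Optional integer seed; the draw is reproducible given the
#'   seed, which is recorded in the population metadata.
#' @return A [dcr_population()].
#' @examples
#' pop <- generate_dcr_population(seed = 1)
#' mean(pop$rate_hz > 100 * stats::median(pop$rate_hz))  # ~0.10
#' @export
generate_dcr_population <- function(n = 2000,
                                    a_aspad = 200,
                                    defective_fraction = 0.10,
                                    plateau_median = 50,
                                    plateau_sdlog = 0.25,
                                    defect_scale = 100 * plateau_median,
                                    seed = NULL) {
  stopifnot(n >= 1, defective_fraction >= 0, defective_fraction < 1,
            plateau_median > 0, plateau_sdlog > 0)
  if (defect_scale <= plateau_median) {
    stop("invalid mixture: defect_scale must exceed plateau_median",
         call. = FALSE)
  }
  rates <- with_seed_if(seed, {
    defective <- stats::runif(n) < defective_fraction
    r <- stats::rlnorm(n, meanlog = log(plateau_median),
                       sdlog = plateau_sdlog)
    n_def <- sum(defective)
    if (n_def > 0) {
      r[defective] <- exp(stats::runif(n_def, log(defect_scale),
                                       log(100 * defect_scale)))
    }
    r
  })
  dcr_population(rates, a_aspad,
                 meta = list(seed = seed,
                             defective_fraction = defective_fraction,
                             plateau_median = plateau_median,
                             defect_scale = defect_scale))
}

#' Estimate the DCR of larger SPADs composed of measured smaller ones
#'
#' A SPAD with `m` times the measured active area is treated as the union
#' of `m` randomly selected measured SPADs (defects are assumed randomly
#' distributed over the array). For each of the `k_out` output SPADs the
#' constituent rates are drawn uniformly with replacement and combined by
#' the chosen rule:
#' \describe{
#'   \item{`quadrature`}{`sqrt(sum(x^2))` (default).}
#'   \item{`m_rms`}{`m` times the RMS of the selected rates,
#'     `m * sqrt(mean(x^2))`.}
#'   \item{`linear_sum`}{`sum(x)` -- the physical sum of independent
#'     Poisson rates.}
#' }
#' The rules differ on the healthy plateau but agree (to within a factor
#' of order 1) whenever a defective constituent dominates, which is what
#' the yield estimate depends on. For non-integer `m`, `floor(m)`
#' constituents are always drawn and one further constituent is included
#' with probability `m - floor(m)`, so the expected defect exposure is
#' exactly proportional to area.
#'
#' @param pop A [dcr_population()] of measured SPADs.
#' @param m Area multiple, `>= 1`.
#' @param k_out Number of composed SPADs to generate. Default: the parent
#'   population size.
#' @param rule Combination rule, see Details.
#' @param seed Optional integer seed.
#' @return A [dcr_population()] at active area `m * a_aspad`.
#' @examples
#' pop <- generate_dcr_population(seed = 1)
#' big <- compose_dcr(pop, m = 2.56, seed = 2)
#' attr(big, "a_aspad")   # 512
#' @export
compose_dcr <- function(pop, m, k_out = nrow(pop),
                        rule = c("quadrature", "m_rms", "linear_sum"),
                        seed = NULL) {
  stopifnot(inherits(pop, "sipm_dcr_population"), nrow(pop) >= 1, k_out >= 1)
  rule <- match.arg(rule)
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("invalid composition: area multiple m must be >= 1", call. = FALSE)
  }
  x <- pop$rate_hz
  n <- length(x)
  base <- floor(m)
  frac <- m - base
  rates <- with_seed_if(seed, {
    vapply(seq_len(k_out), function(k) {
      n_draw <- base + (frac > 0 && stats::runif(1) < frac)
      sel <- x[sample.int(n, n_draw, replace = TRUE)]
      switch(rule,
        quadrature = sqrt(sum(sel^2)),
        m_rms = m * sqrt(mean(sel^2)),
        linear_sum = sum(sel)
      )
    }, numeric(1))
  })
  meta <- attr(pop, "meta")
  meta$composed_from <- attr(pop, "a_aspad")
  meta$m <- m
  meta$rule <- rule
  meta$seed <- seed
  dcr_population(rates, m * attr(pop, "a_aspad"), meta = meta)
}

#' Classify defective SPADs in a DCR population
#'
#' Defective SPADs sit orders of magnitude above the population plateau
#' and must be disabled. Two rules locate the border where the sorted DCR
#' curve rises abruptly:
#' \describe{
#'   \item{`median_multiple`}{defective iff `rate > k * median(rates)`
#'     (default, `k = 100`): robust because the median always sits on the
#'     plateau for defect fractions below 50%.}
#'   \item{`knee`}{threshold at the largest second difference of log-rate
#'     versus rank on the sorted curve, intended for measured data whose
#'     plateau level is not known in advance.}
#' }
#'
#' @param pop A [dcr_population()] with at least 10 SPADs.
#' @param rule Classification rule.
#' @param k Multiple of the median used by `median_multiple`.
#' @return A list with `defective` (logical mask in population order),
#'   `threshold` (Hz) and `fraction` (mean of the mask).
#' @examples
#' pop <- generate_dcr_population(seed = 1)
#' classify_defective(pop)$fraction    # ~0.10
#' @export
classify_defective <- function(pop, rule = c("median_multiple", "knee"),
                               k = 100) {
  stopifnot(inherits(pop, "sipm_dcr_population"), nrow(pop) >= 10)
  rule <- match.arg(rule)
  x <- pop$rate_hz
  if (rule == "median_multiple") {
    threshold <- k * stats::median(x)
  } else {
    if (length(unique(x)) == 1L) {
      stop("no knee: all rates are equal; use rule = 'median_multiple'",
           call. = FALSE)
    }
    s <- sort(x)
    logs <- log(pmax(s, .Machine$double.xmin))
    d2 <- diff(logs, differences = 2)
    i <- which.max(d2) + 1L       # rank just before the abrupt rise
    threshold <- sqrt(s[i] * s[min(i + 1L, length(s))])
  }
  mask <- x > threshold
  list(defective = mask, threshold = threshold, fraction = mean(mask))
}

#' SPAD yield at a larger active area, by DCR composition
#'
#' Composes the measured population up to `target_area`, classifies the
#' composed SPADs against the defect border of the *parent* population
#' (`k` times the parent median -- a single border divides defective from
#' non-defective SPADs at every area), and returns the surviving fraction.
#' Averaged over `n_boot` independent compositions. At the parent area
#' itself the population is classified directly, without resampling.
#'
#' @param pop A [dcr_population()].
#' @param target_area Target active area, um^2; must be `>=` the parent
#'   area (SPADs cannot be decomposed).
#' @param rule Combination rule passed to [compose_dcr()].
#' @param n_boot Number of independent compositions averaged.
#' @param k_out Composed SPADs per composition.
#' @param k Median multiple defining the defect border.
#' @param seed Optional integer seed.
#' @return Yield fraction in `[0, 1]`.
#' @examples
#' pop <- generate_dcr_population(seed = 1)
#' yield_at_area(pop, 512, seed = 2)   # ~0.76
#' @export
yield_at_area <- function(pop, target_area,
                          rule = c("quadrature", "m_rms", "linear_sum"),
                          n_boot = 1, k_out = nrow(pop), k = 100,
                          seed = NULL) {
  stopifnot(inherits(pop, "sipm_dcr_population"), n_boot >= 1)
  rule <- match.arg(rule)
  parent_area <- attr(pop, "a_aspad")
  if (target_area < parent_area) {
    stop("target_area is below the measured SPAD area; ",
         "decomposition is not supported", call. = FALSE)
  }
  threshold <- k * stats::median(pop$rate_hz)
  m <- target_area / parent_area
  if (m == 1) {
    # target equals the measured area: no composition, classify directly
    return(mean(pop$rate_hz <= threshold))
  }
  with_seed_if(seed, {
    surv <- vapply(seq_len(n_boot), function(b) {
      comp <- compose_dcr(pop, m = m, k_out = k_out, rule = rule)
      mean(comp$rate_hz <= threshold)
    }, numeric(1))
    mean(surv)
  })
}

#' Yield versus active area curve
#'
#' Runs [yield_at_area()] over a grid of areas, with percentile confidence
#' bounds over the `n_boot` compositions.
#'
#' @inheritParams yield_at_area
#' @param areas Vector of target active areas, um^2.
#' @param level Confidence level for the percentile bounds.
#' @return A tibble with columns `a_aspad_um2`, `yield`, `ci_lo`, `ci_hi`.
#' @examples
#' pop <- generate_dcr_population(n = 500, seed = 1)
#' yield_curve(pop, areas = c(200, 400, 800), n_boot = 20, seed = 2)
#' @export
yield_curve <- function(pop, areas, rule = "quadrature", n_boot = 50,
                        k_out = nrow(pop), k = 100, level = 0.95,
                        seed = NULL) {
  stopifnot(all(areas >= attr(pop, "a_aspad")), n_boot >= 2)
  threshold <- k * stats::median(pop$rate_hz)
  parent_area <- attr(pop, "a_aspad")
  with_seed_if(seed, {
    purrr::map_dfr(areas, function(a) {
      surv <- vapply(seq_len(n_boot), function(b) {
        comp <- compose_dcr(pop, m = a / parent_area, k_out = k_out,
                            rule = rule)
        mean(comp$rate_hz <= threshold)
      }, numeric(1))
      qs <- stats::quantile(surv, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE)
      tibble::tibble(a_aspad_um2 = a, yield = mean(surv),
                     ci_lo = qs[1], ci_hi = qs[2])
    })
  })
}

#' Deterministic parametric yield surrogate
#'
#' Under randomly distributed defects, a composed SPAD is healthy iff all
#' of its constituents are, so yield decays geometrically with area:
#' `y(a) = y0^(a / a0)`. This closed form is the deterministic envelope of
#' the resampling estimator and is what the optimizer differentiates.
#'
#' @param a_aspad Active area(s), um^2.
#' @param y0 Yield at the reference area, in `(0, 1]`.
#' @param a0 Reference area, um^2.
#' @return Yield fraction(s), vectorised over `a_aspad`.
#' @examples
#' parametric_yield(512, y0 = 0.90, a0 = 200)   # ~0.764
#' @export
parametric_yield <- function(a_aspad, y0 = 0.90, a0 = 200) {
  stopifnot(y0 > 0, y0 <= 1, a0 > 0)
  y0^(a_aspad / a0)
}

#' Yield models for the optimizer
#'
#' The optimizer consumes a yield model as a plain function of active area
#' (um^2) returning a fraction. `parametric_yield_model()` wraps
#' [parametric_yield()]; `calibrate_yield_model()` estimates `y0` from a
#' DCR population (one minus its defective fraction at its own area) and
#' anchors `a0` at the population's measured area;
#' `resampling_yield_model()` wraps the stochastic [yield_at_area()]
#' estimator behind the same interface at a fixed seed (roughly two orders
#' of magnitude slower, for cross-checks).
#'
#' @param y0,a0 See [parametric_yield()].
#' @param pop A [dcr_population()].
#' @param k Median multiple defining the defect border.
#' @param n_boot,seed Passed to [yield_at_area()] by the resampling model.
#' @return A function `f(a_aspad) -> yield fraction`, carrying its
#'   parameters in attribute `"params"`.
#' @examples
#' ym <- calibrate_yield_model(generate_dcr_population(seed = 1))
#' ym(512)
#' @export
parametric_yield_model <- function(y0 = 0.90, a0 = 200) {
  f <- function(a_aspad) parametric_yield(a_aspad, y0 = y0, a0 = a0)
  attr(f, "params") <- list(type = "parametric", y0 = y0, a0 = a0)
  f
}

#' @rdname parametric_yield_model
#' @export
calibrate_yield_model <- function(pop, k = 100) {
  cls <- classify_defective(pop, rule = "median_multiple", k = k)
  parametric_yield_model(y0 = 1 - cls$fraction, a0 = attr(pop, "a_aspad"))
}

#' @rdname parametric_yield_model
#' @export
resampling_yield_model <- function(pop, rule = "quadrature", n_boot = 5,
                                   k = 100, seed = 1) {
  force(pop)
  f <- function(a_aspad) {
    vapply(a_aspad, function(a) {
      if (a <= attr(pop, "a_aspad")) {
        1 - classify_defective(pop, k = k)$fraction
      } else {
        yield_at_area(pop, a, rule = rule, n_boot = n_boot, k = k,
                      seed = seed)
      }
    }, numeric(1))
  }
  attr(f, "params") <- list(type = "resampling", rule = rule,
                            n_boot = n_boot, k = k, seed = seed)
  f
}

#' Read and write DCR populations as CSV
#'
#' Single-column CSV (`rate_hz`) preceded by `#`-comment header lines
#' recording the active area and any scalar metadata.
#'
#' @param pop A [dcr_population()].
#' @param path File path.
#' @return `write_dcr_csv()` returns `path` invisibly; `read_dcr_csv()`
#'   returns a [dcr_population()].
#' @export
write_dcr_csv <- function(pop, path) {
  stopifnot(inherits(pop, "sipm_dcr_population"))
  meta <- attr(pop, "meta")
  hdr <- c(sprintf("# a_aspad_um2: %.10g", attr(pop, "a_aspad")))
  scalars <- meta[vapply(meta, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))]
  hdr <- c(hdr, sprintf("# %s: %.10g", names(scalars), unlist(scalars)))
  writeLines(c(hdr, "rate_hz", sprintf("%.10g", pop$rate_hz)), path)
  invisible(path)
}

#' @rdname write_dcr_csv
#' @export
read_dcr_csv <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (h in lines[is_hdr]) {
    kv <- strsplit(sub("^#\\s*", "", h), ":\\s*")[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  body <- lines[!is_hdr]
  stopifnot(body[1] == "rate_hz")
  a <- meta[["a_aspad_um2"]]
  if (is.null(a)) stop("missing '# a_aspad_um2:' header", call. = FALSE)
  meta[["a_aspad_um2"]] <- NULL
  dcr_population(as.numeric(body[-1]), a_aspad = a, meta = meta)
}
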