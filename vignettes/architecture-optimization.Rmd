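---
title: "Architecture-level sensitivity optimization of digital SiPM pixels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture-level sensitivity optimization of digital SiPM pixels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A digital silicon photomultiplier (dSiPM) pixel for PET timestamps and
counts the optical photons that a 511 keV gamma produces in a
scintillating crystal. Because the counting, quenching and timing
circuits live next to the SPADs on the same CMOS die, every design
choice trades photosensitive area against circuit area, and the circuit
organisation itself loses counts through pile-up. `dsipmopt` implements
an analytic model of those losses, estimates the SPAD yield penalty from
dark-count-rate (DCR) statistics, and searches the architectural design
space for the pixel that maximizes *sensitivity* — the expected counted
fraction per incident photon at the operating illumination.

The design variables are:

* `n_uc` — SPADs per *microcell*. A microcell shares one monostable and
  one reset circuit; simultaneous hits inside it merge (**spatial
  pile-up**).
* `m_spl` — *subpixels* per pixel. Each subpixel ORs its microcell
  pulses onto one bus feeding one counter; overlapping pulses merge
  (**temporal pile-up**).
* `a_aspad` — the SPAD active area (µm²).

## The model

With `Ddet = PDP · Dph · (1 − exp(−Tclk/τ_sct))` the density of detected
photons over the scintillation build-up window, the two pile-up
probabilities are Poisson:

* spatial: `Psp = 1 − exp(−n_uc · a_aspad · Ddet)`
* temporal: `Ptp = 1 − exp(−Nspad · Y · a_aspad · Ddet · Tpulse /
  (m_spl · Tclk))`

and the sensitivity decomposes multiplicatively,

```
S = PDE · Y · (1 − Psp) · (1 − Ptp),      PDE = PDP · FF,
FF = Nspad · a_aspad / A_pxl.
```

`Nspad` comes from the area bookkeeping: the pixel area minus the
per-pixel (TDC, FSM) and per-subpixel (counter tree) blocks, divided by
the per-SPAD cost — the SPAD footprint plus quenching/recharge circuit
and SRAM bit, plus the microcell-shared reset/monostable amortised over
`n_uc`. The quotient is floored: partial SPADs cannot be laid out, and
no divisibility by `m_spl · n_uc` is imposed (the reference device's 762
SPADs are not divisible by 64 either).

**Footprint model.** Only the active area is a design variable; the
footprint adds the guard ring and cathode connection, modelled as a
constant-width dead frame around a square active region:
`(√a_aspad + 2g)²`. The width `g` is the model's one free parameter. It
is calibrated once, in closed form, so that the bookkeeping reproduces
the implemented 1 mm² device (762 SPADs at 512 µm² with the reference
block areas), giving `g ≈ 5.18 µm` (`calibrate_guard_width()`). With
that single calibration the model predicts 1746 and 3099 SPADs for the
2.25 and 4 mm² pixels (reference values 1747 and 3101). The 9 mm²
reference count (7217) is *not* reproducible from the same bookkeeping —
the prediction is ≈ 7040 — and the package does not force-fit it.

**Units.** Areas are µm² internally (mm² at the configuration
boundary), times in seconds, photon densities per mm². The conversions
happen inside the probability functions; the `1e−6` factor between µm²
areas and per-mm² densities is the main implementation hazard of these
formulas, so it lives in exactly one place per formula.

## Yield from dark-count statistics

A non-negligible fraction of CMOS SPADs is defective — their DCR sits
orders of magnitude above the population plateau — and must be disabled,
so the usable fraction `Y` (yield) falls with active area. Under the
assumption that defects are randomly distributed in area, a SPAD `m`
times larger behaves as the union of `m` randomly drawn measured SPADs.
`compose_dcr()` implements that resampling with three combination rules
(`quadrature`, the default `√Σx²`; `m_rms`; `linear_sum`). The rules
differ on the healthy plateau but agree wherever a defective constituent
dominates, which is the only thing the yield estimate depends on — the
choice is documented and testable, not consequential.

Two details matter more than the rule:

* **Non-integer `m`.** A 512 µm² SPAD composed from 200 µm² devices has
  `m = 2.56`. Drawing `⌈m⌉` full constituents would overstate the defect
  exposure (`1 − (1−f)³` instead of `1 − (1−f)^2.56`). The package draws
  `⌊m⌋` constituents and includes one more with probability
  `m − ⌊m⌋`, making the expected defect exposure exactly proportional to
  area.
* **Where the defect border sits.** `yield_at_area()` classifies the
  composed population against the border fixed on the *parent*
  population (100× its median by default): the border that separates
  defective from healthy devices is a property of the measured
  technology, one line dividing the sorted-DCR curves at every area.
  Classifying each composed population against its own median would let
  the weakest defects slip under the (growing) threshold and bias the
  yield high by a couple of percentage points at `m ≈ 2.5`.

For the optimizer, the resampling estimator is replaced by its
deterministic envelope `y(a) = y0^(a/a0)` (`parametric_yield_model()`),
calibrated from a population by `calibrate_yield_model()`. The
stationarity condition the optimizer solves is ill-defined under
resampling noise; the geometric form is exact when defects are random in
area, and the resampling estimator stays available behind the same
function interface (`resampling_yield_model()`) at roughly 100× the
cost.

The synthetic generator (`generate_dcr_population()`) emulates the
measured distribution of an implemented 110 nm array: a log-normal
plateau with 50 Hz median (log-sd 0.25, keeping essentially all healthy
devices below 100 Hz) and a 10% defective fraction drawn log-uniformly
over 5–500 kHz. The plateau *level* and the absolute defect rates are
modelling choices justified only through the yield fraction; nothing
downstream depends on them beyond "orders of magnitude above the
plateau".

## The optimizer

For each `(n_uc, m_spl)` cell, `optimize_active_area()` maximizes
`S(a_aspad)`. The objective is unimodal in area but not smooth: the
floored SPAD count imprints small plateaus and jumps. A golden-section
step can stall on those plateaus (its tie rule discards the half
interval containing the maximum), so after a coarse 96-point log-spaced
scan the bracketing interval is simply rescanned at the same resolution
until the bracket is below a 10⁻³ relative tolerance. Each stage shrinks
the interval ~50×; the result matches or beats a dense 3000-point
exhaustive scan in every cell we test.

`sweep_design_space()` fills the full grid (defaults: `n_uc` 1–16,
`m_spl` powers of two up to 256, area bounds 50–5000 µm²; the bounds
bracket the measured 200 µm² device and all optima encountered). The
sensitivity surface has a broad plateau once `n_uc ≥ 2` and
`m_spl ≥ 4`, so a bare argmax is unstable; cells within 0.05 pp of the
maximum are reported as ties and the best cell is the tied cell with the
smallest `m_spl`, then the smallest `n_uc` (fewer counters and less
sharing for the same sensitivity).

```{r, eval = FALSE}
library(dsipmopt)
sw <- sweep_design_space(design_space(), area_budget(),
                         operating_conditions(), parametric_yield_model())
glance(sw)
autoplot(sw)
```

### Where the model's optimum sits

Evaluated at the reference architecture (`n_uc = 4`, `m_spl = 16`,
512 µm², `Y = 0.77`), the model gives `S = 7.77%`, matching the
published 7.7% decomposition of that device. The *argmax* of the model
is a different matter: with the calibrated footprint and the geometric
yield (`y0 = 0.90` at 200 µm²), the sweep's global optimum for 1 mm² is
`n_uc = 2`, `m_spl = 16`, `a_aspad ≈ 617 µm²` at `S = 7.89%` — the best
`n_uc = 4` cell sits 0.18 pp lower, outside the 0.05 pp tie band, with
its own area optimum near 520 µm². The ranking between `n_uc = 2` and
`n_uc = 4` at fixed area is independent of the yield model (yield
cancels from the ratio), so this is a property of the printed equations
and areas themselves: halving the microcell size costs ~4% of fill
factor through the extra shared-logic area but removes ~5.5% of spatial
pile-up at 500–600 µm². The two organisations only swap rank below
≈ 420 µm². The maximum is extremely flat — ±10% in area moves `S` by
less than 0.2 pp, and the 2-vs-4 gap is of the same order — so the
practical conclusion ("≈ 8% for every pixel size, reached by moderate
sharing and subpixel counts") is unchanged, but the package reports what
the model actually maximizes rather than forcing the reference cell.

## The discrete-event oracle

`simulate_subpixel()` brute-forces the subpixel circuit: PDP thinning,
uniform assignment over enabled microcells, once-per-window microcell
firing (the 5 µs SPAD dead time dwarfs the 20 ns window), `Tpulse`-wide
pulses on a wired-OR bus, counting rising edges. Because the sensitivity
is defined *differentially* (a derivative of counted with respect to
incident photons), the empirical pile-up estimators are marginal ones:

* `p_sp` — fraction of microcells already fired in a window: the
  probability one further photon would find its microcell busy;
* `p_tp` — OR-bus occupancy over the stationary part of the window: the
  probability one further pulse would be absorbed.

Under Poisson illumination these converge exactly to the analytic
formulas; ratio-of-losses estimators (e.g. `1 − triggers/detected`)
converge to different quantities (≈ half the marginal value) and are not
used. At the reference operating point, 10⁴ windows reproduce
`Psp = 0.103` and `Ptp = 0.039` within three binomial standard errors.

**What the closed-form counting curve is, and is not.** Integrating the
marginal sensitivity over the incident count gives the saturating
response `n_out = (Nspad·Y/α)(1 − exp(−α·PDE·n_ph/Nspad))` with
`α = n_uc + Nspad·Y·Tpulse/(m_spl·Tclk)`. The package verifies this two
ways. The identity part — that the closed form is the exact integral of
`PDE·Y·(1−Psp)(1−Ptp)` evaluated at the accumulated detected density —
is checked both algebraically (numeric differentiation) and against the
subpixel oracle at swept densities. The event-level part is an
approximation: the `1/Tclk` in α comes from the window-averaged pulse
rate, while a physical scintillation pulse delivers photons at an
instantaneous rate governed by `1/τ_sct`. With `τ_sct = 2·Tclk` the
closed form overstates temporal losses by roughly a factor two at high
intensities, so the event-level Monte-Carlo (`simulate_event_response()`,
exponential arrival times, whole-event dead time) runs ≈ 2% above the
closed form at 450 incident photons and more in deep saturation, while
agreeing within Monte-Carlo error in the linear and moderate regimes.
Both are implemented exactly as stated and never mixed; the tests assert
agreement where the closed form is exact and bracket the difference by
the closed form's own temporal-loss magnitude where it is not.

## First-photon pixel multiplicity

For timestamp-driven PET the first ~10 detected photons carry the timing
information, and per-pixel TDCs exploit them only if they land on
distinct pixels. `simulate_first_n_multiplicity()` measures the
distribution of distinct pixels among the first `n_first` detections
with a deliberately simple optical model: a single interaction vertex
per event (no Compton chain), depth sampled from an exponential
penetration law (12 mm attenuation length at 511 keV, truncated to the
20 mm crystal; a fixed-depth mode reproduces the near-entrance ideal
case), isotropic emission into the lower hemisphere, straight-line
transport to the readout plane — no reflection, refraction, wrapping or
optical grease — and uniform detection thinning (`PDE·Y`; the first
photons are in the linear regime, so the saturating response is not
needed). The light yield is a free scale fixed so that an interaction at
the typical height produces the operating-point peak density of
450 photons/mm² (`calibrate_light_yield()`, ≈ 1.8 × 10⁵ photons per
event); it is not a measured crystal property.

Passing tests therefore show the *geometric* statements — near-entrance
interactions with ideal PDE flood 8–10 distinct 1 mm pixels; smaller
pixels stochastically dominate larger ones in first-photon multiplicity
at equal PDE — and nothing about absolute timing or about crystals with
reflective wrapping, where light sharing is broader and the advantage of
small pixels can only grow at equal PDE. The pixel-size comparison in
the tests uses a 48 × 48 mm² face so that both 1 mm and 3 mm pitches
tile it exactly.

## Numerical choices and problem sizes

* All stochastic functions take an explicit integer `seed` and restore
  the caller's RNG state; results are bit-reproducible given the seed.
* The 1-D optimizer: 96-point log scans, iterated to a 10⁻³ relative
  bracket; ties on the sweep plateau resolved to smallest `m_spl`, then
  smallest `n_uc`, with the full near-optimal set retained.
* Classification default: 100× the population median, robust for defect
  fractions below 50%; a knee detector (largest second difference of
  log-rate versus rank) is provided for measured data and errors out on
  degenerate all-equal populations rather than inventing a border.
* Test problem sizes are chosen for tight statistical checks at desk
  scale: 10⁴ windows for the pile-up oracle (binomial 3σ ≈ 0.006 on
  `Ptp`), 2000-SPAD DCR populations (3σ ≈ 0.02 on a 10% defect
  fraction), 200–400 events per multiplicity histogram, full 144-cell
  sweeps for the optimizer (≈ 1.5 s each).

## Limitations

* Afterpulsing, optical crosstalk and temperature dependence of the DCR
  are not modelled; the yield model assumes spatially random defects.
* The pile-up model treats the microcell as dead for the whole window
  and the OR-bus load as stationary; both match the analytic formulas
  by construction and the event simulator by measurement, but neither
  resolves sub-window timing structure beyond the pulse width.
* The optical model is a solid-angle calculation, not a photon-transport
  simulation; absolute multiplicities depend on the light-yield scale,
  only orderings and shapes are meaningful.
* The 9 mm² reference SPAD count and the reference best-cell
  architecture are not reproducible from the printed model (see above);
  both discrepancies are reported, not corrected away.
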