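# Discrete-event oracle and scintillation-spread simulator.

test_that("subpixel simulator: degenerate windows", {
  op <- ref_op()
  r0 <- simulate_subpixel(ref_arch(), 48, 1, numeric(0), op, seed = 1)
  expect_identical(r0$counted, 0L)
  expect_identical(r0$p_sp, 0)
  expect_identical(r0$p_tp, 0)

  ideal <- operating_conditions(pdp = 1)
  r1 <- simulate_subpixel(ref_arch(), 48, 1, 5e-9, ideal, seed = 1)
  expect_identical(r1$counted, 1L)
  expect_identical(r1$n_detected, 1L)
  expect_identical(r1$n_triggers, 1L)

  expect_warning(
    r2 <- simulate_subpixel(ref_arch(), 48, 1, c(5e-9, 30e-9), ideal,
                            seed = 1),
    "rejected")
  expect_identical(r2$n_rejected, 1L)
})

test_that("instantaneous pulses reduce the subpixel to PDP thinning", {
  # one SPAD per monostable, zero pulse width, sparse photons: the only
  # loss channel left is the PDP Bernoulli
  op <- operating_conditions(t_pulse = 1e-18, pdp = 0.6)
  arch <- architecture(1, 16, 512)
  counts <- vapply(1:300, function(r) {
    simulate_subpixel(arch, 5000, 1, runif(20, 0, op$t_clk), op,
                      seed = 1000 + r)$counted
  }, integer(1))
  se <- sqrt(20 * 0.6 * 0.4 / 300)
  expect_lt(abs(mean(counts) - 20 * 0.6), 3 * se)
})

test_that("ensemble estimators converge to the analytic pile-up", {
  op <- ref_op()
  e <- simulate_subpixel_ensemble(ref_arch(), ref_budget(), op, y = 0.77,
                                  replicates = 3000, seed = 7)
  d <- detected_density(op)
  psp_ref <- p_spatial(4, 512, d)
  ptp_ref <- p_temporal(762, 0.77, 512, d, op, 16)
  expect_lt(abs(e$p_sp - psp_ref), 3 * e$p_sp_se)
  expect_lt(abs(e$p_tp - ptp_ref),
            3 * sqrt(ptp_ref * (1 - ptp_ref) / e$replicates))
})

test_that("event response: linear regime, monotonicity, saturation", {
  op <- ref_op()
  b <- ref_budget()
  res <- simulate_event_response(c(2, 10, 50), ref_arch(), b, op, 0.77,
                                 replicates = 800, seed = 8)
  pde_y <- 0.3 * fill_factor(762, 512, 1) * 0.77
  # small signals: counted ~= PDE * Y * n_ph
  for (i in 1:2) {
    expect_lt(abs(res$n_out[i] - pde_y * res$n_ph[i]),
              3 * res$se[i] + 0.01 * pde_y * res$n_ph[i])
  }
  expect_true(all(diff(res$n_out) > 0))
  # moderate regime tracks the closed form within Monte-Carlo error
  expect_lt(abs(res$n_out[3] - res$n_out_closed_form[3]), 3 * res$se[3])

  # near saturation the closed form evaluates temporal pile-up at the
  # window-averaged rather than instantaneous rate; the discrete-event
  # result stays within the closed form's own temporal-loss magnitude
  sat <- simulate_event_response(c(450, 1500), ref_arch(), b, op, 0.77,
                                 replicates = 400, seed = 9)
  alpha <- pulse_compression_alpha(ref_arch(), 762, 0.77, op)
  pde <- 0.3 * fill_factor(762, 512, 1)
  no_tp <- counted_photons(sat$n_ph, pde, 762, 0.77, 4)  # alpha w/o pulses
  expect_true(all(abs(sat$n_out - sat$n_out_closed_form) <=
                    (no_tp - sat$n_out_closed_form) + 3 * sat$se))
  expect_true(all(sat$n_out <= 762 * 0.77 / 4))
})

test_that("single-event pixel records are consistent", {
  ev <- simulate_scintillation_event(n_photons = 5000, det_prob = 0.5,
                                     depth = 10, seed = 21)
  expect_true(all(ev$detected <= ev$impinging))
  expect_true(all(is.na(ev$t_first) == (ev$detected == 0)))
  expect_true(all(ev$row >= 1 & ev$row <= 50))
  expect_true(all(ev$col >= 1 & ev$col <= 50))
  expect_error(simulate_scintillation_event(pixel_size = 3), "divide")
})

test_that("multiplicity histogram: normalisation and edge cases", {
  m1 <- simulate_first_n_multiplicity(n_first = 1, n_events = 40,
                                      light_yield = 3000, det_prob = 0.2,
                                      seed = 22)
  expect_equal(m1$histogram$probability, 1)   # one photon, one pixel

  m <- simulate_first_n_multiplicity(n_first = 10, n_events = 60,
                                     light_yield = 5000, det_prob = 0.1,
                                     seed = 23)
  expect_equal(sum(m$histogram$probability), 1, tolerance = 1e-12)
  expect_true(all(m$histogram$multiplicity <= 10))

  # events with no detected photon are excluded but accounted for
  sparse <- simulate_first_n_multiplicity(n_first = 10, n_events = 60,
                                          light_yield = 200,
                                          det_prob = 0.004, seed = 24)
  expect_gt(sparse$n_excluded, 0)
  expect_equal(sum(sparse$events$n_detected == 0), sparse$n_excluded)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})

test_that("ideal sensor near the entrance face floods many pixels", {
  # PDE = 1 and an interaction close to the entrance window: the photons
  # spread over a wide solid angle, so the first 10 land almost surely
  # on 8+ distinct 1 mm pixels
  m <- simulate_first_n_multiplicity(
    n_first = 10, det_prob = 1, n_events = 120, depth_model = "fixed",
    fixed_depth = 19.5, light_yield = 20000, seed = 25)
  probs <- m$histogram$probability
  expect_gte(which.max(probs), 8)
  expect_gte(sum(m$histogram$multiplicity * probs), 8)
})

test_that("smaller pixels dominate larger ones in first-photon spread", {
  # 48 mm face so both 1 mm and 3 mm pitches tile it exactly
  run <- function(ps, seed) {
    simulate_first_n_multiplicity(
      crystal = c(48, 48, 20), pixel_size = ps, n_first = 10,
      det_prob = 0.08, n_events = 250, light_yield = 20000, seed = seed)
  }
  m1 <- run(1, 26)
  m3 <- run(3, 26)
  mean1 <- sum(m1$histogram$multiplicity * m1$histogram$probability)
  mean3 <- sum(m3$histogram$multiplicity * m3$histogram$probability)
  expect_gt(mean1, mean3)
  # first-order stochastic dominance of the multiplicity distribution
  cdf1 <- cumsum(m1$histogram$probability)
  cdf3 <- cumsum(m3$histogram$probability)
  expect_true(all(cdf1 <= cdf3 + 0.02))
})

test_that("simulations are reproducible bit-exactly given a seed", {
  op <- ref_op()
  a <- simulate_subpixel_ensemble(ref_arch(), ref_budget(), op, 0.77,
                                  replicates = 200, seed = 31)
  b <- simulate_subpixel_ensemble(ref_arch(), ref_budget(), op, 0.77,
                                  replicates = 200, seed = 31)
  expect_identical(a, b)
  m1 <- simulate_first_n_multiplicity(n_events = 20, light_yield = 2000,
                                      det_prob = 0.3, seed = 32)
  m2 <- simulate_first_n_multiplicity(n_events = 20, light_yield = 2000,
                                      det_prob = 0.3, seed = 32)
  expect_identical(m1$histogram, m2$histogram)
})
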