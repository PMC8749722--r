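# Analytic response: detected density, pile-up, sensitivity, counting.

test_that("detected density follows the build-up window", {
  op <- ref_op()
  expect_equal(detected_density(op), 0.30 * 450 * (1 - exp(-0.5)))
  expect_equal(detected_density(op), 53.1184, tolerance = 1e-4)
  # saturated build-up: every impinging photon has arrived
  expect_equal(detected_density(operating_conditions(t_clk = 1e-3)),
               135, tolerance = 1e-6)
  expect_lt(detected_density(operating_conditions(t_clk = 1e-15)), 1e-4)
})

test_that("pile-up probabilities at the reference operating point", {
  op <- ref_op()
  d <- detected_density(op)
  expect_equal(p_spatial(4, 512, d), 0.103078, tolerance = 1e-5)
  expect_equal(p_temporal(762, 0.77, 512, d, op, 16), 0.0391081,
               tolerance = 1e-5)
  expect_identical(p_spatial(4, 512, 0), 0)
  expect_identical(p_temporal(762, 0.77, 512, d,
                              operating_conditions(t_pulse = 0), 16), 0)

  # monotonicity: more sharing, bigger SPADs or more light -> more pile-up
  expect_true(all(diff(p_spatial(1:8, 512, d)) > 0))
  expect_true(all(diff(p_spatial(4, c(100, 500, 2000), d)) > 0))
  expect_true(all(diff(p_spatial(4, 512, c(1, 50, 500))) > 0))
  # doubling the subpixel count halves the OR-bus load
  expect_lt(p_temporal(762, 0.77, 512, d, op, 32),
            p_temporal(762, 0.77, 512, d, op, 16))
})

test_that("sensitivity decomposition: reference value and identity", {
  s <- sensitivity(ref_arch(), ref_budget(), ref_op(), y = 0.77)
  expect_equal(s$s, 0.077, tolerance = 0.0015 / 0.077)
  expect_equal(s$n_spad, 762L)
  expect_equal(s$ff, 0.390144, tolerance = 1e-6)

  # multiplicative identity to machine precision on random feasible designs
  set.seed(42)
  for (i in 1:30) {
    arch <- architecture(sample(1:8, 1), 2^sample(0:6, 1),
                         runif(1, 100, 2000))
    y <- runif(1)
    res <- sensitivity(arch, ref_budget(), ref_op(), y)
    expect_lt(abs(res$s - res$pde * res$y * (1 - res$p_sp) *
                    (1 - res$p_tp)), 1e-12)
    expect_true(res$p_sp >= 0 && res$p_sp < 1)
    expect_true(res$p_tp >= 0 && res$p_tp < 1)
    expect_true(res$s >= 0 && res$s <= ref_op()$pdp)
  }

  expect_equal(sensitivity(ref_arch(), ref_budget(), ref_op(), 0)$s, 0)
  # vanishing light and perfect yield: S -> PDP * FF
  dim_op <- operating_conditions(d_ph = 1e-9)
  s0 <- sensitivity(ref_arch(), ref_budget(), dim_op, 1)
  expect_equal(s0$s, 0.30 * s0$ff, tolerance = 1e-6)
})

test_that("sensitivity accepts a yield model function", {
  ym <- parametric_yield_model(y0 = 0.9, a0 = 200)
  s <- sensitivity(ref_arch(), ref_budget(), ref_op(), ym)
  expect_equal(s$y, 0.9^2.56)
})

test_that("compression constant and closed-form counting", {
  op <- ref_op()
  a <- pulse_compression_alpha(ref_arch(), 762, 0.77, op)
  expect_equal(a, 5.46685, tolerance = 1e-5)
  expect_equal(pulse_compression_alpha(
    ref_arch(), 762, 0.77, operating_conditions(t_pulse = 0)), 4)
  expect_equal(pulse_compression_alpha(
    architecture(1, 16, 512), 762, 0.77,
    operating_conditions(t_pulse = 0)), 1)

  pde <- 0.3 * fill_factor(762, 512, 1)
  # small-signal slope is PDE * Y
  expect_equal(counted_photons(1e-6, pde, 762, 0.77, a) / 1e-6,
               pde * 0.77, tolerance = 1e-6)
  # reference evaluation and saturation level
  expect_equal(counted_photons(450, pde, 762, 0.77, a), 33.77,
               tolerance = 1e-3)
  expect_equal(counted_photons(1e9, pde, 762, 0.77, a), 762 * 0.77 / a,
               tolerance = 1e-9)
  expect_equal(762 * 0.77 / a, 107.33, tolerance = 1e-4)
})

test_that("closed form is the exact integral of the marginal survival", {
  # d n_out / d n_ph at n' must equal PDE*Y*(1-Psp)(1-Ptp) with both
  # pile-up terms evaluated at the accumulated detected density
  # PDP * n' / A_pxl (no build-up factor in the event-level response)
  op <- ref_op()
  b <- ref_budget()
  for (pars in list(list(n_uc = 4L, m_spl = 16L, aa = 512, y = 0.77),
                    list(n_uc = 2L, m_spl = 8L, aa = 900, y = 0.5),
                    list(n_uc = 1L, m_spl = 64L, aa = 200, y = 1))) {
    arch <- architecture(pars$n_uc, pars$m_spl, pars$aa)
    n_spad <- spads_per_pixel(arch, b)
    pde <- op$pdp * fill_factor(n_spad, pars$aa, 1)
    alpha <- pulse_compression_alpha(arch, n_spad, pars$y, op)
    for (n in c(10, 100, 450, 1500)) {
      h <- 1e-3
      num_deriv <- (counted_photons(n + h, pde, n_spad, pars$y, alpha) -
                      counted_photons(n - h, pde, n_spad, pars$y, alpha)) /
        (2 * h)
      d_acc <- op$pdp * n / 1          # detected density, photons/mm^2
      marginal <- pde * pars$y *
        (1 - p_spatial(pars$n_uc, pars$aa, d_acc)) *
        (1 - p_temporal(n_spad, pars$y, pars$aa, d_acc, op, pars$m_spl))
      expect_equal(num_deriv, marginal, tolerance = 1e-6)
    }
  }
})

test_that("response curve is non-decreasing, concave and bounded", {
  rc <- response_curve(ref_arch(), ref_budget(), ref_op(), y = 0.77,
                       n_ph = seq(0, 3000, by = 50))
  expect_true(all(diff(rc$n_out) >= 0))
  expect_true(all(diff(diff(rc$n_out)) <= 1e-9))
  p <- attr(rc, "params")
  expect_true(all(rc$n_out <= p$n_spad * p$y / p$alpha + 1e-9))
})

test_that("tidy and glance expose the decomposition", {
  s <- sensitivity(ref_arch(), ref_budget(), ref_op(), 0.77)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$s, s$s)
  expect_equal(glance(s)$s_pct, 100 * s$s)
})
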