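# Two simulated traces shared across the tests in this file (coarse but
# resolved settings; see helper-fixtures.R)
trace_02 <- simulate_adsorption(quick_config(0.2, t_end_s = 3600))
trace_044 <- simulate_adsorption(quick_config(0.44, t_end_s = 3600))

test_that("an empty drop keeps the buffer surface tension", {
  tr <- simulate_adsorption(quick_config(0, t_end_s = 300, dt_out_s = 30))
  expect_equal(tr$gamma_mJ_m2, rep(72.0, nrow(tr)))
  expect_equal(tr$Gamma_um2, rep(0, nrow(tr)))
})

test_that("simulated traces are monotone, bounded and conservative", {
  for (tr in list(trace_02, trace_044)) {
    expect_true(all(diff(tr$gamma_mJ_m2) <= 1e-9))
    expect_true(all(tr$gamma_mJ_m2 > 50))          # gamma0 - Pi_max floor
    expect_true(all(tr$gamma_mJ_m2 <= 72.0 + 1e-9))
    expect_lt(attr(tr, "metadata")$conservation_error, 1e-3)
  }
  # higher concentration: faster drop at any fixed time past induction
  t_probe <- seq(1000, 3500, by = 500)
  g02 <- stats::approx(trace_02$time_s, trace_02$gamma_mJ_m2, t_probe)$y
  g044 <- stats::approx(trace_044$time_s, trace_044$gamma_mJ_m2, t_probe)$y
  expect_true(all(g044 <= g02 + 1e-6))
})

test_that("trace induction time matches the diffusion-limited oracle", {
  # the 1.5 mJ/m^2 crossing sits at coverage excess_of_pi(1.5), so the
  # matching Eq.-1-style oracle is the time to reach that coverage
  eos <- default_eos
  G_thr <- excess_of_pi(1.5, eos)
  t_ind <- extract_induction_time(trace_02)
  t_oracle <- diffusion_limited_induction_time(0.2, G_thr, 45, 2100)
  expect_equal(t_ind, t_oracle, tolerance = 0.05)
  # and exceeds the Gamma0-crossing time by the predicted bounded factor
  t_g0 <- diffusion_limited_induction_time(0.2, eos$Gamma0_um2, 45, 2100)
  expect_gt(t_ind, t_g0)
  expect_lt(t_ind / t_g0, (G_thr / eos$Gamma0_um2)^2 * 1.1)
})

test_that("bulk exchange preserves or resumes the tension decrease", {
  cfg <- quick_config(0.44, t_end_s = 2400)
  # to buffer: gamma frozen after the exchange
  tr0 <- simulate_bulk_exchange(cfg, 1200, 0)
  g_ex <- tr0$gamma_mJ_m2[tr0$time_s == 1200]
  expect_lt(abs(tr0$gamma_mJ_m2[nrow(tr0)] - g_ex), 0.1)
  # to higher concentration: decrease resumes
  tr5 <- simulate_bulk_exchange(cfg, 1200, 5)
  expect_lt(tr5$gamma_mJ_m2[nrow(tr5)],
            tr5$gamma_mJ_m2[tr5$time_s == 1200] - 0.5)
  # to the same concentration: identical up to the exchange; afterwards
  # the refreshed (depletion-free) bulk can only speed adsorption up, by
  # an amount bounded by the boundary-layer depletion
  tr_same <- simulate_bulk_exchange(cfg, 1200, 0.44)
  tr_ref <- simulate_adsorption(cfg)
  g_same <- stats::approx(tr_same$time_s, tr_same$gamma_mJ_m2,
                          tr_ref$time_s)$y
  pre <- tr_ref$time_s <= 1200
  expect_lt(max(abs(g_same[pre] - tr_ref$gamma_mJ_m2[pre])), 1e-6)
  expect_true(all(g_same <= tr_ref$gamma_mJ_m2 + 1e-6))
  expect_lt(max(abs(g_same - tr_ref$gamma_mJ_m2)), 1.5)
})

test_that("area steps compress the layer and round-trip exactly", {
  # contraction of a developed layer: instantaneous tension drop
  cfg <- quick_config(0.44, t_end_s = 1500, dt_out_s = 5)
  tr <- simulate_area_step(cfg, 1000, 0.7)
  g_pre <- tr$gamma_mJ_m2[tr$time_s == 995]
  g_post <- tr$gamma_mJ_m2[tr$time_s == 1000]
  expect_lt(g_post, g_pre - 1)
  expect_equal(tr$area_mm2[tr$time_s == 1000], 50 * 0.7)
  # expansion of a fresh (Gamma < Gamma0) surface: gamma stays at gamma0
  cfg_fresh <- quick_config(0, t_end_s = 300, dt_out_s = 10,
                            Gamma_init_um2 = 0.5 * 24e3)
  tr_f <- simulate_area_step(cfg_fresh, 150, 1.5)
  expect_equal(tr_f$gamma_mJ_m2, rep(72.0, nrow(tr_f)))
  # reciprocal contract-expand on an isolated shell: exact round trip
  cfg_shell <- quick_config(0, t_end_s = 600, dt_out_s = 10,
                            Gamma_init_um2 = 2 * 24e3)
  tr_s <- simulate_area_step(cfg_shell, c(200, 400), c(0.7, 1 / 0.7))
  g <- function(t) tr_s$gamma_mJ_m2[tr_s$time_s == t]
  expect_lt(g(210), g(190))                 # contracted
  expect_equal(g(410), g(190), tolerance = 1e-9)  # restored
})

test_that("induction time extraction interpolates the crossing", {
  flat <- tensiometry_trace(0:10, rep(72, 11),
                            metadata = list(gamma0_mJ_m2 = 72))
  expect_true(is.na(extract_induction_time(flat)))
  # constructed piecewise-linear trace crossing 70.5 at exactly t = 500
  tr <- tensiometry_trace(c(0, 400, 600, 800),
                          c(72, 72, 69, 66),
                          metadata = list(gamma0_mJ_m2 = 72))
  expect_equal(extract_induction_time(tr), 500, tolerance = 1e-9)
  # threshold 0: first departure from gamma0
  expect_equal(extract_induction_time(tr, threshold_mJ_m2 = 0), 400,
               tolerance = 1e-9)
})

test_that("semistable gamma detection respects the rate threshold", {
  # steady ramp faster than 2.5 mJ/m^2 per hour throughout: none
  t <- seq(0, 3600, by = 10)
  ramp <- tensiometry_trace(t, 72 - t * 10 / 3600,
                            metadata = list(gamma0_mJ_m2 = 72))
  expect_true(is.na(extract_semistable_gamma(ramp)))
  # exactly constant after t* = 1800: gamma(t*)
  g <- ifelse(t < 1800, 72 - (t / 1800) * 10, 62)
  tr <- tensiometry_trace(t, g, metadata = list(gamma0_mJ_m2 = 72))
  expect_equal(extract_semistable_gamma(tr), 62, tolerance = 1e-9)
  # simulated trace: semistable value inside the EoS bounds
  g_semi <- extract_semistable_gamma(trace_044)
  expect_gt(g_semi, 50)
  expect_lt(g_semi, 72)
})

test_that("scaled time places the induction crossing at 1 and is idempotent", {
  sc <- scaled_time_trace(trace_044)
  g_at_1 <- stats::approx(sc$time_s, sc$gamma_mJ_m2, 1)$y
  expect_equal(g_at_1, 72 - 1.5, tolerance = 0.02)
  sc2 <- scaled_time_trace(sc)
  expect_equal(sc2$time_s, sc$time_s, tolerance = 1e-9)
  # diffusion-dominated collapse: different concentrations overlap for
  # scaled time <= 1
  sc02 <- scaled_time_trace(trace_02)
  tq <- seq(0.1, 1, by = 0.1)
  g1 <- stats::approx(sc02$time_s, sc02$gamma_mJ_m2, tq)$y
  g2 <- stats::approx(sc$time_s, sc$gamma_mJ_m2, tq)$y
  expect_lt(max(abs(g1 - g2)), 0.5)
  flat <- tensiometry_trace(0:10, rep(72, 11),
                            metadata = list(gamma0_mJ_m2 = 72))
  expect_error(scaled_time_trace(flat), "induction")
})

test_that("trace construction validates monotone time", {
  expect_error(tensiometry_trace(c(0, 2, 1), c(72, 71, 70)),
               "strictly increasing")
  expect_error(tensiometry_trace(c(0, 1), c(72, 71, 70)))
})
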