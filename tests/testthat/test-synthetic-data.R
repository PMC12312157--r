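test_that("a noise-free generated trace equals the simulator output", {
  cfg <- quick_config(0.44, t_end_s = 600, dt_out_s = 20)
  clean <- simulate_adsorption(cfg)
  gen <- generate_trace(cfg, noise_model(sigma_mJ_m2 = 0, drift_mJ_m2_h = 0))
  expect_equal(gen$gamma_mJ_m2, clean$gamma_mJ_m2)
  expect_equal(gen$Gamma_um2, clean$Gamma_um2)
})

test_that("generated traces are reproducible per seed and drift as asked", {
  cfg <- quick_config(0.3, t_end_s = 400, dt_out_s = 20)
  nm <- noise_model(sigma_mJ_m2 = 0.2, seed = 42)
  tr1 <- generate_trace(cfg, nm)
  tr2 <- generate_trace(cfg, nm)
  expect_identical(tr1$gamma_mJ_m2, tr2$gamma_mJ_m2)
  tr3 <- generate_trace(cfg, noise_model(sigma_mJ_m2 = 0.2, seed = 43))
  expect_false(identical(tr1$gamma_mJ_m2, tr3$gamma_mJ_m2))
  # pure drift tilts the trace linearly
  drifted <- generate_trace(cfg, noise_model(sigma_mJ_m2 = 0,
                                             drift_mJ_m2_h = -3.6))
  base <- generate_trace(cfg, noise_model(sigma_mJ_m2 = 0))
  expect_equal(drifted$gamma_mJ_m2 - base$gamma_mJ_m2,
               -3.6 * base$time_s / 3600, tolerance = 1e-9)
})

test_that("induction extraction from noisy traces stays near the truth", {
  cfg <- quick_config(0.44, t_end_s = 900, dt_out_s = 5)
  clean <- simulate_adsorption(cfg)
  t_true <- extract_induction_time(clean)
  errs <- vapply(1:50, function(seed) {
    tr <- generate_trace(cfg, noise_model(sigma_mJ_m2 = 0.2, seed = seed))
    abs(extract_induction_time(tr) / t_true - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("induction dataset generator is exact, reproducible and guarded", {
  cs <- c(0.2, 0.44, 1.0)
  d0 <- generate_induction_dataset(cs, Gamma0_um2 = 24e3, noise_fraction = 0)
  expect_equal(d0$t_induction_s,
               vapply(cs, diffusion_limited_induction_time, numeric(1),
                      Gamma0_um2 = 24e3), tolerance = 1e-9)
  # round trip through the fitter
  expect_equal(fit_gamma0(d0)$estimate$Gamma0_um2, 24e3, tolerance = 1e-3)
  # seeded noise reproducibility
  d1 <- generate_induction_dataset(cs, noise_fraction = 0.2, seed = 7)
  d2 <- generate_induction_dataset(cs, noise_fraction = 0.2, seed = 7)
  expect_identical(d1$t_induction_s, d2$t_induction_s)
  # unattainable concentrations are dropped with a warning
  expect_warning(
    d3 <- generate_induction_dataset(c(0.01, 0.44), Gamma0_um2 = 24e3),
    "unattainable")
  expect_equal(d3$c_uM, 0.44)
})

test_that("area-step generator feeds the master curve round trip", {
  eos <- default_eos
  quiet <- noise_model(sigma_mJ_m2 = 0, relax_amplitude_mJ_m2 = 0)
  gen <- generate_area_step_experiment(eos, alpha_um2 = 2 * eos$Gamma0_um2,
                                       step_factors = rep(0.85, 4),
                                       noise = quiet)
  # zero relaxation: the transient plateau equals the instantaneous value
  expect_equal(unique(gen$transient$gamma_mJ_m2),
               gen$experiment$gamma_mJ_m2, tolerance = 1e-9)
  # two experiments with alpha ratio 3.02/1.80 = 1.68: recovered within 1%
  mk <- function(alpha, steps, seed) {
    generate_area_step_experiment(
      eos, alpha_um2 = alpha, step_factors = steps,
      noise = noise_model(sigma_mJ_m2 = 0, relax_amplitude_mJ_m2 = 0,
                          seed = seed))$experiment
  }
  e1 <- mk(3.02 * eos$Gamma0_um2, rep(0.82, 7), 1)
  e2 <- mk(1.80 * eos$Gamma0_um2, rep(0.85, 6), 2)
  mc <- build_master_curve(list(e1, e2), eos$gamma0_mJ_m2, eos$Gamma0_um2)
  r <- unname(mc$alpha_um2[1] / mc$alpha_um2[2])
  expect_equal(r, 3.02 / 1.80, tolerance = 0.01)
  # relaxation transient decays toward the plateau after a contraction
  noisy <- noise_model(sigma_mJ_m2 = 0, relax_amplitude_mJ_m2 = 2,
                       relax_timescale_s = 100)
  gen2 <- generate_area_step_experiment(eos, 2 * eos$Gamma0_um2,
                                        rep(0.85, 2), noise = noisy,
                                        dwell_s = 400)
  seg <- gen2$transient[gen2$transient$time_s >= 400 &
                          gen2$transient$time_s < 800, ]
  expect_lt(seg$gamma_mJ_m2[1], gen2$experiment$gamma_mJ_m2[2] - 1)
  expect_true(all(diff(seg$gamma_mJ_m2) > 0))
  # seed reproducibility of the noisy plateau table
  g1 <- generate_area_step_experiment(eos, 2 * eos$Gamma0_um2,
                                      rep(0.85, 3),
                                      noise_model(0.3, seed = 5))$experiment
  g2 <- generate_area_step_experiment(eos, 2 * eos$Gamma0_um2,
                                      rep(0.85, 3),
                                      noise_model(0.3, seed = 5))$experiment
  expect_identical(g1$gamma_mJ_m2, g2$gamma_mJ_m2)
})
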