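test_that("equation of state honours its three anchors", {
  eos <- default_eos
  # onset: Pi = 0 at and below Gamma0, continuous at Gamma0
  expect_identical(pi_of_excess(0, eos), 0)
  expect_identical(pi_of_excess(eos$Gamma0_um2, eos), 0)
  expect_lt(pi_of_excess(eos$Gamma0_um2 * (1 + 1e-9), eos), 1e-6)
  # saturation: Pi -> Pi_max = 22
  expect_equal(pi_of_excess(1e9, eos), 22, tolerance = 1e-3)
  # one-sided numerical modulus Gamma dPi/dGamma at 1.001 Gamma0 is E0 = 15
  G <- eos$Gamma0_um2 * 1.001
  dPi <- (pi_of_excess(G * 1.0001, eos) - pi_of_excess(G * 0.9999, eos)) /
    (G * 2e-4)
  expect_equal(G * dPi, 15, tolerance = 0.005)
  # gamma = gamma0 - Pi everywhere
  g_grid <- seq(0, 3e5, length.out = 50)
  expect_equal(gamma_of_excess(g_grid, eos),
               eos$gamma0_mJ_m2 - pi_of_excess(g_grid, eos))
})

test_that("Pi is non-decreasing and the modulus vanishes at high coverage", {
  eos <- default_eos
  g_grid <- seq(0, 1e6, length.out = 400)
  Pi <- pi_of_excess(g_grid, eos)
  expect_true(all(diff(Pi) >= 0))
  expect_true(all(Pi < eos$Pi_max_mJ_m2))
  # modulus Gamma dPi/dGamma -> 0 as the curve flattens
  modulus <- function(G) {
    G * (pi_of_excess(G * 1.001, eos) - pi_of_excess(G * 0.999, eos)) /
      (G * 0.002)
  }
  expect_lt(modulus(50 * eos$Gamma0_um2), 0.01 * modulus(1.01 * eos$Gamma0_um2))
})

test_that("excess_of_pi inverts pi_of_excess exactly", {
  eos <- default_eos
  expect_equal(excess_of_pi(0, eos), eos$Gamma0_um2)
  set.seed(31)
  Pi <- stats::runif(100, 0, eos$Pi_max_mJ_m2 * 0.9999)
  expect_equal(pi_of_excess(excess_of_pi(Pi, eos), eos), Pi,
               tolerance = 1e-10)
  # up to ~11 Gamma0; deeper in saturation 1 - Pi/Pi_max underflows and
  # the round trip is inherently ill-conditioned
  G <- eos$Gamma0_um2 * (1 + 10^stats::runif(100, -3, 1))
  expect_equal(excess_of_pi(pi_of_excess(G, eos), eos), G,
               tolerance = 1e-10)
  expect_error(excess_of_pi(eos$Pi_max_mJ_m2, eos), "Pi_max")
  expect_error(excess_of_pi(-1, eos), "non-negative")
})

test_that("area per molecule matches the printed anchors and decreases in Pi", {
  eos <- default_eos
  expect_equal(area_per_molecule_at(0, eos), 42, tolerance = 0.01)
  # at Gamma_collapse = 3.5 Gamma0 the area is ~12 nm^2
  Pi_collapse <- pi_of_excess(eos$Gamma_collapse_um2, eos)
  expect_equal(area_per_molecule_at(Pi_collapse, eos), 12, tolerance = 0.01)
  Pi_grid <- seq(0, 21.5, length.out = 60)
  expect_true(all(diff(area_per_molecule_at(Pi_grid, eos)) < 0))
})

test_that("a single anchor-spanning experiment is rescaled onto the truth", {
  eos <- default_eos
  alpha_true <- 2 * eos$Gamma0_um2
  # steps spanning the onset: A_r = 2 sits exactly at the onset coverage
  A_r <- c(4, 2.4, 2, 1.8, 1.6, 1.4, 1.2, 1, 0.85, 0.7, 0.6, 0.5)
  exps <- list(area_step_experiment(A_r, gamma_of_excess(alpha_true / A_r, eos),
                                    label = "a"))
  mc <- build_master_curve(exps, eos$gamma0_mJ_m2, eos$Gamma0_um2)
  expect_equal(unname(mc$alpha_um2), alpha_true, tolerance = 1e-9)
  expect_lt(mc$residual_norm, 1e-8)
})

test_that("two noiseless experiments recover the imposed scale ratio", {
  eos <- default_eos
  # scale ratio 2.36/1.80 between the two runs
  alphas <- eos$Gamma0_um2 * c(2.36, 1.80)
  A_r1 <- c(2.36, 2, 1.7, 1.4, 1.2, 1, 0.85, 0.7, 0.6)
  A_r2 <- c(1.8, 1.5, 1.3, 1.1, 1, 0.9, 0.8, 0.7)
  exps <- list(
    area_step_experiment(A_r1, gamma_of_excess(alphas[1] / A_r1, eos), "a"),
    area_step_experiment(A_r2, gamma_of_excess(alphas[2] / A_r2, eos), "b"))
  mc <- build_master_curve(exps, eos$gamma0_mJ_m2, eos$Gamma0_um2)
  ratio <- mc$alpha_um2[["a"]] / mc$alpha_um2[["b"]]
  expect_equal(ratio, 2.36 / 1.80, tolerance = 0.01)
})

test_that("noisy experiments recover alpha within 5% (Monte Carlo)", {
  eos <- default_eos
  alpha_true <- 2 * eos$Gamma0_um2
  A_r <- c(4, 2.4, 2, 1.8, 1.6, 1.4, 1.2, 1, 0.85, 0.7, 0.6, 0.5)
  g_clean <- gamma_of_excess(alpha_true / A_r, eos)
  set.seed(32)
  rel_err <- replicate(100, {
    g_noisy <- g_clean + stats::rnorm(length(g_clean), sd = 0.3)
    exps <- list(area_step_experiment(A_r, g_noisy, "a"))
    mc <- tryCatch(build_master_curve(exps, eos$gamma0_mJ_m2,
                                      eos$Gamma0_um2),
                   error = function(e) NULL)
    if (is.null(mc)) NA_real_ else abs(mc$alpha_um2[["a"]] / alpha_true - 1)
  })
  expect_lt(stats::median(rel_err, na.rm = TRUE), 0.05)
})

test_that("experiments with disjoint tension ranges are rejected", {
  eos <- default_eos
  # one experiment just past onset (gamma ~ 69-72), one deep in
  # compression (gamma ~ 51): no shared range, relative scale
  # unidentifiable
  A_r1 <- c(1.3, 1.1, 1)
  A_r2 <- c(1, 0.9, 0.8)
  e1 <- area_step_experiment(A_r1,
                             gamma_of_excess(1.3 * eos$Gamma0_um2 / A_r1, eos),
                             "near-onset")
  e2 <- area_step_experiment(A_r2,
                             gamma_of_excess(6 * eos$Gamma0_um2 / A_r2, eos),
                             "compressed")
  expect_error(build_master_curve(list(e1, e2)), "unidentifiable")
})
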