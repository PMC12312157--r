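#' Instrument noise model for synthetic traces
#'
#' Emulates the nuisance features of real tensiometer data: white
#' measurement noise, a slow linear drift, and the viscoelastic partial
#' relaxation transient seen after area steps. All generators driven by
#' this model are pure functions of (parameters, seed).
#'
#' @param sigma_mJ_m2 Gaussian noise s.d., mJ/m^2. Default 0.2.
#' @param drift_mJ_m2_h Linear drift, mJ/m^2 per hour. Default 0.
#' @param relax_amplitude_mJ_m2 Amplitude of the post-step relaxation
#'   overshoot, mJ/m^2. Default 2.
#' @param relax_timescale_s Relaxation timescale, s. Default 100.
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_mJ_m2 = 0.2, drift_mJ_m2_h = 0,
                        relax_amplitude_mJ_m2 = 2, relax_timescale_s = 100,
                        seed = 1L) {
  stopifnot(sigma_mJ_m2 >= 0, relax_timescale_s >= 0)
  structure(
    list(sigma_mJ_m2 = sigma_mJ_m2, drift_mJ_m2_h = drift_mJ_m2_h,
         relax_amplitude_mJ_m2 = relax_amplitude_mJ_m2,
         relax_timescale_s = relax_timescale_s, seed = as.integer(seed)),
    class = "noise_model"
  )
}

# evaluate fn under a local RNG state so generators are reproducible and
# do not disturb the caller's stream
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate a noisy synthetic tensiometry trace
#'
#' Forward-simulates gamma(t) with [simulate_adsorption()] and adds
#' Gaussian noise and optional drift. With zero noise the output equals
#' the simulator output exactly; with a fixed seed it is bit-reproducible.
#'
#' @param config A [simulation_config()].
#' @param noise A [noise_model()].
#' @return A [tensiometry_trace()].
#' @export
generate_trace <- function(config, noise = noise_model()) {
  trace <- simulate_adsorption(config)
  if (noise$sigma_mJ_m2 > 0 || noise$drift_mJ_m2_h != 0) {
    eps <- .with_seed(noise$seed, function() {
      stats::rnorm(nrow(trace), sd = noise$sigma_mJ_m2)
    })
    trace$gamma_mJ_m2 <- trace$gamma_mJ_m2 + eps +
      noise$drift_mJ_m2_h * trace$time_s / 3600
  }
  md <- attr(trace, "metadata")
  md$noise_sigma_mJ_m2 <- noise$sigma_mJ_m2
  md$noise_seed <- noise$seed
  attr(trace, "metadata") <- md
  trace
}

#' Generate a synthetic induction-time-vs-concentration dataset
#'
#' Diffusion-limited induction times at the requested concentrations,
#' multiplied by lognormal noise (median 1, log-sd `noise_fraction`).
#' Concentrations whose drops do not contain enough protein to reach
#' `Gamma0_um2` are dropped with a warning.
#'
#' @param c_uM Bulk concentrations, uM.
#' @param Gamma0_um2 Critical coverage, molecules/um^2.
#' @param D_um2_s Diffusion coefficient, um^2/s.
#' @param R_um Drop sphere radius, um.
#' @param noise_fraction Log-sd of the multiplicative noise (0 = exact).
#' @param seed Integer seed.
#' @return An [induction_dataset()].
#' @export
generate_induction_dataset <- function(c_uM, Gamma0_um2 = 24e3,
                                       D_um2_s = 45, R_um = 2100,
                                       noise_fraction = 0, seed = 1L) {
  stopifnot(all(c_uM > 0), noise_fraction >= 0)
  attainable <- molar_to_number_density(c_uM) * R_um / 3 > Gamma0_um2
  if (!all(attainable)) {
    warning(sprintf("dropping %d unattainable concentration(s): %s uM",
                    sum(!attainable),
                    paste(c_uM[!attainable], collapse = ", ")))
    c_uM <- c_uM[attainable]
  }
  if (length(c_uM) == 0L) stop("no attainable concentrations")
  t <- vapply(c_uM, diffusion_limited_induction_time, numeric(1),
              Gamma0_um2 = Gamma0_um2, D_um2_s = D_um2_s, R_um = R_um)
  if (noise_fraction > 0) {
    t <- t * .with_seed(seed, function() {
      stats::rlnorm(length(t), meanlog = 0, sdlog = noise_fraction)
    })
  }
  induction_dataset(c_uM, t,
                    provenance = sprintf("synthetic (seed %d)", seed))
}

#' Generate a synthetic area-step experiment
#'
#' Quasi-plateau surface tensions from the equation of state at
#' Gamma = alpha / A_r, plus a full transient trace in which each
#' contraction is followed by an exponentially decaying viscoelastic
#' overshoot (a nuisance transient, not equation-of-state data). The
#' plateau table is what [build_master_curve()] consumes.
#'
#' @param eos A [surface_eos()].
#' @param alpha_um2 True scale of the experiment: Gamma at relative
#'   area 1, molecules/um^2.
#' @param step_factors Multiplicative area changes applied sequentially
#'   (< 1 contracts).
#' @param noise A [noise_model()]; `sigma_mJ_m2` perturbs the plateau
#'   readings, `relax_*` shapes the transient.
#' @param dwell_s Time between steps in the transient trace, s.
#' @return List with `experiment` (an [area_step_experiment()]) and
#'   `transient` (a [tensiometry_trace()]).
#' @export
generate_area_step_experiment <- function(eos = surface_eos(),
                                          alpha_um2 = 2 * eos$Gamma0_um2,
                                          step_factors = rep(0.85, 4),
                                          noise = noise_model(),
                                          dwell_s = 300) {
  stopifnot(alpha_um2 > 0, all(step_factors > 0))
  A_r <- cumprod(c(1, step_factors))
  gamma_plateau <- gamma_of_excess(alpha_um2 / A_r, eos)
  eps <- .with_seed(noise$seed, function() {
    stats::rnorm(length(gamma_plateau), sd = noise$sigma_mJ_m2)
  })
  experiment <- area_step_experiment(A_r, gamma_plateau + eps,
                                     label = sprintf("synthetic-a%.3g",
                                                     alpha_um2))
  # transient trace: plateau levels joined by relaxation overshoots
  dt <- 1
  t_all <- NULL
  g_all <- NULL
  for (k in seq_along(A_r)) {
    tk <- seq(0, dwell_s - dt, by = dt) + (k - 1) * dwell_s
    gk <- rep(gamma_plateau[k], length(tk))
    if (k > 1L && noise$relax_amplitude_mJ_m2 > 0 &&
        noise$relax_timescale_s > 0 && step_factors[k - 1] < 1) {
      # contraction overshoot: instantaneous extra drop relaxing upward
      gk <- gk - noise$relax_amplitude_mJ_m2 *
        exp(-(tk - tk[1]) / noise$relax_timescale_s)
    }
    t_all <- c(t_all, tk)
    g_all <- c(g_all, gk)
  }
  transient <- tensiometry_trace(
    t_all, g_all,
    metadata = list(gamma0_mJ_m2 = eos$gamma0_mJ_m2,
                    alpha_um2 = alpha_um2, synthetic = TRUE))
  list(experiment = experiment, transient = transient)
}
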