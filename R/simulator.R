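#' Simulation configuration
#'
#' Bundles everything the forward model needs: drop geometry, protein
#' properties, the surface equation of state, barrier parameters, optional
#' isodesmic clustering, the initial bulk concentration and solver/output
#' controls.
#'
#' @param c_bulk_uM Initial uniform bulk concentration, uM.
#' @param geometry A [drop_geometry()].
#' @param protein A [protein_spec()].
#' @param eos A [surface_eos()].
#' @param barrier A [barrier_params()].
#' @param clustering An [isodesmic_params()] or `NULL` for a monomer-only
#'   run.
#' @param const A [physical_constants()].
#' @param t_end_s Simulated duration, s. Default 7200 (about 2 h).
#' @param dt_out_s Output interval, s. Default 1.
#' @param n_cells,h_surface_um Radial grid resolution (see
#'   [radial_grid()]).
#' @param rtol,atol Time-integration tolerances.
#' @param Gamma_init_um2 Pre-existing surface excess at t = 0,
#'   molecules/um^2 (e.g. a protein shell left on a buffer drop after a
#'   bulk exchange). Default 0.
#' @param seed Integer seed recorded for downstream noise generators.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(c_bulk_uM, geometry = drop_geometry(),
                              protein = protein_spec(), eos = surface_eos(),
                              barrier = barrier_params(), clustering = NULL,
                              const = physical_constants(),
                              t_end_s = 7200, dt_out_s = 1,
                              n_cells = 150, h_surface_um = 1,
                              rtol = 1e-8, atol = 1e-8,
                              Gamma_init_um2 = 0, seed = 1L) {
  stopifnot(c_bulk_uM >= 0, t_end_s > 0, dt_out_s > 0, Gamma_init_um2 >= 0)
  if (!is.null(clustering)) stopifnot(inherits(clustering, "isodesmic_params"))
  structure(
    list(c_bulk_uM = c_bulk_uM, geometry = geometry, protein = protein,
         eos = eos, barrier = barrier, clustering = clustering,
         const = const, t_end_s = t_end_s, dt_out_s = dt_out_s,
         n_cells = n_cells, h_surface_um = h_surface_um,
         rtol = rtol, atol = atol, Gamma_init_um2 = Gamma_init_um2,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Tensiometry trace container
#'
#' @param time_s Strictly increasing times, s.
#' @param gamma_mJ_m2 Surface tension, mJ/m^2.
#' @param Gamma_um2 Optional model surface excess, molecules/um^2.
#' @param area_mm2,volume_uL Optional drop area and volume columns.
#' @param metadata Named list of provenance entries.
#' @return A data.frame of class `tensiometry_trace`.
#' @export
tensiometry_trace <- function(time_s, gamma_mJ_m2, Gamma_um2 = NULL,
                              area_mm2 = NULL, volume_uL = NULL,
                              metadata = list()) {
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  stopifnot(length(gamma_mJ_m2) == length(time_s))
  out <- data.frame(time_s = time_s, gamma_mJ_m2 = gamma_mJ_m2)
  if (!is.null(Gamma_um2)) out$Gamma_um2 <- Gamma_um2
  if (!is.null(area_mm2)) out$area_mm2 <- rep_len(area_mm2, length(time_s))
  if (!is.null(volume_uL)) out$volume_uL <- rep_len(volume_uL, length(time_s))
  attr(out, "metadata") <- metadata
  class(out) <- c("tensiometry_trace", "data.frame")
  out
}

#' @export
print.tensiometry_trace <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Tensiometry trace: %d points, t = %.4g..%.4g s, gamma = %.2f..%.2f mJ/m^2\n",
              nrow(x), min(x$time_s), max(x$time_s),
              min(x$gamma_mJ_m2), max(x$gamma_mJ_m2)))
  if (length(md)) {
    cat("  metadata:", paste(names(md), unlist(lapply(md, format)),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Bin an isodesmic distribution into a manageable number of species
# classes for the PDE: exact sizes up to `n_exact`, then geometric bins.
# Each bin keeps its exact cluster number and monomer mass; the
# representative size nbar = mass/number enters the rate law (the n^s
# barrier factor varies negligibly within a bin for s = 1/20).
.bin_distribution <- function(dist, n_exact = 8, max_bins = 24) {
  n <- dist$n
  c_n <- dist$c_n
  if (max(n) <= n_exact) {
    keep <- c_n > 0
    return(list(nbar = n[keep], c_bin = c_n[keep]))
  }
  edges <- unique(c(seq_len(n_exact),
                    round(exp(seq(log(n_exact), log(max(n) + 1),
                                  length.out = max_bins - n_exact + 1)))))
  edges <- sort(unique(c(edges, max(n) + 1)))
  idx <- findInterval(n, edges)
  num <- tapply(c_n, idx, sum)
  mass <- tapply(n * c_n, idx, sum)
  keep <- num > 0
  list(nbar = as.numeric(mass[keep] / num[keep]),
       c_bin = as.numeric(num[keep]))
}

# Internal model state carried between protocol segments
.init_state <- function(config, c_uM = config$c_bulk_uM) {
  R_um <- config$geometry$radius_sphere_um
  grid <- radial_grid(R_um, config$n_cells, config$h_surface_um)
  c_tot <- molar_to_number_density(c_uM)
  if (is.null(config$clustering) || c_tot == 0) {
    nbar <- 1
    c_bin <- c_tot
  } else {
    b <- .bin_distribution(isodesmic_distribution(c_tot, config$clustering))
    nbar <- b$nbar
    c_bin <- b$c_bin
  }
  Gamma <- numeric(length(nbar))
  # any pre-existing layer is booked against the monomer-unit budget of
  # the first species class
  Gamma[1] <- config$Gamma_init_um2 / nbar[1]
  list(grid = grid, nbar = nbar,
       c = matrix(rep(c_bin, each = grid$n_cells), grid$n_cells,
                  length(nbar)),
       Gamma = Gamma,
       area_factor = 1)
}

.species_for <- function(config, state, c_uM) {
  # uniform profile of a fresh solution mapped onto the existing species
  # binning (bulk exchange keeps the species layout of the running model)
  c_tot <- molar_to_number_density(c_uM)
  if (length(state$nbar) == 1L && state$nbar[1] == 1) return(c_tot)
  if (c_tot == 0) return(numeric(length(state$nbar)))
  dist <- isodesmic_distribution(c_tot, config$clustering)
  # re-bin onto the same nbar classes by nearest representative size
  edges <- c(0, sqrt(state$nbar[-1] * state$nbar[-length(state$nbar)]), Inf)
  idx <- findInterval(dist$n, edges, rightmost.closed = TRUE)
  out <- numeric(length(state$nbar))
  num <- tapply(dist$c_n, idx, sum)
  mass <- tapply(dist$n * dist$c_n, idx, sum)
  j <- as.integer(names(num))
  # preserve monomer mass exactly: scale cluster numbers within each class
  out[j] <- as.numeric(mass) / state$nbar[j]
  out
}

# run one uninterrupted segment; returns updated state plus output rows
.run_segment <- function(config, state, t_grid, barrier_fn) {
  nbar <- state$nbar
  p <- config$barrier
  eos <- config$eos
  rate_fn <- function(Gam, c_surf) {
    Pi <- pi_of_excess(sum(nbar * Gam), eos)
    dg <- barrier_fn(Pi)
    # cluster-unit rates: one cluster adsorbed delivers nbar monomers
    p$B_um2_s * exp(-nbar^p$s * p$q * dg) * (c_surf / p$c_ref_um3)
  }
  sol <- solve_radial_pde(state$c, config$protein$diffusion_um2_s, rate_fn,
                          t_grid - t_grid[1], grid = state$grid,
                          Gamma0_um2 = state$Gamma,
                          rtol = config$rtol, atol = config$atol)
  n_t <- length(sol$t_s)
  Gamma_tot <- as.numeric(sol$Gamma_um2 %*% nbar)
  total <- as.numeric(sol$total_per_area_um2 %*% nbar)
  cons_err <- if (total[1] > 0) max(abs(total - total[1])) / total[1] else 0
  state$c <- matrix(sol$c_um3[n_t, , ], state$grid$n_cells, length(nbar))
  state$Gamma <- sol$Gamma_um2[n_t, ]
  list(state = state,
       rows = data.frame(time_s = t_grid, Gamma_um2 = Gamma_tot),
       conservation_error = cons_err)
}

.finish_trace <- function(config, rows, cons_err, extra_meta = list()) {
  af <- if (is.null(rows$area_factor)) rep(1, nrow(rows)) else rows$area_factor
  gamma <- gamma_of_excess(rows$Gamma_um2, config$eos)
  tensiometry_trace(
    rows$time_s, gamma, Gamma_um2 = rows$Gamma_um2,
    area_mm2 = config$geometry$area_mm2 * af,
    volume_uL = config$geometry$volume_uL * af^1.5,
    metadata = c(list(gamma0_mJ_m2 = config$eos$gamma0_mJ_m2,
                      c_bulk_uM = config$c_bulk_uM,
                      clustering = !is.null(config$clustering),
                      conservation_error = cons_err),
                 extra_meta)
  )
}

#' Simulate a dynamic surface tension trace
#'
#' Runs the coupled model: radial diffusion inside the drop, the
#' pressure-dependent barrier rate at the surface, and the equation of
#' state mapping the accumulated surface excess to surface tension.
#' Cluster contributions to the surface excess are pooled before the
#' mapping.
#'
#' @param config A [simulation_config()].
#' @return A [tensiometry_trace()] with the model `Gamma_um2` column.
#' @export
simulate_adsorption <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  state <- .init_state(config)
  barrier_fn <- .barrier_energy_fn(config$eos, config$barrier, config$const)
  t_grid <- seq(0, config$t_end_s, by = config$dt_out_s)
  seg <- .run_segment(config, state, t_grid, barrier_fn)
  .finish_trace(config, seg$rows, seg$conservation_error)
}

#' Simulate a bulk-exchange experiment
#'
#' The drop's bulk is exchanged through a coaxial capillary while the
#' adsorbed layer stays in place. Modelled as an instantaneous uniform
#' reset of all bulk concentrations at `exchange_time_s`; the surface
#' excess is retained (irreversible layer).
#'
#' @param config A [simulation_config()].
#' @param exchange_time_s Time of the exchange, s (< `t_end_s`).
#' @param new_c_uM Concentration of the replacement solution, uM
#'   (0 = pure buffer).
#' @return A [tensiometry_trace()]; conservation is tracked piecewise
#'   between exchanges.
#' @export
simulate_bulk_exchange <- function(config, exchange_time_s, new_c_uM) {
  stopifnot(inherits(config, "simulation_config"),
            exchange_time_s > 0, exchange_time_s < config$t_end_s,
            new_c_uM >= 0)
  state <- .init_state(config)
  barrier_fn <- .barrier_energy_fn(config$eos, config$barrier, config$const)
  t1 <- seq(0, exchange_time_s, by = config$dt_out_s)
  if (t1[length(t1)] < exchange_time_s) t1 <- c(t1, exchange_time_s)
  seg1 <- .run_segment(config, state, t1, barrier_fn)
  state <- seg1$state
  c_new <- .species_for(config, state, new_c_uM)
  state$c <- matrix(rep(c_new, each = state$grid$n_cells),
                    state$grid$n_cells, length(state$nbar))
  t2 <- seq(exchange_time_s, config$t_end_s, by = config$dt_out_s)
  if (t2[length(t2)] < config$t_end_s) t2 <- c(t2, config$t_end_s)
  seg2 <- .run_segment(config, state, t2, barrier_fn)
  rows <- rbind(seg1$rows, seg2$rows[-1, ])
  .finish_trace(config, rows,
                max(seg1$conservation_error, seg2$conservation_error),
                list(exchange_time_s = exchange_time_s,
                     new_c_uM = new_c_uM))
}

# remap a radial profile onto a new grid, preserving the distance from the
# surface (liquid is withdrawn/injected at the drop centre through the
# capillary; the boundary layer under the surface stays in place)
.remap_profile <- function(c_old, grid_old, grid_new) {
  depth_old <- grid_old$R_um - grid_old$centers_um
  depth_new <- grid_new$R_um - grid_new$centers_um
  out <- matrix(0, grid_new$n_cells, ncol(c_old))
  for (s in seq_len(ncol(c_old))) {
    out[, s] <- stats::approx(depth_old, c_old[, s], xout = depth_new,
                              rule = 2, ties = mean)$y
  }
  out
}

#' Simulate an area-step (contraction/expansion) experiment
#'
#' At each step time the drop area is multiplied by the corresponding
#' factor; the irreversibly adsorbed layer is compressed or diluted so
#' that Gamma scales with 1/area, the surface tension is recomputed from
#' the equation of state, and the bulk profile is carried over (preserving
#' depth below the surface) onto the resized drop. Steps are instantaneous;
#' the experimentally observed viscoelastic relaxation after a step is not
#' modelled here (the synthetic-data generator adds it as a nuisance).
#'
#' @param config A [simulation_config()].
#' @param step_times_s Increasing step times, s.
#' @param area_factors Multiplicative area changes (> 0), one per step;
#'   < 1 contracts, > 1 expands.
#' @return A [tensiometry_trace()] whose `area_mm2`/`volume_uL` columns
#'   follow the steps.
#' @export
simulate_area_step <- function(config, step_times_s, area_factors) {
  stopifnot(inherits(config, "simulation_config"),
            length(step_times_s) == length(area_factors),
            all(area_factors > 0), all(diff(c(0, step_times_s)) > 0),
            all(step_times_s < config$t_end_s))
  state <- .init_state(config)
  barrier_fn <- .barrier_energy_fn(config$eos, config$barrier, config$const)
  bounds <- c(0, step_times_s, config$t_end_s)
  rows <- NULL
  cons <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    tg <- seq(bounds[k], bounds[k + 1], by = config$dt_out_s)
    if (tg[length(tg)] < bounds[k + 1]) tg <- c(tg, bounds[k + 1])
    seg <- .run_segment(config, state, tg, barrier_fn)
    seg$rows$area_factor <- state$area_factor
    cons <- max(cons, seg$conservation_error)
    rows <- if (is.null(rows)) seg$rows else rbind(rows, seg$rows[-1, ])
    state <- seg$state
    if (k <= length(area_factors)) {
      f <- area_factors[k]
      state$Gamma <- state$Gamma / f
      new_af <- state$area_factor * f
      R_new <- config$geometry$radius_sphere_um * sqrt(new_af)
      grid_new <- radial_grid(R_new, config$n_cells,
                              min(config$h_surface_um, R_new / (2 * config$n_cells)))
      state$c <- .remap_profile(state$c, state$grid, grid_new)
      state$grid <- grid_new
      state$area_factor <- new_af
      # record the instantaneous post-step value
      rows[nrow(rows), "Gamma_um2"] <- sum(state$nbar * state$Gamma)
      rows[nrow(rows), "area_factor"] <- new_af
    }
  }
  .finish_trace(config, rows, cons,
                list(step_times_s = paste(step_times_s, collapse = ";"),
                     area_factors = paste(area_factors, collapse = ";")))
}

.trace_gamma0 <- function(trace, gamma0 = NULL) {
  if (!is.null(gamma0)) return(gamma0)
  md <- attr(trace, "metadata")
  if (!is.null(md$gamma0_mJ_m2)) md$gamma0_mJ_m2 else 72.0
}

#' Induction time of a trace
#'
#' The first time at which the surface tension has dropped by `threshold`
#' below the clean-surface value, located by linear interpolation between
#' samples.
#'
#' @param trace A [tensiometry_trace()] (>= 2 points).
#' @param threshold_mJ_m2 Drop below gamma0 defining the induction time.
#'   Default 1.5 mJ/m^2.
#' @param gamma0_mJ_m2 Clean-surface tension; defaults to the trace
#'   metadata, else 72.0.
#' @return Induction time in s, or `NA_real_` if the threshold is never
#'   crossed.
#' @export
extract_induction_time <- function(trace, threshold_mJ_m2 = 1.5,
                                   gamma0_mJ_m2 = NULL) {
  stopifnot(nrow(trace) >= 2L)
  g0 <- .trace_gamma0(trace, gamma0_mJ_m2)
  target <- g0 - threshold_mJ_m2
  below <- which(trace$gamma_mJ_m2 < target)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(trace$time_s[1])
  t0 <- trace$time_s[i - 1]; t1 <- trace$time_s[i]
  g0i <- trace$gamma_mJ_m2[i - 1]; g1 <- trace$gamma_mJ_m2[i]
  t0 + (t1 - t0) * (g0i - target) / (g0i - g1)
}

#' Semistable surface tension of a trace
#'
#' The surface tension at the first time after the induction time at which
#' the magnitude of the smoothed rate of change falls below
#' `rate_threshold` (mJ/m^2 per hour). The rate is a centred difference of
#' the trace interpolated over a window.
#'
#' @param trace A [tensiometry_trace()].
#' @param rate_threshold_mJ_m2_h Rate threshold, mJ/m^2 per hour.
#'   Default 2.5.
#' @param window_s Width of the centred-difference window, s. Default 100.
#' @param gamma0_mJ_m2 Clean-surface tension override.
#' @return Semistable gamma in mJ/m^2, or `NA_real_` if the rate never
#'   falls below the threshold (or there is no induction crossing).
#' @export
extract_semistable_gamma <- function(trace, rate_threshold_mJ_m2_h = 2.5,
                                     window_s = 100, gamma0_mJ_m2 = NULL) {
  t_ind <- extract_induction_time(trace, gamma0_mJ_m2 = gamma0_mJ_m2)
  if (is.na(t_ind)) return(NA_real_)
  t <- trace$time_s
  g <- trace$gamma_mJ_m2
  cand <- which(t > t_ind & t - window_s / 2 >= t[1] &
                  t + window_s / 2 <= t[length(t)])
  if (length(cand) < 3L) return(NA_real_)
  g_lo <- stats::approx(t, g, xout = t[cand] - window_s / 2, ties = mean)$y
  g_hi <- stats::approx(t, g, xout = t[cand] + window_s / 2, ties = mean)$y
  rate_h <- abs(g_hi - g_lo) / window_s * 3600
  ok <- which(rate_h < rate_threshold_mJ_m2_h)
  if (length(ok) == 0L) return(NA_real_)
  g[cand[ok[1]]]
}

#' Normalise a trace's time axis by its induction time
#'
#' @inheritParams extract_induction_time
#' @return The trace with `time_s` replaced by t / t_induction (the
#'   threshold crossing sits at scaled time 1); errors if no induction
#'   time exists.
#' @export
scaled_time_trace <- function(trace, threshold_mJ_m2 = 1.5,
                              gamma0_mJ_m2 = NULL) {
  t_ind <- extract_induction_time(trace, threshold_mJ_m2, gamma0_mJ_m2)
  if (is.na(t_ind) || t_ind <= 0) {
    stop("trace has no positive induction time; cannot rescale")
  }
  out <- trace
  out$time_s <- trace$time_s / t_ind
  md <- attr(out, "metadata")
  md$time_scaled_by_s <- t_ind
  attr(out, "metadata") <- md
  out
}
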