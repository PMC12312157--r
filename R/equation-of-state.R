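#' Surface equation of state
#'
#' Empirical surface pressure - surface excess relation of the adsorbed
#' film. Below the critical coverage Gamma0 the film is in a two-phase
#' (gas + condensed) region and the surface pressure is zero; above it the
#' pressure rises with a 2D bulk elastic modulus E0 at onset and saturates
#' at Pi_max as the film approaches collapse. The default family is a
#' saturating exponential
#'   Pi(Gamma) = Pi_max * (1 - exp(-(E0/Pi_max) * (Gamma/Gamma0 - 1)))
#' which satisfies the three anchors exactly: Pi(Gamma0) = 0, modulus
#' Gamma dPi/dGamma = E0 at Gamma0, and Pi -> Pi_max as Gamma -> Inf.
#'
#' @param gamma0_mJ_m2 Clean-interface surface tension, mJ/m^2.
#'   Default 72.0 (buffer at room temperature).
#' @param Gamma0_um2 Critical coverage at the end of the induction time,
#'   molecules/um^2. Default 24e3.
#' @param E0_mJ_m2 2D bulk elastic modulus at Gamma0, mJ/m^2. Default 15.
#' @param Pi_max_mJ_m2 Maximum surface pressure, mJ/m^2. Default 22.
#' @param Gamma_collapse_um2 Coverage at which the film approaches its
#'   maximum pressure, molecules/um^2. Default 3.5 * Gamma0.
#' @return An object of class `surface_eos`.
#' @export
surface_eos <- function(gamma0_mJ_m2 = 72.0, Gamma0_um2 = 24e3,
                        E0_mJ_m2 = 15, Pi_max_mJ_m2 = 22,
                        Gamma_collapse_um2 = 3.5 * Gamma0_um2) {
  stopifnot(gamma0_mJ_m2 > 0, Gamma0_um2 > 0, E0_mJ_m2 > 0,
            Pi_max_mJ_m2 > 0, Gamma_collapse_um2 > Gamma0_um2)
  structure(
    list(gamma0_mJ_m2 = gamma0_mJ_m2, Gamma0_um2 = Gamma0_um2,
         E0_mJ_m2 = E0_mJ_m2, Pi_max_mJ_m2 = Pi_max_mJ_m2,
         Gamma_collapse_um2 = Gamma_collapse_um2),
    class = "surface_eos"
  )
}

#' @export
print.surface_eos <- function(x, ...) {
  cat(sprintf(
    paste0("Surface equation of state: gamma0 = %.1f mJ/m^2, ",
           "Gamma0 = %.3g/um^2, E0 = %.3g mJ/m^2, Pi_max = %.3g mJ/m^2, ",
           "Gamma_collapse = %.3g/um^2\n"),
    x$gamma0_mJ_m2, x$Gamma0_um2, x$E0_mJ_m2, x$Pi_max_mJ_m2,
    x$Gamma_collapse_um2))
  invisible(x)
}

#' Surface pressure at a given surface excess
#'
#' @param Gamma_um2 Surface excess, molecules/um^2 (non-negative, vector ok).
#' @param eos A [surface_eos()].
#' @return Surface pressure Pi in mJ/m^2.
#' @export
pi_of_excess <- function(Gamma_um2, eos = surface_eos()) {
  if (any(Gamma_um2 < 0)) stop("surface excess must be non-negative")
  out <- numeric(length(Gamma_um2))
  above <- Gamma_um2 > eos$Gamma0_um2
  k <- eos$E0_mJ_m2 / eos$Pi_max_mJ_m2
  out[above] <- eos$Pi_max_mJ_m2 *
    (1 - exp(-k * (Gamma_um2[above] / eos$Gamma0_um2 - 1)))
  out
}

#' Surface excess at a given surface pressure
#'
#' Analytic inverse of [pi_of_excess()] on the one-phase branch. By
#' convention Pi = 0 maps to the onset coverage Gamma0.
#'
#' @param Pi_mJ_m2 Surface pressure, mJ/m^2; must lie in [0, Pi_max).
#' @param eos A [surface_eos()].
#' @return Surface excess in molecules/um^2.
#' @export
excess_of_pi <- function(Pi_mJ_m2, eos = surface_eos()) {
  if (any(Pi_mJ_m2 < 0)) stop("surface pressure must be non-negative")
  if (any(Pi_mJ_m2 >= eos$Pi_max_mJ_m2))
    stop("surface pressure at or above Pi_max has no finite coverage")
  k <- eos$E0_mJ_m2 / eos$Pi_max_mJ_m2
  eos$Gamma0_um2 * (1 - log(1 - Pi_mJ_m2 / eos$Pi_max_mJ_m2) / k)
}

#' Surface tension at a given surface excess
#'
#' gamma(Gamma) = gamma0 - Pi(Gamma).
#'
#' @inheritParams pi_of_excess
#' @return Surface tension in mJ/m^2.
#' @export
gamma_of_excess <- function(Gamma_um2, eos = surface_eos()) {
  eos$gamma0_mJ_m2 - pi_of_excess(Gamma_um2, eos)
}

#' Area per molecule at a given surface pressure
#'
#' @inheritParams excess_of_pi
#' @return Area per molecule in nm^2; strictly decreasing in Pi.
#' @examples
#' area_per_molecule_at(0)  # ~42 nm^2 at the onset coverage
#' @export
area_per_molecule_at <- function(Pi_mJ_m2, eos = surface_eos()) {
  1e6 / excess_of_pi(Pi_mJ_m2, eos)
}

#' Area-step (contraction/expansion) experiment
#'
#' Quasi-plateau surface tension readings after stepwise changes of the
#' drop area. On the timescale of a step the adsorbed layer is effectively
#' irreversible, so the surface excess scales as alpha / A_r with A_r the
#' relative area and alpha an unknown per-experiment scale.
#'
#' @param A_r Relative drop areas (dimensionless, > 0).
#' @param gamma_mJ_m2 Surface tension at the post-step quasi-plateau.
#' @param label Experiment label.
#' @return An object of class `area_step_experiment` (a data.frame with
#'   attribute `label`).
#' @export
area_step_experiment <- function(A_r, gamma_mJ_m2, label = "exp") {
  stopifnot(length(A_r) == length(gamma_mJ_m2), all(A_r > 0))
  out <- data.frame(A_r = A_r, gamma_mJ_m2 = gamma_mJ_m2)
  attr(out, "label") <- label
  class(out) <- c("area_step_experiment", "data.frame")
  out
}

# piecewise-linear interpolant of a fitted monotone curve, with constant
# extrapolation beyond the data range
.curve_interp <- function(curve, Gamma) {
  stats::approx(curve$Gamma_um2, curve$gamma_mJ_m2, xout = Gamma,
                rule = 2, ties = mean)$y
}

# fit a monotone non-increasing gamma(Gamma) through pooled points by
# isotonic regression of -gamma against Gamma
.fit_monotone_curve <- function(Gamma, gamma) {
  o <- order(Gamma)
  fit <- stats::isoreg(Gamma[o], -gamma[o])
  agg <- stats::aggregate(list(gamma_mJ_m2 = -fit$yf),
                          by = list(Gamma_um2 = Gamma[o]), FUN = mean)
  agg[order(agg$Gamma_um2), ]
}

#' Merge area-step experiments into a master surface tension curve
#'
#' Each experiment determines surface tension as a function of
#' Gamma = alpha_x / A_r up to its unknown scale alpha_x. The scales are
#' found by alternating between (i) an isotonic (monotone non-increasing)
#' fit of gamma against pooled Gamma and (ii) per-experiment refit of
#' alpha_x against the current curve, until convergence. The absolute
#' scale is fixed by anchoring the merged curve's departure from the clean
#' surface tension gamma0 at the onset coverage Gamma0.
#'
#' @param experiments List of [area_step_experiment()]s (>= 2 steps each).
#' @param gamma0_mJ_m2 Clean-interface tension used as the onset anchor.
#' @param Gamma0_um2 Onset coverage used as the onset anchor.
#' @param max_iter,tol Iteration controls for the alternating fit.
#' @return An object of class `master_curve`: list with `alpha_um2` (named
#'   per-experiment scales), `curve` (data.frame Gamma_um2, gamma_mJ_m2 of
#'   merged points) and `residual_norm`.
#' @export
build_master_curve <- function(experiments, gamma0_mJ_m2 = 72.0,
                               Gamma0_um2 = 24e3, max_iter = 200,
                               tol = 1e-10) {
  stopifnot(length(experiments) >= 1L)
  for (e in experiments) {
    stopifnot(inherits(e, "area_step_experiment"))
    if (nrow(e) < 2L) stop("each experiment needs at least 2 steps")
  }
  labels <- vapply(seq_along(experiments), function(i) {
    lab <- attr(experiments[[i]], "label")
    if (is.null(lab)) sprintf("exp%d", i) else lab
  }, character(1))

  # experiments must share gamma range pairwise-connectedly, else the
  # relative scales are unidentifiable
  if (length(experiments) > 1L) {
    rng <- lapply(experiments, function(e) range(e$gamma_mJ_m2))
    n <- length(experiments)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- rng[[i]][1] <= rng[[j]][2] + 0.5 &&
        rng[[j]][1] <= rng[[i]][2] + 0.5
    }
    comp <- seq_len(n)
    repeat {
      new_comp <- comp
      for (i in seq_len(n)) new_comp[i] <- min(comp[adj[i, ]])
      if (identical(new_comp, comp)) break
      comp <- new_comp
    }
    if (length(unique(comp)) > 1L) {
      stop(sprintf(
        "unidentifiable scale: experiments {%s} share no surface tension range with the rest",
        paste(labels[comp != comp[1]], collapse = ", ")))
    }
  }

  # initial scales: put each experiment's unit area at the onset coverage
  alpha <- rep(Gamma0_um2, length(experiments))
  refit_alpha <- function(e, curve, a_start) {
    obj <- function(log_a) {
      G <- exp(log_a) / e$A_r
      sum((e$gamma_mJ_m2 - .curve_interp(curve, G))^2)
    }
    opt <- stats::optimize(obj, interval = log(a_start) + c(-3, 3))
    exp(opt$minimum)
  }
  prev <- alpha
  for (iter in seq_len(max_iter)) {
    G_all <- unlist(mapply(function(e, a) a / e$A_r, experiments, alpha,
                           SIMPLIFY = FALSE))
    g_all <- unlist(lapply(experiments, function(e) e$gamma_mJ_m2))
    curve <- .fit_monotone_curve(G_all, g_all)
    if (length(experiments) > 1L) {
      alpha <- mapply(refit_alpha, experiments, MoreArgs = list(curve = curve),
                      a_start = alpha)
      # normalise the gauge freedom: keep geometric mean of scales fixed
      alpha <- alpha * exp(mean(log(prev)) - mean(log(alpha)))
    }
    if (max(abs(log(alpha / prev))) < tol) break
    prev <- alpha
  }

  # fix the absolute scale by the onset anchor: the merged curve must
  # leave gamma = gamma0 at Gamma = Gamma0
  G_all <- unlist(mapply(function(e, a) a / e$A_r, experiments, alpha,
                         SIMPLIFY = FALSE))
  g_all <- unlist(lapply(experiments, function(e) e$gamma_mJ_m2))
  curve <- .fit_monotone_curve(G_all, g_all)
  G_onset <- .onset_coverage(curve, gamma0_mJ_m2)
  s <- Gamma0_um2 / G_onset
  alpha <- alpha * s
  curve$Gamma_um2 <- curve$Gamma_um2 * s

  G_all <- G_all * s
  resid <- g_all - .curve_interp(curve, G_all)
  structure(
    list(alpha_um2 = stats::setNames(alpha, labels), curve = curve,
         residual_norm = sqrt(sum(resid^2)), iterations = iter),
    class = "master_curve"
  )
}

# coverage at which a fitted monotone non-increasing curve leaves gamma0.
# The curve is located where it crosses gamma0 - 0.75 mJ/m^2 (a level
# below plateau noise); if the left end of the crossing segment still sits
# on the plateau (within 0.4 mJ/m^2 of gamma0) that point is the onset,
# otherwise the segment is extended linearly up to gamma0. When the
# plateau was never sampled the first decreasing segment is extrapolated.
.onset_coverage <- function(curve, gamma0) {
  G <- curve$Gamma_um2
  g <- curve$gamma_mJ_m2
  i <- which(g < gamma0 - 0.75)[1]
  if (is.na(i)) stop("curve never leaves gamma0; onset undefined")
  if (i == 1L) {
    j <- which(g < g[1] - 1e-9)[1]
    if (is.na(j)) stop("degenerate curve; onset undefined")
    return(G[1] + (G[j] - G[1]) * (gamma0 - g[1]) / (g[j] - g[1]))
  }
  if (g[i - 1] >= gamma0 - 0.4) return(G[i - 1])
  G[i - 1] + (G[i] - G[i - 1]) * (gamma0 - g[i - 1]) / (g[i] - g[i - 1])
}

#' @export
print.master_curve <- function(x, ...) {
  cat("Master curve from", length(x$alpha_um2), "area-step experiment(s)\n")
  cat("  alpha (molecules/um^2):",
      paste(sprintf("%s = %.4g", names(x$alpha_um2), x$alpha_um2),
            collapse = ", "), "\n")
  cat(sprintf("  residual norm %.4g after %d iteration(s)\n",
              x$residual_norm, x$iterations))
  invisible(x)
}
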