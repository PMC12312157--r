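#' Induction-time dataset
#'
#' @param c_uM Bulk concentrations, uM (> 0).
#' @param t_induction_s Measured induction times, s (>= 0).
#' @param provenance Free-text provenance.
#' @return A data.frame of class `induction_dataset`.
#' @export
induction_dataset <- function(c_uM, t_induction_s, provenance = "") {
  stopifnot(length(c_uM) == length(t_induction_s),
            all(c_uM > 0), all(t_induction_s >= 0))
  out <- data.frame(c_uM = c_uM, t_induction_s = t_induction_s)
  attr(out, "provenance") <- provenance
  class(out) <- c("induction_dataset", "data.frame")
  out
}

.fit_result <- function(estimate, residual_norm, converged, details = list()) {
  structure(
    c(list(estimate = estimate, residual_norm = residual_norm,
           converged = converged), details),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result:\n")
  for (nm in names(x$estimate)) {
    cat(sprintf("  %s = %.6g\n", nm, x$estimate[[nm]]))
  }
  cat(sprintf("  residual norm = %.4g, converged = %s\n",
              x$residual_norm, x$converged))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Fit the critical coverage from induction times
#'
#' Least squares in log time between observed induction times and the
#' diffusion-limited prediction of [diffusion_limited_induction_time()],
#' over the single parameter Gamma0. Log residuals are used because
#' induction times span orders of magnitude across a concentration ladder.
#'
#' @param data An [induction_dataset()] (or data.frame with columns
#'   `c_uM`, `t_induction_s`).
#' @param D_um2_s Diffusion coefficient, um^2/s.
#' @param R_um Drop sphere radius, um.
#' @return A `fit_result` with estimate `Gamma0_um2`.
#' @export
fit_gamma0 <- function(data, D_um2_s = 45, R_um = 2100) {
  stopifnot(nrow(data) >= 1L, all(c("c_uM", "t_induction_s") %in% names(data)))
  keep <- data$t_induction_s > 0
  if (!any(keep)) stop("no usable rows (all induction times are zero)")
  d <- data[keep, ]
  upper <- 0.999 * min(molar_to_number_density(d$c_uM)) * R_um / 3
  obj <- function(Gamma0) {
    pred <- vapply(d$c_uM, diffusion_limited_induction_time,
                   numeric(1), Gamma0_um2 = Gamma0,
                   D_um2_s = D_um2_s, R_um = R_um)
    sum((log(pred) - log(d$t_induction_s))^2)
  }
  opt <- stats::optimize(obj, interval = c(upper * 1e-6, upper),
                         tol = upper * 1e-8)
  .fit_result(list(Gamma0_um2 = opt$minimum), sqrt(opt$objective),
              converged = TRUE,
              details = list(n_points = nrow(d),
                             D_um2_s = D_um2_s, R_um = R_um))
}

#' Fit the barrier parameters (B, q) to surface tension traces
#'
#' Minimises the summed squared deviation between simulated and observed
#' gamma(t), trapezoid-weighted over each trace's time grid, over
#' (log B, q) with q constrained to [0, 1]. Full curves are compared
#' rather than extracted features, because the features alone leave (B, q)
#' weakly identified. Derivative-free Nelder-Mead search restarted from
#' three starting points; failed simulations at candidate parameters are
#' penalised, not fatal.
#'
#' @param traces List of [tensiometry_trace()]s.
#' @param c_uM Bulk concentration of each trace, uM.
#' @param config Template [simulation_config()] fixing everything except
#'   (B, q); its resolution settings are reused for the candidate
#'   simulations.
#' @param start Named vector with starting `B_um2_s` and `q`.
#' @param fix_q Optional: hold q at this value and fit B alone (a 1D
#'   profile of the objective).
#' @return A `fit_result` with estimates `B_um2_s` and `q`. With traces at
#'   a single concentration the convergence flag carries a weak-
#'   identifiability note.
#' @export
fit_barrier_params <- function(traces, c_uM, config,
                               start = c(B_um2_s = 5e4, q = 0.2),
                               fix_q = NULL) {
  stopifnot(length(traces) >= 1L, length(c_uM) == length(traces))
  note <- NULL
  if (length(unique(c_uM)) < 2L) {
    note <- "traces at a single concentration: (B, q) weakly identified"
    warning(note)
  }
  weights <- lapply(traces, function(tr) {
    t <- tr$time_s
    w <- c(diff(t), 0) / 2 + c(0, diff(t)) / 2  # trapezoid weights
    w / sum(w)
  })
  obj <- function(par) {
    B <- exp(par[1])
    q <- par[2]
    if (q < 0 || q > 1) return(1e8 * (1 + abs(q)))
    tot <- 0
    for (i in seq_along(traces)) {
      cfg <- config
      cfg$c_bulk_uM <- c_uM[i]
      cfg$barrier <- barrier_params(B_um2_s = B, q = q,
                                    s = config$barrier$s,
                                    c_ref_um3 = config$barrier$c_ref_um3,
                                    a0_nm2 = config$barrier$a0_nm2)
      cfg$t_end_s <- max(traces[[i]]$time_s)
      sim <- tryCatch(simulate_adsorption(cfg), error = function(e) NULL)
      if (is.null(sim)) return(1e8)
      g_sim <- stats::approx(sim$time_s, sim$gamma_mJ_m2,
                             xout = traces[[i]]$time_s, rule = 2,
                             ties = mean)$y
      tot <- tot + sum(weights[[i]] * (g_sim - traces[[i]]$gamma_mJ_m2)^2)
    }
    tot
  }
  if (!is.null(fix_q)) {
    opt <- stats::optimize(function(lb) obj(c(lb, fix_q)),
                           interval = log(start[["B_um2_s"]]) + c(-4, 4),
                           tol = 1e-7)
    return(.fit_result(list(B_um2_s = exp(opt$minimum), q = fix_q),
                       sqrt(opt$objective), converged = TRUE,
                       details = list(note = note,
                                      objective = opt$objective)))
  }
  starts <- list(c(log(start[["B_um2_s"]]), start[["q"]]),
                 c(log(start[["B_um2_s"]]) + 1.2, 0.9 * start[["q"]]),
                 c(log(start[["B_um2_s"]]) - 1.2, 1.25 * start[["q"]]))
  best <- NULL
  for (p0 in starts) {
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-7, maxit = 200))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  .fit_result(list(B_um2_s = exp(best$par[1]), q = best$par[2]),
              sqrt(best$value), converged = best$convergence == 0,
              details = list(note = note, objective = best$value))
}
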