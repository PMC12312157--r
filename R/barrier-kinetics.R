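#' Adsorption barrier parameters
#'
#' Parameters of the surface-pressure-dependent activation barrier for
#' adsorption. The rate prefactor B carries the published units
#' (molecules um^-2 s^-1 at unit relative concentration) because the
#' chemical-potential factor exp((mu - mu0)/kT) reduces to c/c_ref in the
#' ideal-dilute approximation, with the standard state fixed at
#' c_ref = 1 molecule/um^3.
#'
#' @param B_um2_s Rate prefactor, molecules um^-2 s^-1 per unit relative
#'   concentration. Default 70e3.
#' @param q Dimensionless fraction of the free-energy barrier felt at the
#'   transition state, in [0, 1]. Default 0.15.
#' @param s Cluster-size scaling exponent of the barrier
#'   (barrier multiplier n^s). Default 1/20.
#' @param c_ref_um3 Standard-state number density, molecules/um^3.
#'   Default 1.
#' @param a0_nm2 Uncompressed molecular footprint area, nm^2. `NULL`
#'   (default) means the area per molecule at the onset coverage of the
#'   equation of state in use.
#' @return An object of class `barrier_params`.
#' @export
barrier_params <- function(B_um2_s = 70e3, q = 0.15, s = 1 / 20,
                           c_ref_um3 = 1, a0_nm2 = NULL) {
  stopifnot(B_um2_s > 0, q >= 0, q <= 1, s >= 0, c_ref_um3 > 0)
  structure(
    list(B_um2_s = B_um2_s, q = q, s = s, c_ref_um3 = c_ref_um3,
         a0_nm2 = a0_nm2),
    class = "barrier_params"
  )
}

.a0_nm2 <- function(params, eos) {
  if (is.null(params$a0_nm2)) 1e6 / eos$Gamma0_um2 else params$a0_nm2
}

#' Cavitation free energy
#'
#' Work of opening a molecule-sized cavity in the surface layer against
#' its surface pressure: dG_cav = Pi * a(Pi), where a(Pi) is the area per
#' molecule at that pressure — the cavity shrinks as the film compresses.
#'
#' @param Pi_mJ_m2 Surface pressure, mJ/m^2, in [0, Pi_max).
#' @param eos A [surface_eos()].
#' @param const A [physical_constants()].
#' @return Free energy in units of kT.
#' @export
delta_g_cav <- function(Pi_mJ_m2, eos = surface_eos(),
                        const = physical_constants()) {
  a_nm2 <- area_per_molecule_at(Pi_mJ_m2, eos)
  # mJ/m^2 * nm^2 = 1e-3 J/m^2 * 1e-18 m^2 = 1e-21 J
  Pi_mJ_m2 * a_nm2 * 1e-21 / const$kBT_J
}

#' Compression free energy
#'
#' Isothermal work of compressing the incoming molecule from its
#' uncompressed footprint a0 down to the area per molecule a(Pi) of the
#' surface layer, along the equation of state:
#' dG_comp = integral from a(Pi) to a0 of Pi(a') da'.
#'
#' @inheritParams delta_g_cav
#' @param params A [barrier_params()] (supplies a0).
#' @return Free energy in units of kT.
#' @export
delta_g_comp <- function(Pi_mJ_m2, eos = surface_eos(),
                         params = barrier_params(),
                         const = physical_constants()) {
  a0 <- .a0_nm2(params, eos)
  vapply(Pi_mJ_m2, function(Pi) {
    if (Pi < 0 || Pi >= eos$Pi_max_mJ_m2) stop("Pi outside [0, Pi_max)")
    a_Pi <- area_per_molecule_at(Pi, eos)
    if (a_Pi >= a0) return(0)
    w <- stats::integrate(function(a_nm2) pi_of_excess(1e6 / a_nm2, eos),
                          lower = a_Pi, upper = a0, rel.tol = 1e-8)$value
    w * 1e-21 / const$kBT_J
  }, numeric(1))
}

#' Total activation barrier (cavitation + compression)
#'
#' @inheritParams delta_g_comp
#' @return dG_cav + dG_comp in units of kT.
#' @export
barrier_free_energy <- function(Pi_mJ_m2, eos = surface_eos(),
                                params = barrier_params(),
                                const = physical_constants()) {
  delta_g_cav(Pi_mJ_m2, eos, const) +
    delta_g_comp(Pi_mJ_m2, eos, params, const)
}

# fast barrier evaluator: spline of dG(Pi) on a fixed grid, built once per
# simulation; quadrature at every ODE step would dominate the runtime
.barrier_energy_fn <- function(eos, params, const, n_knots = 400) {
  Pi_grid <- seq(0, eos$Pi_max_mJ_m2 * (1 - 1e-9), length.out = n_knots)
  dg <- delta_g_cav(Pi_grid, eos, const) +
    delta_g_comp(Pi_grid, eos, params, const)
  stats::splinefun(Pi_grid, dg, method = "hyman")
}

#' Monomer adsorption rate
#'
#' The surface-pressure-limited rate law
#'   dGamma/dt = B exp(-q (dG_comp + dG_cav)/kT) * (c/c_ref),
#' with Pi determined from the current coverage through the equation of
#' state. Adsorption is fully irreversible: the rate is never negative.
#'
#' @param Gamma_um2 Current total surface excess, molecules/um^2.
#' @param c_surface_um3 Bulk number density just below the surface,
#'   molecules/um^3.
#' @param params A [barrier_params()].
#' @param eos A [surface_eos()].
#' @param const A [physical_constants()].
#' @return Adsorption rate dGamma/dt in molecules um^-2 s^-1.
#' @export
adsorption_rate <- function(Gamma_um2, c_surface_um3,
                            params = barrier_params(), eos = surface_eos(),
                            const = physical_constants()) {
  if (any(c_surface_um3 < 0)) stop("concentration must be non-negative")
  Pi <- pi_of_excess(Gamma_um2, eos)
  dg <- barrier_free_energy(Pi, eos, params, const)
  params$B_um2_s * exp(-params$q * dg) * (c_surface_um3 / params$c_ref_um3)
}

#' Cluster-resolved adsorption rate
#'
#' Extends the monomer rate law to a population of clusters: a cluster of
#' n monomers delivers n monomers at once, with a barrier scaled by the
#' very weak factor n^s (default s = 1/20):
#'   dGamma/dt = sum_n n B exp(-n^s q dG/kT) (c_n/c_ref).
#' With only n = 1 populated this reduces exactly to [adsorption_rate()].
#'
#' @param Gamma_um2 Current total surface excess (monomer units),
#'   molecules/um^2.
#' @param c_n_um3 Per-size cluster number densities at the surface,
#'   molecules/um^3, for sizes `n`.
#' @param n Cluster sizes (monomers per cluster) matching `c_n_um3`.
#' @inheritParams adsorption_rate
#' @return List with `total` (monomer-unit dGamma/dt, um^-2 s^-1) and
#'   `per_size` (monomer-unit rates per size class).
#' @export
cluster_adsorption_rate <- function(Gamma_um2, c_n_um3, n = seq_along(c_n_um3),
                                    params = barrier_params(),
                                    eos = surface_eos(),
                                    const = physical_constants()) {
  if (any(c_n_um3 < 0)) stop("concentrations must be non-negative")
  stopifnot(length(n) == length(c_n_um3), all(n >= 1))
  Pi <- pi_of_excess(Gamma_um2, eos)
  dg <- barrier_free_energy(Pi, eos, params, const)
  per_size <- n * params$B_um2_s * exp(-n^params$s * params$q * dg) *
    (c_n_um3 / params$c_ref_um3)
  list(total = sum(per_size), per_size = per_size)
}
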