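#' Physical constants
#'
#' Bundles Avogadro's number and the thermal energy used throughout the
#' barrier model. Internal units are micrometres, seconds, number densities
#' in molecules/um^3, and free energies in units of kT.
#'
#' @param temperature_K Absolute temperature in kelvin. Default 298 K
#'   (room temperature).
#' @return An object of class `physical_constants` with fields
#'   `avogadro` (1/mol), `temperature_K` (K) and `kBT_J` (J).
#' @examples
#' physical_constants()$kBT_J  # ~4.11e-21 J at 298 K
#' @export
physical_constants <- function(temperature_K = 298) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            temperature_K > 0)
  structure(
    list(
      avogadro = 6.02214076e23,
      boltzmann_J_K = 1.380649e-23,
      temperature_K = temperature_K,
      kBT_J = 1.380649e-23 * temperature_K
    ),
    class = "physical_constants"
  )
}

#' Drop geometry
#'
#' Geometry of the hanging drop. The sphere radius used for the diffusion
#' model is kept independent of the measured (area, volume) pair: the
#' instrument reports all three and a pendant drop is not a perfect sphere,
#' so no attempt is made to reconcile them.
#'
#' @param radius_sphere_mm Radius of the equivalent sphere used by the
#'   diffusion model, mm. Default 2.1 mm.
#' @param area_mm2 Measured drop surface area, mm^2. Default 50 mm^2.
#' @param volume_uL Measured drop volume, uL. Default 40 uL.
#' @return An object of class `drop_geometry`.
#' @export
drop_geometry <- function(radius_sphere_mm = 2.1, area_mm2 = 50,
                          volume_uL = 40) {
  stopifnot(radius_sphere_mm > 0, area_mm2 > 0, volume_uL > 0)
  structure(
    list(radius_sphere_mm = radius_sphere_mm,
         radius_sphere_um = radius_sphere_mm * 1e3,
         area_mm2 = area_mm2,
         area_um2 = area_mm2 * 1e6,
         volume_uL = volume_uL,
         volume_um3 = volume_uL * 1e9),
    class = "drop_geometry"
  )
}

#' Protein specification
#'
#' @param molar_mass_g_mol Molar mass, g/mol. Default 27e3 g/mol
#'   (a 241-residue chaperone).
#' @param diffusion_um2_s Translational diffusion coefficient, um^2/s.
#'   Default 45 um^2/s.
#' @return An object of class `protein_spec`.
#' @export
protein_spec <- function(molar_mass_g_mol = 27e3, diffusion_um2_s = 45) {
  stopifnot(molar_mass_g_mol > 0, diffusion_um2_s > 0)
  structure(
    list(molar_mass_g_mol = molar_mass_g_mol,
         diffusion_um2_s = diffusion_um2_s),
    class = "protein_spec"
  )
}

#' Convert molar concentration to number density
#'
#' 1 uM corresponds to N_A x 1e-21 molecules per um^3 (about 602.2/um^3).
#'
#' @param c_uM Concentration(s) in uM; must be non-negative.
#' @return Number density in molecules/um^3.
#' @seealso [number_density_to_molar()] for the inverse.
#' @export
molar_to_number_density <- function(c_uM) {
  if (any(c_uM < 0)) stop("concentration must be non-negative")
  c_uM * (6.02214076e23 * 1e-21)
}

#' Convert number density to molar concentration
#'
#' @param c_um3 Number density in molecules/um^3; must be non-negative.
#' @return Concentration in uM.
#' @export
number_density_to_molar <- function(c_um3) {
  if (any(c_um3 < 0)) stop("number density must be non-negative")
  c_um3 / (6.02214076e23 * 1e-21)
}

#' Mass per area of an adsorbed layer
#'
#' Converts a surface excess in molecules/um^2 to mg/m^2.
#'
#' @param gamma_excess_um2 Surface excess, molecules/um^2 (non-negative).
#' @param spec A [protein_spec()].
#' @return Mass surface excess in mg/m^2.
#' @examples
#' mass_surface_excess(24e3, protein_spec())  # ~1.1 mg/m^2
#' @export
mass_surface_excess <- function(gamma_excess_um2, spec = protein_spec()) {
  if (any(gamma_excess_um2 < 0)) stop("surface excess must be non-negative")
  # molecules/um^2 -> mol/m^2 -> g/m^2 -> mg/m^2
  gamma_excess_um2 * 1e12 / 6.02214076e23 * spec$molar_mass_g_mol * 1e3
}

#' Area and radius of the molecular footprint
#'
#' The inverse of the surface excess gives the area per adsorbed molecule;
#' the footprint radius is that of the equivalent disc.
#'
#' @param gamma_excess_um2 Surface excess, molecules/um^2 (strictly positive).
#' @return A list with `area_nm2` and `radius_nm`.
#' @examples
#' footprint(24e3)  # ~42 nm^2, ~3.6 nm
#' @export
footprint <- function(gamma_excess_um2) {
  if (any(gamma_excess_um2 <= 0)) stop("surface excess must be positive")
  area_nm2 <- 1e6 / gamma_excess_um2   # 1 um^2 = 1e6 nm^2
  list(area_nm2 = area_nm2, radius_nm = sqrt(area_nm2 / pi))
}

#' Bulk depletion caused by adsorption
#'
#' How much the bulk concentration of a finite drop drops when a surface
#' excess Gamma has accumulated on its measured area: dc = Gamma * A / V.
#' Uses the measured area and volume, not the sphere approximation.
#'
#' @param gamma_excess_um2 Surface excess, molecules/um^2 (non-negative).
#' @param geometry A [drop_geometry()].
#' @return Depletion in uM.
#' @examples
#' bulk_depletion(24e3, drop_geometry())  # ~0.05 uM
#' @export
bulk_depletion <- function(gamma_excess_um2, geometry = drop_geometry()) {
  if (any(gamma_excess_um2 < 0)) stop("surface excess must be non-negative")
  dn_um3 <- gamma_excess_um2 * geometry$area_um2 / geometry$volume_um3
  number_density_to_molar(dn_um3)
}

#' Sauerbrey mass from a QCM-D frequency shift
#'
#' Converts a resonance frequency shift to adsorbed (wet) mass per area via
#' the crystal's mass sensitivity constant. Fundamental-frequency use only;
#' adsorption gives a negative frequency shift and a positive mass.
#'
#' @param delta_f_Hz Frequency shift in Hz (negative for adsorption).
#' @param sensitivity_ng_cm2_Hz Mass sensitivity, ng/cm^2 per Hz.
#'   Default 17.7.
#' @return Mass per area in mg/m^2.
#' @export
sauerbrey_mass <- function(delta_f_Hz, sensitivity_ng_cm2_Hz = 17.7) {
  if (sensitivity_ng_cm2_Hz <= 0) stop("sensitivity must be positive")
  # ng/cm^2 = 1e-9 g / 1e-4 m^2 = 1e-2 mg/m^2
  sensitivity_ng_cm2_Hz * (-delta_f_Hz) * 1e-2
}

#' Size scaling of the diffusion-limited flux of clusters
#'
#' For spherical clusters of n monomers, D scales as n^(-1/3) and the
#' early-time planar diffusion-limited adsorbed amount as D^(1/2). At fixed
#' total monomer concentration the monomer-equivalent adsorbed amount of a
#' population of pure n-mers therefore scales as
#' n * (c_tot/n) * sqrt(D1 n^(-1/3)) ~ n^(-1/6). This helper computes those
#' amounts and returns the fitted log-log slope.
#'
#' @param n_values At least two distinct cluster sizes (all >= 1).
#' @param D1_um2_s Monomer diffusion coefficient, um^2/s.
#' @param c_tot_um3 Total monomer number density, molecules/um^3.
#' @param t_s Fixed observation time, s.
#' @return A list with `slope` (the fitted exponent) and a data.frame
#'   `amounts` of (n, gamma_um2).
#' @examples
#' cluster_flux_scaling(c(1, 8, 64, 512))$slope  # -1/6
#' @export
cluster_flux_scaling <- function(n_values, D1_um2_s = 45, c_tot_um3 = 602.214,
                                 t_s = 100) {
  n_values <- unique(as.numeric(n_values))
  if (length(n_values) < 2L) stop("need at least 2 distinct cluster sizes")
  if (any(n_values < 1)) stop("cluster sizes must be >= 1")
  D_n <- D1_um2_s * n_values^(-1 / 3)
  # planar early-time amount per species, in monomer units
  gamma <- n_values * (c_tot_um3 / n_values) * 2 * sqrt(D_n * t_s / pi)
  fit <- stats::lm(log(gamma) ~ log(n_values))
  list(slope = unname(stats::coef(fit)[2]),
       amounts = data.frame(n = n_values, gamma_um2 = gamma))
}
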