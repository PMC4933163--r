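# Fixed physical constants (CODATA-style; not configurable).
.const <- list(
  avogadro = 6.02214076e23,
  joule_per_kcal = 4184,
  metre_per_angstrom = 1e-10
)

# newtons per (kcal/mol/A)
newton_per_kcal_mol_A <- function() {
  .const$joule_per_kcal / (.const$avogadro * .const$metre_per_angstrom)
}

#' Young-Laplace internal pressure of a lipoprotein particle
#'
#' P = 2 alpha / R: the excess pressure inside a curved monolayer of
#' surface tension alpha and radius R. Smaller particles (HDL) carry a
#' higher internal pressure than larger ones (LDL) at the same tension.
#'
#' @param surface_tension alpha, N/m.
#' @param radius_A Particle radius, angstroms.
#' @return Pressure in pascals.
#' @export
#' @examples
#' laplace_pressure(0.020, 50) # HDL-sized particle
laplace_pressure <- function(surface_tension, radius_A) {
  if (any(surface_tension <= 0)) rlang::abort("surface tension must be positive")
  if (any(radius_A <= 0)) rlang::abort("radius must be positive")
  2 * surface_tension / (radius_A * .const$metre_per_angstrom)
}

#' Internal pressure difference between two lipoprotein particles
#'
#' @param surface_tension Common surface tension, N/m, or a length-2
#'   vector (donor, acceptor).
#' @param r_donor_A,r_acceptor_A Particle radii, angstroms (donor = the
#'   smaller, higher-pressure particle, e.g. HDL).
#' @return Pressure difference donor minus acceptor, pascals; the sign is
#'   preserved, so a larger donor gives a negative value.
#' @export
#' @examples
#' pressure_difference(0.020, 50, 110)
pressure_difference <- function(surface_tension, r_donor_A, r_acceptor_A) {
  st <- rep_len(surface_tension, 2)
  laplace_pressure(st[1], r_donor_A) - laplace_pressure(st[2], r_acceptor_A)
}

#' Driving force on a ligand in a tunnel from a pressure difference
#'
#' The pressure difference acts on the circular tunnel cross-section:
#' force = dP * pi (d/2)^2, converted from newtons to kcal/mol/A
#' (1 kcal/mol/A = 4184 / (N_A * 1e-10) N ~ 6.948e-11 N).
#'
#' @param dP Pressure difference, pascals.
#' @param tunnel_diameter_A Tunnel diameter, angstroms.
#' @return Driving force, kcal/mol/A.
#' @export
#' @examples
#' driving_force(pressure_difference(0.020, 50, 110), 6)
driving_force <- function(dP, tunnel_diameter_A) {
  if (any(tunnel_diameter_A <= 0)) rlang::abort("tunnel diameter must be positive")
  area_m2 <- pi * (tunnel_diameter_A / 2 * .const$metre_per_angstrom)^2
  dP * area_m2 / newton_per_kcal_mol_A()
}

#' Physiological driving force from particle geometry and surface tension
#'
#' Chains [pressure_difference()] and [driving_force()] for the standard
#' donor/acceptor geometry: HDL and LDL radii and a circular tunnel
#' cross-section.
#'
#' @param surface_tension N/m (vectorised: one force per tension).
#' @param r_hdl_A,r_ldl_A Particle radii, angstroms (defaults: mean HDL
#'   diameter ~100 A, LDL ~220 A).
#' @param tunnel_diameter_A Tunnel diameter, angstroms (default: the ~6 A
#'   neck of the CETP channel).
#' @return Driving force(s), kcal/mol/A.
#' @export
#' @examples
#' physiological_driving_force(c(0.020, 0.033))
physiological_driving_force <- function(surface_tension, r_hdl_A = 50,
                                        r_ldl_A = 110, tunnel_diameter_A = 6) {
  vapply(
    surface_tension,
    function(a) driving_force(pressure_difference(a, r_hdl_A, r_ldl_A), tunnel_diameter_A),
    numeric(1)
  )
}

#' Per-CETP transfer rate from a radiolabel specific activity
#'
#' Converts a specific activity in nmol CE per hour per microgram CETP
#' into CE molecules transferred per second per CETP molecule, using the
#' CETP molar mass.
#'
#' @param activity_nmol_h_ug Specific activity, nmol/h/ug CETP (>= 0).
#' @param cetp_mass_Da CETP molar mass, daltons.
#' @return CE molecules per second per CETP molecule.
#' @export
#' @examples
#' rate_from_specific_activity(75.7, 73000)
rate_from_specific_activity <- function(activity_nmol_h_ug, cetp_mass_Da = 73000) {
  if (any(activity_nmol_h_ug < 0)) rlang::abort("activity must be nonnegative")
  if (any(cetp_mass_Da <= 0)) rlang::abort("CETP molar mass must be positive")
  mol_ce_per_s_per_ug <- activity_nmol_h_ug * 1e-9 / 3600
  mol_cetp_per_ug <- 1e-6 / cetp_mass_Da
  mol_ce_per_s_per_ug / mol_cetp_per_ug
}

#' Per-CETP transfer rate from a plasma CE mass flux
#'
#' Converts a bulk plasma flux (ug CE per hour per ml) into CE molecules
#' per second per CETP molecule, given the plasma CETP concentration and
#' the molar masses of CE and CETP.
#'
#' @param flux_ug_h_ml CE flux, ug/h/ml (>= 0).
#' @param cetp_conc_ug_ml Plasma CETP concentration, ug/ml (> 0).
#' @param ce_mass_Da CE molar mass, daltons.
#' @param cetp_mass_Da CETP molar mass, daltons.
#' @return CE molecules per second per CETP molecule.
#' @export
#' @examples
#' rate_from_plasma_flux(64, 1.75, 651, 73000)
rate_from_plasma_flux <- function(flux_ug_h_ml, cetp_conc_ug_ml = 1.75,
                                  ce_mass_Da = 651, cetp_mass_Da = 73000) {
  if (any(flux_ug_h_ml < 0)) rlang::abort("flux must be nonnegative")
  if (any(cetp_conc_ug_ml <= 0)) rlang::abort("CETP concentration must be positive")
  if (any(ce_mass_Da <= 0) || any(cetp_mass_Da <= 0)) {
    rlang::abort("molar masses must be positive")
  }
  mol_ce_per_s_per_ml <- flux_ug_h_ml * 1e-6 / ce_mass_Da / 3600
  mol_cetp_per_ml <- cetp_conc_ug_ml * 1e-6 / cetp_mass_Da
  mol_ce_per_s_per_ml / mol_cetp_per_ml
}

#' Per-molecule transfer time from a rate
#'
#' @param rate CE molecules per second (> 0).
#' @return Seconds per CE molecule (the reciprocal).
#' @export
#' @examples
#' per_molecule_time(1.54)
per_molecule_time <- function(rate) {
  if (any(rate <= 0)) rlang::abort("rate must be positive")
  1 / rate
}

#' Physiological transfer-time prediction from the biophysical chain
#'
#' End-to-end convenience: surface tension and particle geometry give the
#' Laplace driving force; a power-law fit converts it to a transfer time
#' and a per-second rate. Driving forces far below the steered-force
#' range are an extrapolation and flagged as such.
#'
#' @param fit Power-law fit or list with `A`, `b`.
#' @param surface_tension N/m, vectorised.
#' @inheritParams physiological_driving_force
#' @return Tibble with `surface_tension`, `force` (kcal/mol/A),
#'   `time_s` (s/CE molecule), `rate_per_s` (CE molecules/s),
#'   `extrapolated`.
#' @export
#' @examples
#' physiological_prediction(list(A = 475, b = 2.75), c(0.020, 0.033))
physiological_prediction <- function(fit, surface_tension, r_hdl_A = 50,
                                     r_ldl_A = 110, tunnel_diameter_A = 6) {
  f <- physiological_driving_force(surface_tension, r_hdl_A, r_ldl_A, tunnel_diameter_A)
  pred <- predict_time(fit, f)
  tibble::tibble(
    surface_tension = surface_tension,
    force = f,
    time_s = pred$time_ns * 1e-9,
    rate_per_s = 1 / (pred$time_ns * 1e-9),
    extrapolated = pred$extrapolated
  )
}
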