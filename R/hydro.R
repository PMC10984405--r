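#' Buffer conditions for sedimentation analysis
#'
#' @param density Solvent density, g/ml.
#' @param viscosity Solvent viscosity, poise.
#' @param temperature Temperature, degrees C.
#' @param label Free-text label.
#' @return A list of class `buffer_conditions`.
#' @export
buffer_conditions <- function(density, viscosity, temperature = 20,
                              label = "") {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature, label = label),
            class = "buffer_conditions")
}

#' Water at 20 degrees C (the s20,w standard state)
#' @return A [buffer_conditions()] with the reference constants.
#' @export
water_20C <- function() {
  buffer_conditions(density = flexsas_constants$rho_20w_g_ml,
                    viscosity = flexsas_constants$eta_20w_poise,
                    temperature = 20, label = "water, 20C")
}

#' Standardise an observed sedimentation coefficient to s20,w
#'
#' `s20,w = s_T,B * (eta_T,B / eta_20,w) * (1 - vbar rho)_20,w /
#' (1 - vbar rho)_T,B`: corrects an observed value to water at 20 C using
#' the buffer viscosity and density and the solute partial specific
#' volume. Identity when the buffer is already water at 20 C.
#'
#' @param s_obs Observed sedimentation coefficient, Svedberg.
#' @param buffer A [buffer_conditions()].
#' @param vbar Partial specific volume, ml/g.
#' @return s20,w in Svedberg.
#' @export
s20w_correct <- function(s_obs, buffer, vbar) {
  eta_ref <- flexsas_constants$eta_20w_poise
  rho_ref <- flexsas_constants$rho_20w_g_ml
  denom <- 1 - vbar * buffer$density
  if (abs(denom) < 1e-6) {
    abort("Neutral buoyancy: (1 - vbar * rho) is ~0 in the buffer")
  }
  if (denom < 0) abort("(1 - vbar * rho) must be positive in the buffer")
  s_obs * (buffer$viscosity / eta_ref) * (1 - vbar * rho_ref) / denom
}

#' Svedberg mass scaling of a sedimentation coefficient
#'
#' At constant frictional ratio, `s` scales with `(mass)^(2/3)`:
#' `s_new = s_ref (m_new / m_ref)^(2/3)`. Used to predict the s20,w change
#' from a mass change alone (e.g. removal of 5.0 kDa of glycan).
#'
#' @param s_ref Reference s, Svedberg.
#' @param mass_ref,mass_new Masses, kDa.
#' @return Scaled s, Svedberg.
#' @export
svedberg_mass_scaled_s <- function(s_ref, mass_ref, mass_new) {
  stopifnot(mass_ref > 0, mass_new > 0)
  s_ref * (mass_new / mass_ref)^(2 / 3)
}

#' Hull-based theoretical sedimentation coefficient
#'
#' Convex-hull reduction of the HullRad idea to its sedimentation core:
#' the hull volume of all atoms (glycans included) gives an
#' equivalent-sphere radius; adding a hydration thickness gives the Stokes
#' radius R_s; then `s = M (1 - vbar rho) / (N_A 6 pi eta R_s)` in
#' water-at-20C constants.
#'
#' @param model An [atomic_model()] with `mass` (kDa) and `vbar` set.
#' @param hydration_thickness Hydration shell added to the equivalent
#'   radius, nm (default 0.28).
#' @param buffer Conditions for the buoyancy/viscosity terms (default
#'   water at 20 C, giving s20,w directly).
#' @return A list of class `sedimentation_estimate`: `s20w` (Svedberg),
#'   `stokes_radius` (nm), `hull_volume` (nm^3), `mass`, `vbar`.
#' @export
hull_s20w <- function(model, hydration_thickness = 0.28,
                      buffer = water_20C()) {
  if (is.na(model$mass) || model$mass <= 0) abort("Model mass must be set")
  vol <- convex_hull_volume(coords(model))   # nm^3
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)       # nm
  r_s <- r_eq + hydration_thickness
  m_g <- model$mass * 1000                   # g/mol
  buoy <- 1 - model$vbar * buffer$density
  if (buoy <= 0) abort("Non-positive buoyancy term (1 - vbar * rho)")
  s_sec <- m_g * buoy /
    (flexsas_constants$avogadro * 6 * pi * buffer$viscosity * (r_s * 1e-7))
  structure(list(s20w = s_sec / flexsas_constants$svedberg_s,
                 stokes_radius = r_s, hull_volume = vol,
                 mass = model$mass, vbar = model$vbar),
            class = "sedimentation_estimate")
}

#' @export
print.sedimentation_estimate <- function(x, ...) {
  cat(sprintf(
    "<sedimentation_estimate> s20,w = %.2f S (R_s %.2f nm, hull %.1f nm^3, M %.1f kDa)\n",
    x$s20w, x$stokes_radius, x$hull_volume, x$mass))
  invisible(x)
}
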