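# Photon/electron physics for the electron-stream simulator: Co-60 line
# spectrum, Compton kinematics with Klein-Nishina angle sampling, CSDA
# electron ranges in acrylic, and helical motion in the static field.

ELECTRON_REST_MEV <- 0.511

# radiation length of air (36.62 g/cm^2 at 1.205e-3 g/cm^3), for the
# Highland multiple-scattering angle
AIR_RADIATION_LENGTH_CM <- 30390

# Frozen material constants for acrylic (PMMA, 1.18 g/cm^3).
# Linear attenuation coefficients (1/cm) at the two Co-60 lines and a
# CSDA range table (MeV -> g/cm^2), log-log interpolated.
PMMA_MU_PER_CM <- c("1.17" = 0.0756, "1.33" = 0.0708)
PMMA_CSDA <- data.frame(
  energy_mev = c(0.01, 0.02, 0.05, 0.10, 0.20, 0.30,
                 0.40, 0.50, 0.70, 1.00, 1.25, 1.33, 1.50),
  range_gcm2 = c(2.52e-4, 8.57e-4, 4.32e-3, 1.43e-2, 4.49e-2, 8.42e-2,
                 1.28e-1, 1.74e-1, 2.70e-1, 4.15e-1, 5.41e-1, 5.82e-1, 6.53e-1)
)

#' Physics configuration for the electron-stream simulator
#'
#' @param photon_lines Two-column matrix or data frame: photon energy (MeV)
#'   and emission weight; weights must sum to 1. Default is the Co-60 doublet.
#' @param b_field Magnetic flux density along `+y`, tesla.
#' @param phantom_attenuation Named numeric: linear attenuation coefficient
#'   (1/cm) per photon line; names are the energies as printed.
#' @param csda_table Data frame with `energy_mev` and `range_gcm2` for the
#'   phantom material.
#' @param phantom_density g/cm^3, converts CSDA ranges to cm.
#' @param air_interactions `"csda"` (default): electrons lose energy along
#'   their helical path in air following the CSDA range table scaled to air
#'   density, and are dropped when the path to the panel exceeds their
#'   range — this is what makes panel doses fall with distance; `"none"`
#'   treats air as vacuum.
#' @param air_density g/cm^3 used for the air energy-loss correction.
#' @param transport_isotropic_fraction Fraction of electrons whose in-phantom
#'   transport direction is redrawn isotropically instead of keeping the
#'   ballistic Compton direction. A surrogate for multiple-scattering
#'   diffusion; in particular it is what lets a small albedo of electrons
#'   reach back out through the beam-entrance surface (single-scatter
#'   kinematics alone never send an electron backwards).
#' @return An object of class `physics_config`.
#' @export
physics_config <- function(photon_lines = cbind(energy_mev = c(1.17, 1.33),
                                                weight = c(0.5, 0.5)),
                           b_field = 0.35,
                           phantom_attenuation = PMMA_MU_PER_CM,
                           csda_table = PMMA_CSDA,
                           phantom_density = 1.18,
                           air_interactions = c("csda", "none"),
                           air_density = 1.205e-3,
                           transport_isotropic_fraction = 0.2) {
  air_interactions <- match.arg(air_interactions)
  if (transport_isotropic_fraction < 0 || transport_isotropic_fraction > 1)
    abort("`transport_isotropic_fraction` must lie in [0, 1]")
  photon_lines <- as.matrix(photon_lines)
  if (abs(sum(photon_lines[, 2]) - 1) > 1e-9)
    abort("photon line weights must sum to 1")
  if (any(phantom_attenuation <= 0) || any(csda_table$range_gcm2 <= 0))
    abort("attenuation coefficients and CSDA ranges must be positive")
  if (b_field < 0) abort("`b_field` must be non-negative (tesla)")
  structure(
    list(photon_lines = photon_lines, b_field = b_field,
         electron_rest_energy = ELECTRON_REST_MEV,
         phantom_attenuation = phantom_attenuation,
         csda_table = csda_table, phantom_density = phantom_density,
         air_interactions = air_interactions, air_density = air_density,
         transport_isotropic_fraction = transport_isotropic_fraction),
    class = "physics_config"
  )
}

# log-log interpolation of the CSDA range, cm (extrapolates linearly in
# log-log space beyond the table ends)
csda_range_cm <- function(energy_mev, physics,
                          density = physics$phantom_density) {
  tab <- physics$csda_table
  lr <- approx(log(tab$energy_mev), log(tab$range_gcm2), log(energy_mev),
               rule = 2)$y
  # linear log-log extrapolation below/above the table
  out <- exp(lr) / density
  lo <- energy_mev < tab$energy_mev[1]
  if (any(lo)) {
    slope <- (log(tab$range_gcm2[2]) - log(tab$range_gcm2[1])) /
      (log(tab$energy_mev[2]) - log(tab$energy_mev[1]))
    out[lo] <- exp(log(tab$range_gcm2[1]) +
                     slope * (log(energy_mev[lo]) - log(tab$energy_mev[1]))) /
      density
  }
  hi <- energy_mev > tab$energy_mev[nrow(tab)]
  if (any(hi)) {
    n <- nrow(tab)
    slope <- (log(tab$range_gcm2[n]) - log(tab$range_gcm2[n - 1])) /
      (log(tab$energy_mev[n]) - log(tab$energy_mev[n - 1]))
    out[hi] <- exp(log(tab$range_gcm2[n]) +
                     slope * (log(energy_mev[hi]) - log(tab$energy_mev[n]))) /
      density
  }
  out
}

# inverse of csda_range_cm: energy (MeV) whose range is `range_cm`
csda_energy_mev <- function(range_cm, physics,
                            density = physics$phantom_density) {
  tab <- physics$csda_table
  lrg <- log(range_cm * density)
  le <- approx(log(tab$range_gcm2), log(tab$energy_mev), lrg, rule = 2)$y
  out <- exp(le)
  lo <- lrg < log(tab$range_gcm2[1])
  if (any(lo)) {
    slope <- (log(tab$energy_mev[2]) - log(tab$energy_mev[1])) /
      (log(tab$range_gcm2[2]) - log(tab$range_gcm2[1]))
    out[lo] <- exp(log(tab$energy_mev[1]) + slope * (lrg[lo] - log(tab$range_gcm2[1])))
  }
  out
}

#' Compton kinematics
#'
#' `compton_electron_energy()` gives the kinetic energy transferred to the
#' electron for a photon of energy `E` scattered through `theta`;
#' `compton_edge()` is its maximum (backscatter); `compton_electron_angle()`
#' the electron polar angle relative to the incident photon, from
#' `cot(phi) = (1 + alpha) tan(theta/2)`.
#'
#' @param energy_mev Incident photon energy, MeV.
#' @param cos_theta Cosine of the photon scattering angle.
#' @return Energies in MeV; angles in radians.
#' @export
compton_electron_energy <- function(energy_mev, cos_theta) {
  a <- energy_mev / ELECTRON_REST_MEV
  energy_mev * a * (1 - cos_theta) / (1 + a * (1 - cos_theta))
}

#' @rdname compton_electron_energy
#' @export
compton_edge <- function(energy_mev) {
  a <- energy_mev / ELECTRON_REST_MEV
  energy_mev * 2 * a / (1 + 2 * a)
}

#' @rdname compton_electron_energy
#' @export
compton_electron_angle <- function(energy_mev, cos_theta) {
  a <- energy_mev / ELECTRON_REST_MEV
  tan_half <- sqrt(pmax(0, (1 - cos_theta) / (1 + cos_theta)))
  atan2(1, (1 + a) * tan_half)
}

# unnormalized Klein-Nishina density in cos(theta)
kn_density <- function(cos_theta, alpha) {
  p <- 1 / (1 + alpha * (1 - cos_theta))
  p^2 * (p + 1 / p - (1 - cos_theta^2))
}

#' Sample Compton scattering angles and electron kinematics
#'
#' Photon scattering angles are drawn from the Klein-Nishina differential
#' cross section by rejection sampling (uniform proposal in `cos(theta)`);
#' the electron energy and polar angle follow from two-body kinematics, and
#' the electron azimuth is uniform.
#'
#' @param energy_mev Vector of incident photon energies, MeV.
#' @param physics A [physics_config()] (for the electron rest energy).
#' @return A list with `cos_theta` (photon), `electron_kinetic_mev`,
#'   `electron_polar` (radians from the photon direction) and
#'   `electron_azimuth`.
#' @export
sample_compton <- function(energy_mev, physics = physics_config()) {
  n <- length(energy_mev)
  alpha <- energy_mev / ELECTRON_REST_MEV
  # envelope: per-event maximum of the density over a fine grid (the density
  # is smooth; grid maximum Inflated by 1.001 is a safe bound)
  grid <- seq(-1, 1, length.out = 513)
  env <- vapply(unique(alpha), function(a) 1.001 * max(kn_density(grid, a)),
                numeric(1))
  env <- env[match(alpha, unique(alpha))]
  cos_theta <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    prop <- runif(length(todo), -1, 1)
    u <- runif(length(todo)) * env[todo]
    ok <- u <= kn_density(prop, alpha[todo])
    cos_theta[todo[ok]] <- prop[ok]
    todo <- todo[!ok]
  }
  list(
    cos_theta = cos_theta,
    electron_kinetic_mev = compton_electron_energy(energy_mev, cos_theta),
    electron_polar = compton_electron_angle(energy_mev, cos_theta),
    electron_azimuth = runif(n, 0, 2 * pi)
  )
}

#' Relativistic electron momentum and gyroradius
#'
#' `electron_momentum_mev()` returns `pc` in MeV for a given kinetic energy;
#' `gyroradius_cm()` the radius of the circular motion transverse to the
#' field, `r = p_perp / (e B)`, expressed in cm for `pc` in MeV and `B` in
#' tesla.
#'
#' @param kinetic_mev Electron kinetic energy, MeV.
#' @param pc_mev Momentum times c, MeV.
#' @param b_field Tesla.
#' @return cm.
#' @export
electron_momentum_mev <- function(kinetic_mev) {
  et <- kinetic_mev + ELECTRON_REST_MEV
  sqrt(et^2 - ELECTRON_REST_MEV^2)
}

#' @rdname electron_momentum_mev
#' @export
gyroradius_cm <- function(pc_mev, b_field) {
  if (b_field <= 0) return(rep(Inf, length(pc_mev)))
  # r[m] = pc[eV] / (c[m/s] * B[T]); 1e6/2.99792458e8 m = 1/2.99792458 cm
  pc_mev / (2.99792458 * b_field)
}
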