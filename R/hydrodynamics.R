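# Boltzmann constant, J/K
.kB <- 1.380649e-23

# viscosities cross the API boundary in centipoise (matching the bundled
# oil tables); all internals are SI
.cp_to_pas <- function(viscosity_cp) viscosity_cp * 1e-3
.pas_to_cp <- function(viscosity_pas) viscosity_pas * 1e3

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("'%s' must be finite and strictly positive", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Rotational tumbling rate from the Stokes-Einstein relation
#'
#' Rate at which a spherical molecule of gyration radius \eqn{r_g} reorients
#' in a fluid of viscosity \eqn{\eta}:
#' \deqn{1/\tau_c = \frac{3 k_B T}{4 \pi \eta r_g^3}}
#'
#' @param radius_m gyration (Stokes) radius in metres.
#' @param viscosity_cp fluid viscosity in centipoise (1 cp = 1 mPa s).
#' @param temperature_k absolute temperature in kelvin.
#' @return the tumbling rate \eqn{1/\tau_c} in s^-1.
#' @examples
#' # oleic acid scale: r ~ 0.5 nm in its own melt at 20 C
#' 1 / tumbling_rate(0.5e-9, 17.6, 293)   # tau_c, seconds
#' @export
tumbling_rate <- function(radius_m, viscosity_cp, temperature_k) {
  .check_positive(radius_m = radius_m, viscosity_cp = viscosity_cp,
                  temperature_k = temperature_k)
  3 * .kB * temperature_k /
    (4 * pi * .cp_to_pas(viscosity_cp) * radius_m^3)
}

#' Rotational correlation time from the Stokes-Einstein-Debye relation
#'
#' \deqn{\tau_c = C_r \frac{\eta V}{k_B T}}
#' where \eqn{V} is the effective (hydrodynamic) molecular volume and
#' \eqn{C_r} an empirical fitting parameter. With \eqn{C_r = 1} and a
#' spherical volume \eqn{V = (4/3)\pi r^3} this is exactly the inverse of
#' [tumbling_rate()].
#'
#' @param volume_m3 effective molecular volume in m^3 (see [sphere_volume()]).
#' @param viscosity_cp viscosity in centipoise.
#' @param temperature_k temperature in kelvin.
#' @param cr_fit dimensionless empirical factor \eqn{C_r}, default 1.
#' @return \eqn{\tau_c} in seconds.
#' @export
tau_c_sed <- function(volume_m3, viscosity_cp, temperature_k, cr_fit = 1) {
  .check_positive(volume_m3 = volume_m3, viscosity_cp = viscosity_cp,
                  temperature_k = temperature_k, cr_fit = cr_fit)
  cr_fit * .cp_to_pas(viscosity_cp) * volume_m3 / (.kB * temperature_k)
}

#' Rotational diffusion coefficient of a sphere
#'
#' \deqn{D_r = \frac{k_B T}{8 \pi \eta R^3}}
#' The correlation time is inversely proportional to \eqn{D_r}; for a sphere
#' \eqn{\tau_c D_r = 1/6} independent of viscosity and temperature.
#'
#' @param radius_m Stokes radius in metres.
#' @param viscosity_cp viscosity in centipoise.
#' @param temperature_k temperature in kelvin.
#' @return \eqn{D_r} in s^-1.
#' @export
rotational_diffusion <- function(radius_m, viscosity_cp, temperature_k) {
  .check_positive(radius_m = radius_m, viscosity_cp = viscosity_cp,
                  temperature_k = temperature_k)
  .kB * temperature_k / (8 * pi * .cp_to_pas(viscosity_cp) * radius_m^3)
}

#' Volume of a sphere of given radius
#'
#' @param radius_m radius in metres.
#' @return volume in m^3.
#' @export
sphere_volume <- function(radius_m) {
  .check_positive(radius_m = radius_m)
  (4 / 3) * pi * radius_m^3
}

#' Molecular-weight scaling of the viscosity-normalized relaxation rate
#'
#' For unentangled chains the self-diffusion coefficient scales as
#' \eqn{M_w^{-\alpha}} with \eqn{\alpha = 1}, which combined with the
#' Stokes-Einstein-Debye relation makes \eqn{R_2/\eta} proportional to the
#' molecular weight. This proportionality underpins the chain-length
#' calibration: for chemically similar unbranched chains, molecular weight
#' tracks the carbon count.
#'
#' @param mw_gmol molecular weight in g/mol.
#' @param coefficient proportionality constant (s^-1 cp^-1 per g/mol).
#' @param mwc_gmol entanglement coupling molecular weight above which the
#'   linear law breaks down; default \code{Inf} (no entanglement). Exceeding
#'   it raises a warning, not an error.
#' @return predicted \eqn{R_2/\eta} in s^-1 cp^-1, vectorized over
#'   \code{mw_gmol}.
#' @export
r2_over_eta_mw_scaling <- function(mw_gmol, coefficient, mwc_gmol = Inf) {
  if (!is.numeric(mw_gmol) || any(!is.finite(mw_gmol)) || any(mw_gmol <= 0))
    stop("'mw_gmol' must be finite and strictly positive", call. = FALSE)
  if (!is.numeric(coefficient) || length(coefficient) != 1L)
    stop("'coefficient' must be a single number", call. = FALSE)
  if (any(mw_gmol >= mwc_gmol))
    warning("molecular weight at or above the entanglement coupling weight; ",
            "the linear R2/eta ~ Mw law may not hold", call. = FALSE)
  coefficient * mw_gmol
}
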