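#' Dipolar relaxation parameters for the BPP model
#'
#' Bundles the constants entering the Bloembergen-Purcell-Pound (BPP)
#' description of intramolecular proton-proton dipolar relaxation: the Larmor
#' frequency of the spectrometer and the strength of the dipolar coupling,
#' expressed either through the inter-proton distance \code{l} or directly as
#' the combined prefactor \eqn{(\mu_0/4\pi)^2 \gamma^4 \hbar^2 / l^6} (s^-2).
#'
#' The angular Larmor frequency \eqn{\omega_0 = 2\pi f} is computed here, and
#' only here, from the cyclic frequency in MHz, so no caller ever applies the
#' factor of \eqn{2\pi} twice.
#'
#' @param larmor_frequency_mhz proton Larmor frequency in MHz (default 23, a
#'   typical benchtop permanent-magnet field).
#' @param interproton_distance_m distance between adjacent protons on the same
#'   molecule, in metres. Default 1.79e-10 m, a typical geminal 1H-1H
#'   distance.
#' @param dipolar_prefactor optional override for the combined dipolar
#'   constant in s^-2; when \code{NULL} it is computed from
#'   \code{interproton_distance_m}.
#' @param second_moment optional rigid-lattice second moment M2 (s^-2), used
#'   by the fast-motion law [fast_motion_r2()].
#'
#' @return An object of class \code{"bpp_params"}: a list with elements
#'   \code{larmor_frequency_mhz}, \code{omega0} (rad/s),
#'   \code{interproton_distance_m}, \code{dipolar_prefactor},
#'   \code{second_moment}.
#' @examples
#' p <- bpp_params()
#' t1_bpp(1e-9, p) / t2_bpp(1e-9, p)
#' @export
bpp_params <- function(larmor_frequency_mhz = 23,
                       interproton_distance_m = 1.79e-10,
                       dipolar_prefactor = NULL,
                       second_moment = NULL) {
  if (!is.numeric(larmor_frequency_mhz) || larmor_frequency_mhz <= 0)
    stop("'larmor_frequency_mhz' must be a positive number", call. = FALSE)
  if (!is.numeric(interproton_distance_m) || interproton_distance_m <= 0)
    stop("'interproton_distance_m' must be a positive number", call. = FALSE)
  if (is.null(dipolar_prefactor)) {
    dipolar_prefactor <- .dipolar_prefactor(interproton_distance_m)
  } else if (!is.numeric(dipolar_prefactor) || dipolar_prefactor <= 0) {
    stop("'dipolar_prefactor' must be a positive number", call. = FALSE)
  }
  if (!is.null(second_moment) && (!is.numeric(second_moment) || second_moment <= 0))
    stop("'second_moment' must be a positive number", call. = FALSE)
  structure(
    list(
      larmor_frequency_mhz = larmor_frequency_mhz,
      omega0 = 2 * pi * larmor_frequency_mhz * 1e6,
      interproton_distance_m = interproton_distance_m,
      dipolar_prefactor = dipolar_prefactor,
      second_moment = second_moment
    ),
    class = "bpp_params"
  )
}

# (mu0/4pi)^2 gamma^4 hbar^2 / l^6, in s^-2
.dipolar_prefactor <- function(l) {
  mu0_4pi <- 1e-7              # T m / A
  gamma_h <- 2.675221e8        # rad s^-1 T^-1
  hbar <- 1.054571817e-34      # J s
  (mu0_4pi^2 * gamma_h^4 * hbar^2) / l^6
}

#' @export
print.bpp_params <- function(x, ...) {
  cat("BPP dipolar relaxation parameters\n")
  cat(sprintf("  Larmor frequency : %g MHz (omega0 = %.4g rad/s)\n",
              x$larmor_frequency_mhz, x$omega0))
  cat(sprintf("  inter-proton l   : %.3g m\n", x$interproton_distance_m))
  cat(sprintf("  dipolar prefactor: %.4g s^-2\n", x$dipolar_prefactor))
  if (!is.null(x$second_moment))
    cat(sprintf("  second moment M2 : %.4g s^-2\n", x$second_moment))
  invisible(x)
}

.check_tau_c <- function(tau_c) {
  if (!is.numeric(tau_c) || length(tau_c) == 0 || any(!is.finite(tau_c)) ||
      any(tau_c <= 0))
    stop("'tau_c' must be finite and strictly positive", call. = FALSE)
}

#' Longitudinal relaxation time from BPP theory
#'
#' Evaluates the spin-lattice relaxation time of like-spin protons relaxed by
#' intramolecular dipolar coupling modulated by isotropic rotational tumbling:
#' \deqn{1/T_1 = \frac{3}{10} C \left[ \frac{\tau_c}{1+\omega_0^2\tau_c^2} +
#'   \frac{4\tau_c}{1+4\omega_0^2\tau_c^2} \right]}
#' with \eqn{C} the dipolar prefactor. \eqn{T_1} passes through a minimum near
#' \eqn{\omega_0\tau_c \approx 0.616} and grows on both sides of it.
#'
#' @param tau_c rotational correlation time(s) in seconds; strictly positive.
#' @param params a [bpp_params()] object.
#' @return \eqn{T_1} in seconds, vectorized over \code{tau_c}.
#' @seealso [t2_bpp()], [t1_over_t2()]
#' @export
t1_bpp <- function(tau_c, params = bpp_params()) {
  .check_tau_c(tau_c)
  x2 <- (params$omega0 * tau_c)^2
  rate <- 0.3 * params$dipolar_prefactor *
    (tau_c / (1 + x2) + 4 * tau_c / (1 + 4 * x2))
  1 / rate
}

#' Transverse relaxation time from BPP theory
#'
#' Evaluates the spin-spin relaxation time for the same dipolar mechanism as
#' [t1_bpp()]:
#' \deqn{1/T_2 = \frac{3}{20} C \left[ 3\tau_c +
#'   \frac{5\tau_c}{1+\omega_0^2\tau_c^2} +
#'   \frac{2\tau_c}{1+4\omega_0^2\tau_c^2} \right]}
#' The zero-frequency spectral density term \eqn{3\tau_c} makes \eqn{T_2}
#' strictly decreasing in \eqn{\tau_c}, so \eqn{T_2 \le T_1} always, with
#' equality in the extreme-narrowing (fast motion) limit
#' \eqn{\omega_0\tau_c \ll 1}.
#'
#' @inheritParams t1_bpp
#' @return \eqn{T_2} in seconds, vectorized over \code{tau_c}.
#' @export
t2_bpp <- function(tau_c, params = bpp_params()) {
  .check_tau_c(tau_c)
  x2 <- (params$omega0 * tau_c)^2
  rate <- (3 / 20) * params$dipolar_prefactor *
    (3 * tau_c + 5 * tau_c / (1 + x2) + 2 * tau_c / (1 + 4 * x2))
  1 / rate
}

#' T1/T2 ratio as a function of the reduced correlation time
#'
#' The dipolar prefactor cancels in the ratio of the two BPP rates, leaving a
#' universal function of \eqn{x = \omega_0\tau_c}:
#' \deqn{T_1/T_2 = \frac{3 + 5/(1+x^2) + 2/(1+4x^2)}
#'   {2\left[1/(1+x^2) + 4/(1+4x^2)\right]}}
#' It equals 1 at \eqn{x = 0} and increases monotonically, which is why a
#' \eqn{T_1/T_2 > 1} component on a T1-T2 map signals slowed rotation
#' (aggregates, polymers, binding).
#'
#' @param omega0_tau_c dimensionless product \eqn{\omega_0\tau_c}; must be
#'   \eqn{\ge 0}.
#' @return the dimensionless ratio \eqn{T_1/T_2}, vectorized.
#' @export
t1_over_t2 <- function(omega0_tau_c) {
  if (!is.numeric(omega0_tau_c) || any(!is.finite(omega0_tau_c)) ||
      any(omega0_tau_c < 0))
    stop("'omega0_tau_c' must be finite and nonnegative", call. = FALSE)
  x2 <- omega0_tau_c^2
  num <- 3 + 5 / (1 + x2) + 2 / (1 + 4 * x2)
  den <- 2 * (1 / (1 + x2) + 4 / (1 + 4 * x2))
  num / den
}

#' Invert a measured T1/T2 ratio to a rotational correlation time
#'
#' Numerically inverts [t1_over_t2()] on its monotone branch by bisection in
#' \eqn{\log \tau_c}. A ratio of exactly 1 is the fast-motion limit and is
#' reported as the configured lower bracket; a ratio below 1 is unphysical for
#' dipolar relaxation and raises an error.
#'
#' @param ratio measured \eqn{T_1/T_2}; must be \eqn{\ge 1}.
#' @param params a [bpp_params()] object (supplies \eqn{\omega_0}).
#' @param bracket search interval for \eqn{\tau_c} in seconds. The default
#'   spans small molecules through polymeric aggregates at benchtop fields.
#' @param tol relative tolerance on \eqn{\tau_c}.
#' @return \eqn{\tau_c} in seconds.
#' @export
invert_tau_c_from_ratio <- function(ratio, params = bpp_params(),
                                    bracket = c(1e-13, 1e-5),
                                    tol = 1e-10) {
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio))
    stop("'ratio' must be a single finite number", call. = FALSE)
  if (ratio < 1)
    stop("unphysical T1/T2: ratio must be >= 1", call. = FALSE)
  if (length(bracket) != 2L || any(bracket <= 0) || bracket[1] >= bracket[2])
    stop("'bracket' must be an increasing pair of positive times", call. = FALSE)
  lo <- t1_over_t2(params$omega0 * bracket[1])
  hi <- t1_over_t2(params$omega0 * bracket[2])
  if (ratio <= lo) return(bracket[1])
  if (ratio > hi)
    stop(sprintf("ratio %.4g exceeds the value %.4g at the upper bracket; widen 'bracket'",
                 ratio, hi), call. = FALSE)
  f <- function(u) t1_over_t2(params$omega0 * exp(u)) - ratio
  root <- stats::uniroot(f, lower = log(bracket[1]), upper = log(bracket[2]),
                         tol = tol / 4)$root
  exp(root)
}

#' Fast-motion (extreme narrowing) transverse relaxation rate
#'
#' In the fast-motion regime \eqn{\omega_0\tau_c \ll 1} the transverse rate is
#' linear in the correlation time, \eqn{R_2 = c\, M_2\, \tau_c}, with the
#' rigid-lattice second moment \eqn{M_2} measuring the dipolar coupling
#' strength. The proportionality constant \code{constant} is configurable
#' (default 10). This linear law is exposed only for the regime where it
#' holds; outside extreme narrowing use [t2_bpp()].
#'
#' @param tau_c correlation time(s), seconds, positive.
#' @param second_moment second moment M2 in s^-2, positive.
#' @param constant dimensionless proportionality constant, default 10.
#' @return \eqn{R_2} in s^-1, vectorized over \code{tau_c}.
#' @export
fast_motion_r2 <- function(tau_c, second_moment, constant = 10) {
  .check_tau_c(tau_c)
  if (!is.numeric(second_moment) || second_moment <= 0)
    stop("'second_moment' must be a positive number", call. = FALSE)
  constant * second_moment * tau_c
}

#' Tabulate BPP theory curves
#'
#' Convenience wrapper producing the classic log-log theory plot data: T1, T2
#' and their ratio on a logarithmic grid of correlation times.
#'
#' @param tau_c_range range of correlation times in seconds.
#' @param n number of grid points.
#' @param params a [bpp_params()] object.
#' @return a data.frame with columns \code{tau_c_s}, \code{t1_s}, \code{t2_s},
#'   \code{ratio}.
#' @export
bpp_theory_curve <- function(tau_c_range = c(1e-12, 1e-6), n = 200,
                             params = bpp_params()) {
  tau <- exp(seq(log(tau_c_range[1]), log(tau_c_range[2]), length.out = n))
  data.frame(
    tau_c_s = tau,
    t1_s = t1_bpp(tau, params),
    t2_s = t2_bpp(tau, params),
    ratio = t1_over_t2(params$omega0 * tau)
  )
}
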