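#' Steady perfusion decay rate
#'
#' Spatial decay rate of the steady temperature profile,
#' \eqn{\lambda = \sqrt{\omega_b \rho_b c_b / k}} (1/m): the reciprocal of
#' the depth over which blood perfusion carries a surface disturbance away.
#' With no perfusion (\eqn{\omega_b = 0}) the rate is 0 and the steady
#' profile degenerates to the conduction-only (linear / constant-gradient)
#' limit, which [steady_profile()] handles analytically.
#'
#' @param params a `bioheat_params` object.
#' @return decay rate (1/m); 0 when `omega_b = 0`.
#' @export
decay_rate <- function(params) {
  sqrt(.wbcb(params) / params$tissue$k)
}

#' Steady-state temperature profile
#'
#' The time-independent increment profile \eqn{\varphi(x)} that carries the
#' surface load, used to homogenise the boundary conditions of the
#' transient problem (\eqn{\theta = \theta_1 + \varphi(x) H(t)}).  It
#' solves \eqn{\varphi'' = \lambda^2 \varphi} with the case boundary
#' conditions:
#'
#' * case I (`constant_temperature`):
#'   \eqn{\varphi(x) = \theta_0 (e^{-\lambda x} - e^{\lambda(x-2L)}) /
#'   (1 - e^{-2\lambda L})}, so \eqn{\varphi(0)=\theta_0},
#'   \eqn{\varphi(L)=0};
#' * case II (`constant_flux`):
#'   \eqn{\varphi(x) = q_e (e^{-\lambda(L-x)} - e^{\lambda(L-x)}) /
#'   (\lambda (e^{-\lambda L} + e^{\lambda L}))} with effective boundary
#'   gradient \eqn{q_e = \varphi'(0)}; under the default `as_printed`
#'   convention \eqn{q_e = Q_0 (1-R_d)} (taken over verbatim, which makes
#'   the surface increment negative for positive irradiance), under
#'   `physical` \eqn{q_e = -Q_0(1-R_d)/k}.
#'
#' Both expressions are evaluated in rearrangements whose exponents are all
#' non-positive, so large \eqn{\lambda L} cannot overflow.  The
#' \eqn{\omega_b = 0} limits (\eqn{\theta_0(1-x/L)} and \eqn{-q_e(L-x)})
#' are taken analytically.
#'
#' @param params a `bioheat_params` object.
#' @return object of class `steady_profile`: list with `lambda_s`, the
#'   evaluators `phi(x)` and `dphi(x)`, the boundary-gradient value
#'   `q_eff` (case II), and the case tag.
#' @examples
#' sp <- steady_profile(bioheat_params())
#' sp$phi(c(0, 0.0045, 0.009))
#' @export
steady_profile <- function(params) {
  validate_params(params)
  lam <- decay_rate(params)
  L <- params$geom$L
  case <- params$load$case
  if (case == "constant_temperature") {
    th0 <- params$load$theta_0
    q_eff <- NA_real_
    if (lam == 0) {
      phi <- function(x) th0 * (1 - x / L)
      dphi <- function(x) rep_len(-th0 / L, length(x))
    } else {
      den <- 1 - exp(-2 * lam * L)
      phi <- function(x) th0 * (exp(-lam * x) - exp(lam * (x - 2 * L))) / den
      dphi <- function(x) th0 * lam * (-exp(-lam * x) - exp(lam * (x - 2 * L))) / den
    }
  } else {
    q_eff <- flux_gradient(params)
    if (lam == 0) {
      phi <- function(x) -q_eff * (L - x)
      dphi <- function(x) rep_len(q_eff, length(x))
    } else {
      den <- lam * (1 + exp(-2 * lam * L))
      phi <- function(x) q_eff * (exp(-lam * (2 * L - x)) - exp(-lam * x)) / den
      dphi <- function(x) q_eff * lam * (exp(-lam * (2 * L - x)) + exp(-lam * x)) / den
    }
  }
  structure(list(lambda_s = lam, phi = phi, dphi = dphi,
                 q_eff = q_eff, case = case, L = L),
            class = "steady_profile")
}

# effective boundary gradient d(theta)/dx at x = 0 for the flux case
flux_gradient <- function(params) {
  qin <- params$load$Q_0 * (1 - params$load$R_d)
  if (params$load$flux_convention == "as_printed") qin else -qin / params$tissue$k
}

#' Scale of the applied surface load
#'
#' Reference temperature magnitude used to normalise errors, thresholds and
#' convergence criteria: \eqn{|\theta_0|} for the constant-temperature case
#' and the magnitude of the steady surface increment \eqn{|\varphi(0)|} for
#' the constant-flux case.
#'
#' @param params a `bioheat_params` object.
#' @return positive scalar (degrees C).
#' @export
load_scale <- function(params) {
  if (params$load$case == "constant_temperature") {
    abs(params$load$theta_0)
  } else {
    abs(steady_profile(params)$phi(0))
  }
}

#' Projection of the steady profile onto the eigenbasis
#'
#' Coefficients \eqn{c_n = (2/L) \int_0^L Y_n(x) \varphi(x) \mathrm{d}x}
#' feeding the modal initial conditions.  Because \eqn{\varphi} is a
#' combination of two exponentials the integral is evaluated in closed
#' form; after the boundary terms cancel it collapses to
#' \deqn{c_n = \frac{2 \theta_0 \lambda_n}{L(\lambda^2 + \lambda_n^2)}
#'   \quad \textrm{(case I)}, \qquad
#'   c_n = \frac{-2 q_e}{L(\lambda^2 + \lambda_n^2)}
#'   \quad \textrm{(case II)},}
#' formulas that remain exact in the \eqn{\omega_b = 0} (\eqn{\lambda = 0})
#' limit.  Adaptive quadrature of the defining integral is used as the test
#' oracle, not here.
#'
#' @param params a `bioheat_params` object.
#' @param n mode index (vectorised), `n >= 1`.
#' @return coefficients \eqn{c_n} (degrees C).
#' @export
projection_coefficient <- function(params, n) {
  stopifnot(all(n >= 1), all(n == round(n)))
  L <- params$geom$L
  lam_s <- decay_rate(params)
  if (params$load$case == "constant_temperature") {
    lam_n <- n * pi / L
    2 * params$load$theta_0 * lam_n / (L * (lam_s^2 + lam_n^2))
  } else {
    lam_n <- (2 * n - 1) * pi / (2 * L)
    -2 * flux_gradient(params) / (L * (lam_s^2 + lam_n^2))
  }
}
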