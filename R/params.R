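#' Parameter set for a bio-heat simulation
#'
#' Bundles the thermophysical properties of the tissue slab, the perfusing
#' arterial blood, the three constitutive phase lags, the surface load and
#' the geometry into a single validated object.  All internal computation is
#' in SI units and works on the temperature increment
#' \eqn{\theta = T - T_a} so that degrees Celsius and Kelvin coincide.
#'
#' The defaults are the reference skin-tissue parameter set used throughout
#' the package's worked examples: dermis-like conductivity
#' \eqn{k = 0.235} W/(m K), rate of thermal conductivity
#' \eqn{k^* = 0.1} W/(m K s) (an assumed value -- no measurement of
#' \eqn{k^*} for living tissue exists, see the methods vignette), blood
#' perfusion \eqn{\omega_b = 1.87\times 10^{-3}} 1/s, phase lags
#' \eqn{\tau_q = 16} s, \eqn{\tau_T = 6} s, \eqn{\tau_v = 2} s, a 9 mm slab
#' heated from 37 to 80 degrees C on its outer surface.
#'
#' @param rho_t,c_t,k,k_star tissue mass density (kg/m^3), specific heat
#'   (J/(kg K)), thermal conductivity (W/(m K)) and rate of thermal
#'   conductivity (W/(m K s)).  `k_star = 0` selects the DPL/C-V/Pennes
#'   family.
#' @param rho_b,c_b,omega_b,T_a blood density (kg/m^3), specific heat
#'   (J/(kg K)), perfusion rate (1/s; volume of arterial blood flowing
#'   through unit tissue volume per unit time) and arterial temperature
#'   (degrees C).
#' @param tau_q,tau_T,tau_v phase lags (s) of the heat-flux vector, the
#'   temperature gradient and the thermal-displacement gradient.
#' @param L slab thickness (m); `x = 0` is the heated outer surface,
#'   `x = L` the inner surface held at arterial temperature.
#' @param variant one of `"TPL"`, `"DPL"`, `"CV"`, `"Pennes"`.
#' @param case surface-load case: `"constant_temperature"` (step surface
#'   temperature, case I) or `"constant_flux"` (step laser irradiance,
#'   case II).
#' @param theta_0 surface temperature increment \eqn{T_0 - T_a} (degrees C,
#'   case I).  Alternatively give `T_0`.
#' @param T_0 absolute surface temperature (degrees C); used only when
#'   `theta_0` is missing.
#' @param Q_0 maximum laser irradiance, in W/cm^2 as conventionally printed
#'   (case II); converted to W/m^2 at ingestion.
#' @param R_d diffuse reflectance of light at the irradiated surface
#'   (dimensionless, in \[0, 1\]).
#' @param flux_convention how the flux boundary condition is interpreted:
#'   `"as_printed"` equates the surface temperature gradient to
#'   \eqn{\phi_{in}(1-R_d)} directly; `"physical"` uses the
#'   Fourier-consistent \eqn{-\phi_{in}(1-R_d)/k}.  See the methods
#'   vignette for why both exist.
#' @param Q_m,Q_laser volumetric metabolic and laser heat sources (W/m^3).
#'   Default 0; constant sources do not enter the transient path (their
#'   time derivative vanishes), see the methods vignette.
#'
#' @return An object of class `bioheat_params`: a nested list with
#'   components `tissue`, `blood`, `lags`, `load`, `sources`, `geom`,
#'   `variant`.
#' @seealso [validate_params()], [reduce_model()], [bioheat_model()]
#' @examples
#' p <- bioheat_params()                      # reference TPL skin set
#' p_cv <- reduce_model(p, "CV")              # Cattaneo-Vernotte reduction
#' cv_wave_speed(p_cv)
#' @export
bioheat_params <- function(rho_t = 1190, c_t = 3600, k = 0.235, k_star = 0.1,
                           rho_b = 1060, c_b = 3770, omega_b = 1.87e-3,
                           T_a = 37,
                           tau_q = 16, tau_T = 6, tau_v = 2,
                           L = 0.009,
                           variant = c("TPL", "DPL", "CV", "Pennes"),
                           case = c("constant_temperature", "constant_flux"),
                           theta_0 = NULL, T_0 = 80,
                           Q_0 = 2, R_d = 0.05,
                           flux_convention = c("as_printed", "physical"),
                           Q_m = 0, Q_laser = 0) {
  variant <- match.arg(variant)
  case <- match.arg(case)
  flux_convention <- match.arg(flux_convention)
  if (is.null(theta_0)) theta_0 <- T_0 - T_a
  p <- structure(list(
    tissue = list(rho_t = rho_t, c_t = c_t, k = k, k_star = k_star),
    blood = list(rho_b = rho_b, c_b = c_b, omega_b = omega_b, T_a = T_a),
    lags = list(tau_q = tau_q, tau_T = tau_T, tau_v = tau_v),
    load = list(case = case, theta_0 = theta_0,
                Q_0 = Q_0 * 1e4,  # W/cm^2 -> W/m^2
                R_d = R_d, flux_convention = flux_convention),
    sources = list(Q_m = Q_m, Q_laser = Q_laser),
    geom = list(L = L),
    variant = variant
  ), class = "bioheat_params")
  validate_params(p)
}

#' Validate a bio-heat parameter set
#'
#' Checks positivity and consistency invariants and returns the parameter
#' set unchanged when they hold.  Violations of hard physical requirements
#' (non-positive density, specific heat, conductivity or thickness,
#' negative lags, reflectance outside \[0,1\], a variant label inconsistent
#' with the lag/conductivity values) are errors naming the offending field.
#' A TPL set whose positive lags do not respect the stability ordering
#' \eqn{0 \le \tau_v < \tau_T < \tau_q} only triggers a warning: the
#' ordering is a stability heuristic, not a mathematical requirement, and
#' e.g. \eqn{\tau_v = 0} runs are legitimate study cases.
#'
#' @param params a `bioheat_params` object.
#' @return `params`, invisibly unchanged, if valid.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "bioheat_params"))
  ti <- params$tissue; bl <- params$blood; lg <- params$lags
  ld <- params$load; so <- params$sources; ge <- params$geom
  fail <- function(field, why) {
    stop("invalid parameter `", field, "`: ", why, call. = FALSE)
  }
  if (!is.finite(ti$rho_t) || ti$rho_t <= 0) fail("tissue$rho_t", "must be > 0")
  if (!is.finite(ti$c_t) || ti$c_t <= 0) fail("tissue$c_t", "must be > 0")
  if (!is.finite(ti$k) || ti$k <= 0) fail("tissue$k", "must be > 0")
  if (!is.finite(ti$k_star) || ti$k_star < 0) fail("tissue$k_star", "must be >= 0")
  if (!is.finite(bl$rho_b) || bl$rho_b <= 0) fail("blood$rho_b", "must be > 0")
  if (!is.finite(bl$c_b) || bl$c_b <= 0) fail("blood$c_b", "must be > 0")
  if (!is.finite(bl$omega_b) || bl$omega_b < 0) fail("blood$omega_b", "must be >= 0")
  if (!is.finite(bl$T_a)) fail("blood$T_a", "must be finite")
  for (nm in names(lg)) {
    if (!is.finite(lg[[nm]]) || lg[[nm]] < 0) fail(paste0("lags$", nm), "must be >= 0")
  }
  if (!is.finite(ge$L) || ge$L <= 0) fail("geom$L", "must be > 0")
  if (!is.finite(ld$theta_0)) fail("load$theta_0", "must be finite")
  if (!is.finite(ld$Q_0) || ld$Q_0 < 0) fail("load$Q_0", "must be >= 0")
  if (!is.finite(ld$R_d) || ld$R_d < 0 || ld$R_d > 1) fail("load$R_d", "must be in [0, 1]")
  if (so$Q_m < 0) fail("sources$Q_m", "must be >= 0")
  if (so$Q_laser < 0) fail("sources$Q_laser", "must be >= 0")

  # variant consistency: DPL drops k*, CV additionally both gradient lags,
  # Pennes additionally the flux lag
  v <- params$variant
  if (v %in% c("DPL", "CV", "Pennes") && ti$k_star != 0)
    fail("tissue$k_star", paste0("must be 0 for the ", v, " variant"))
  if (v %in% c("CV", "Pennes") && (lg$tau_T != 0 || lg$tau_v != 0))
    fail("lags", paste0("tau_T and tau_v must be 0 for the ", v, " variant"))
  if (v == "Pennes" && lg$tau_q != 0)
    fail("lags$tau_q", "must be 0 for the Pennes variant")

  if (v == "TPL" && all(unlist(lg) > 0) &&
      !(lg$tau_v < lg$tau_T && lg$tau_T < lg$tau_q)) {
    warning("phase lags do not satisfy the stability ordering ",
            "0 <= tau_v < tau_T < tau_q", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.bioheat_params <- function(x, ...) {
  cat("<bioheat_params> variant:", x$variant, "| load case:", x$load$case, "\n")
  cat(sprintf("  tissue: rho_t=%g kg/m^3, c_t=%g J/(kg K), k=%g W/(m K), k*=%g W/(m K s)\n",
              x$tissue$rho_t, x$tissue$c_t, x$tissue$k, x$tissue$k_star))
  cat(sprintf("  blood:  rho_b=%g, c_b=%g, omega_b=%g 1/s, T_a=%g C\n",
              x$blood$rho_b, x$blood$c_b, x$blood$omega_b, x$blood$T_a))
  cat(sprintf("  lags:   tau_q=%g s, tau_T=%g s, tau_v=%g s\n",
              x$lags$tau_q, x$lags$tau_T, x$lags$tau_v))
  if (x$load$case == "constant_temperature") {
    cat(sprintf("  load:   step surface temperature, theta_0=%g C\n", x$load$theta_0))
  } else {
    cat(sprintf("  load:   step surface flux, Q_0=%g W/m^2, R_d=%g (%s)\n",
                x$load$Q_0, x$load$R_d, x$load$flux_convention))
  }
  cat(sprintf("  geom:   L=%g m\n", x$geom$L))
  invisible(x)
}

# volumetric heat capacities and perfusion product, used everywhere
.rtct <- function(params) params$tissue$rho_t * params$tissue$c_t
.wbcb <- function(params) params$blood$omega_b * params$blood$rho_b * params$blood$c_b
.kq <- function(params) 1 + params$lags$tau_q * params$tissue$k_star / params$tissue$k

#' Cattaneo-Vernotte thermal wave speed
#'
#' Finite propagation speed of the thermal wave implied by a heat-flux
#' relaxation time, \eqn{V_{C\textrm{-}V} = \sqrt{k / (\tau_q \rho_t c_t)}}.
#' With \eqn{\tau_q = 0} (the Pennes limit) propagation is instantaneous and
#' `Inf` is returned with a warning.
#'
#' @param params a `bioheat_params` object.
#' @return wave speed in m/s (`Inf` for \eqn{\tau_q = 0}).
#' @examples
#' cv_wave_speed(bioheat_params(k = 0.2, tau_q = 20, rho_t = 1000, c_t = 4200))
#' @export
cv_wave_speed <- function(params) {
  validate_params(params)
  if (params$lags$tau_q == 0) {
    warning("tau_q = 0: infinite propagation speed (Pennes condition)",
            call. = FALSE)
    return(Inf)
  }
  sqrt(params$tissue$k / (params$lags$tau_q * .rtct(params)))
}

#' Reduce a parameter set to a simpler conduction model
#'
#' Produces the exact limiting parameter set of a target model family:
#' `"DPL"` zeroes the rate of thermal conductivity \eqn{k^*}; `"CV"`
#' additionally zeroes both gradient lags \eqn{\tau_T, \tau_v}; `"Pennes"`
#' additionally zeroes the flux lag \eqn{\tau_q}.  All other parameters are
#' preserved, and the operation is idempotent.
#'
#' @param params a `bioheat_params` object.
#' @param target one of `"DPL"`, `"CV"`, `"Pennes"`.
#' @return a new `bioheat_params` object of the target variant.
#' @export
reduce_model <- function(params, target = c("DPL", "CV", "Pennes")) {
  target <- match.arg(target)
  validate_params(params)
  params$tissue$k_star <- 0
  if (target %in% c("CV", "Pennes")) {
    params$lags$tau_T <- 0
    params$lags$tau_v <- 0
  }
  if (target == "Pennes") params$lags$tau_q <- 0
  params$variant <- target
  validate_params(params)
  params
}

#' Per-mode characteristic cubic coefficients
#'
#' For eigenvalue \eqn{\lambda_n} the modal amplitude \eqn{B_n(t)} satisfies
#' \eqn{a B'''+ b B'' + c B' + d B = f(t)} with
#' \deqn{a = \tau_q \rho_t c_t, \quad
#'       b = \rho_t c_t k_q + \tau_q \omega_b \rho_b c_b + k \tau_T \lambda_n^2,}
#' \deqn{c = \rho_t c_t k^*/k + \omega_b \rho_b c_b k_q + (k + k^* \tau_v)\lambda_n^2,
#'       \quad
#'       d = \omega_b \rho_b c_b k^*/k + k^* \lambda_n^2,}
#' where \eqn{k_q = 1 + \tau_q k^*/k}.  With \eqn{k^* = 0} the constant term
#' vanishes exactly (the cubic has a zero root, the signature of the
#' once-differentiated DPL/C-V family); with \eqn{\tau_q = 0} the leading
#' coefficient vanishes and the mode equation drops order (handled by a
#' dedicated degenerate path downstream, never by dividing by `a`).
#'
#' @param params a `bioheat_params` object.
#' @param lambda_n eigenvalue (1/m), strictly positive; may be a vector.
#' @return a list of class `cubic_coefficients` with vector fields
#'   `a`, `b`, `c`, `d`, `k_q`, `lambda_n`.
#' @export
cubic_coefficients <- function(params, lambda_n) {
  stopifnot(all(lambda_n > 0))
  rtct <- .rtct(params); wbcb <- .wbcb(params)
  k <- params$tissue$k; ks <- params$tissue$k_star
  tq <- params$lags$tau_q; tT <- params$lags$tau_T; tv <- params$lags$tau_v
  kq <- .kq(params)
  structure(list(
    a = rep_len(tq * rtct, length(lambda_n)),
    b = rtct * kq + tq * wbcb + k * tT * lambda_n^2,
    c = rtct * ks / k + wbcb * kq + (k + ks * tv) * lambda_n^2,
    d = wbcb * ks / k + ks * lambda_n^2,
    k_q = kq,
    lambda_n = lambda_n
  ), class = "cubic_coefficients")
}

# step-load forcing bracket coefficients: substituting theta = theta1 +
# phi(x) H(t) into the governing equation leaves -phi(x) {a H''' + b2 H''
# + c2 H'} on the right-hand side (the undifferentiated-H terms cancel
# because phi solves the steady equation)
.step_bracket <- function(params) {
  rtct <- .rtct(params); wbcb <- .wbcb(params)
  k <- params$tissue$k; ks <- params$tissue$k_star
  tq <- params$lags$tau_q; tT <- params$lags$tau_T; tv <- params$lags$tau_v
  list(b2 = rtct * .kq(params) + wbcb * (tq - tT),
       c2 = (rtct + wbcb * (tq - tv)) * ks / k)
}
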