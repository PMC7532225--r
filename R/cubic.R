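#' Classify a mode's characteristic cubic
#'
#' Computes the depressed-cubic invariants
#' \deqn{p = \frac{3ac - b^2}{3a^2}, \qquad
#'       q = \frac{2b^3 - 9abc + 27a^2 d}{27 a^3}, \qquad
#'       \Delta = (q/2)^2 + (p/3)^3,}
#' assigns one of four root configurations and returns the roots:
#'
#' * `three_real_distinct` (\eqn{\Delta < 0}): roots from the principal
#'   complex cube root of \eqn{-q/2 + i\sqrt{-\Delta}};
#' * `one_real_pair_complex` (\eqn{\Delta > 0}): one real root
#'   \eqn{r_1} plus the conjugate pair \eqn{\alpha \pm i\beta};
#' * `repeated_double` (\eqn{\Delta = 0}, \eqn{(q/2)^2 = -(p/3)^3 \ne 0}):
#'   a simple root \eqn{r_1} and a double root \eqn{r};
#' * `triple` (\eqn{p = q = 0}): \eqn{r = -b/(3a)}.
#'
#' Floating-point \eqn{\Delta} is never exactly zero on generic input, so
#' the repeated cases are entered through a relative tolerance band
#' \eqn{|\Delta| < 10^{-12}((q/2)^2 + |p/3|^3)}, and distinct roots closer
#' than \eqn{10^{-6} \max|r|} are reclassified as repeated to avoid the
#' catastrophic cancellation in the distinct-root kernel denominators.
#' Every closed-form root is polished by one Newton step on the original
#' cubic (the Cardano expressions lose digits when root magnitudes are
#' widely separated).
#'
#' @param coeffs a `cubic_coefficients` object (scalar entries), or a list
#'   with numeric fields `a > 0`, `b`, `c`, `d`.
#' @return object of class `cubic_analysis`: list with `p`, `q`, `Delta`,
#'   `case`, `roots` (real parts; for the complex case `r1` and
#'   `alpha`, `beta`), and the input coefficients.
#' @seealso [kernel_functions()], [mode_response()]
#' @export
classify_cubic <- function(coeffs) {
  a <- coeffs$a[1]; b <- coeffs$b[1]; cc <- coeffs$c[1]; d <- coeffs$d[1]
  if (a <= 0) {
    stop("leading coefficient a must be > 0 (tau_q = 0 collapses the mode ",
         "equation to lower order; use the degenerate path)", call. = FALSE)
  }
  p <- (3 * a * cc - b^2) / (3 * a^2)
  q <- (2 * b^3 - 9 * a * b * cc + 27 * a^2 * d) / (27 * a^3)
  Delta <- (q / 2)^2 + (p / 3)^3
  shift <- b / (3 * a)
  tiny <- .Machine$double.xmin
  eps <- .Machine$double.eps
  # rounding-noise floors of p, q and Delta, from the magnitudes of the
  # cancelling terms: generic coefficients never give an exact zero, so
  # the degenerate cases are entered through these bands
  eps_p <- eps * (3 * abs(a * cc) + b^2) / (3 * a^2)
  eps_q <- eps * (2 * abs(b)^3 + 9 * abs(a * b * cc) + 27 * a^2 * abs(d)) /
    (27 * a^3)
  tol_rep <- 10 * (abs(q / 2) * eps_q + (p / 3)^2 * eps_p) +
    1e-12 * ((q / 2)^2 + abs(p / 3)^3 + tiny)
  p_scale <- shift^2 + abs(cc / a) + tiny

  newton <- function(r) {
    # one polishing step; guards against a vanishing derivative
    f <- ((a * r + b) * r + cc) * r + d
    fp <- (3 * a * r + 2 * b) * r + cc
    ifelse(abs(fp) > tiny, r - f / fp, r)
  }

  if (abs(p) <= max(10 * eps_p, 1e-10 * p_scale) &&
      abs(q) <= max(10 * eps_q, 1e-10 * p_scale^1.5)) {
    r <- -shift
    out <- list(case = "triple", roots = c(r, r, r))
  } else if (abs(Delta) <= tol_rep) {
    cr <- .cbrt(-q / 2)
    r1 <- newton(2 * cr - shift)
    r <- -cr - shift
    out <- list(case = "repeated_double", roots = c(r1, r, r))
  } else if (Delta > 0) {
    u <- .cbrt(-q / 2 + sqrt(Delta))
    v <- .cbrt(-q / 2 - sqrt(Delta))
    r1 <- u + v - shift
    alpha <- -(u + v) / 2 - shift
    beta <- sqrt(3) / 2 * (u - v)
    r1 <- newton(r1)
    z <- .newton_c(complex(real = alpha, imaginary = beta), a, b, cc, d)
    alpha <- Re(z); beta <- abs(Im(z))
    sc <- max(abs(r1), abs(alpha), abs(beta))
    if (sqrt((alpha - r1)^2 + beta^2) < 1e-5 * max(1, sc)) {
      rr <- (r1 + 2 * alpha) / 3     # all three roots coincide to noise
      out <- list(case = "triple", roots = c(rr, rr, rr))
    } else if (abs(beta) < 1e-6 * sc) {
      out <- list(case = "repeated_double", roots = c(r1, alpha, alpha))
    } else {
      out <- list(case = "one_real_pair_complex",
                  roots = c(r1, alpha, alpha), alpha = alpha, beta = beta)
    }
  } else {
    z <- complex(real = -q / 2, imaginary = sqrt(-Delta))^(1 / 3)  # principal branch
    al <- Re(z); be <- Im(z)
    r <- sort(newton(c(2 * al - shift,
                       -al - sqrt(3) * be - shift,
                       -al + sqrt(3) * be - shift)))
    gaps <- c(r[2] - r[1], r[3] - r[2])
    sc <- max(abs(r))
    if (all(gaps < 1e-6 * sc)) {
      rr <- mean(r)
      out <- list(case = "triple", roots = c(rr, rr, rr))
    } else if (gaps[1] < 1e-6 * sc) {
      out <- list(case = "repeated_double", roots = c(r[3], rep(mean(r[1:2]), 2)))
    } else if (gaps[2] < 1e-6 * sc) {
      out <- list(case = "repeated_double", roots = c(r[1], rep(mean(r[2:3]), 2)))
    } else {
      out <- list(case = "three_real_distinct", roots = r)
    }
  }
  structure(c(out, list(p = p, q = q, Delta = Delta,
                        a = a, b = b, c = cc, d = d)),
            class = "cubic_analysis")
}

.cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

# kernels for one isolated real root r1 and a close real pair m +/- delta,
# with the pair combined analytically through sinh(delta t)/delta so that
# no difference of nearly equal exponentials is ever formed; delta = 0
# reproduces the double-root formulas exactly
.kernels_pair <- function(r1, m, delta) {
  D1 <- (m - r1)^2 - delta^2
  tS <- function(t) {
    x <- delta * t
    t * ifelse(abs(x) < 1e-5, 1 + x^2 / 6, sinh(x) / x)
  }
  Cc <- function(t) cosh(delta * t)
  V2 <- function(t) (exp(r1 * t) + exp(m * t) * ((m - r1) * tS(t) - Cc(t))) / D1
  dV2 <- function(t) (r1 * exp(r1 * t) + exp(m * t) *
                        ((m * (m - r1) - delta^2) * tS(t) - r1 * Cc(t))) / D1
  V0 <- function(t) ((m^2 - delta^2) * exp(r1 * t) + r1 * exp(m * t) *
                       ((m * (m - r1) + delta^2) * tS(t) - (2 * m - r1) * Cc(t))) / D1
  s1 <- r1 + 2 * m
  list(V0 = V0, V1 = function(t) s1 * V2(t) - dV2(t), V2 = V2, dV2 = dV2)
}

.newton_c <- function(z, a, b, cc, d) {
  f <- ((a * z + b) * z + cc) * z + d
  fp <- (3 * a * z + 2 * b) * z + cc
  if (Mod(fp) > .Machine$double.xmin) z - f / fp else z
}

# residual of each root in the original cubic, relative to the largest term
cubic_residual <- function(analysis) {
  a <- analysis$a; b <- analysis$b; cc <- analysis$c; d <- analysis$d
  r <- if (analysis$case == "one_real_pair_complex") {
    c(analysis$roots[1],
      complex(real = analysis$alpha, imaginary = analysis$beta))
  } else analysis$roots
  vapply(r, function(ri) {
    num <- Mod(((a * ri + b) * ri + cc) * ri + d)
    den <- max(Mod(a * ri^3), Mod(b * ri^2), Mod(cc * ri), abs(d),
               .Machine$double.xmin)
    num / den
  }, numeric(1))
}

#' Initial-condition kernel functions of the mode equation
#'
#' Builds the three response functions \eqn{V_0, V_1, V_2} of the monic
#' third-order mode equation: \eqn{V_0} responds to a unit initial value,
#' \eqn{V_1} to a unit initial slope (with the sign convention of the modal
#' solution \eqn{B_n(t) = V_0 B_n(0) - V_1 \dot B_n(0) + V_2 \ddot B_n(0)},
#' so \eqn{\dot V_1(0) = -1}), and \eqn{V_2} to a unit initial curvature.
#' The closed form depends on the root configuration: exponential partial
#' fractions for three distinct real roots, an
#' \eqn{e^{\alpha t}(\cos\beta t, \sin\beta t)} combination for a complex
#' pair, and polynomial-times-exponential forms for repeated roots
#' (e.g. \eqn{V_2 = t^2 e^{rt}/2} for a triple root).  The derivative
#' \eqn{V_2'} is also returned; together with \eqn{V_2} and \eqn{V_0} it
#' assembles the step-load modal response (see [mode_amplitude()]).
#'
#' All evaluators are vectorised in `t` and numerically stable for large
#' times when the roots decay (every exponent is then non-positive).
#'
#' @param analysis a `cubic_analysis` object from [classify_cubic()].
#' @return object of class `kernel_triple`: list of functions
#'   `V0(t)`, `V1(t)`, `V2(t)`, `dV2(t)`.
#' @export
kernel_functions <- function(analysis) {
  stopifnot(inherits(analysis, "cubic_analysis"))
  out <- switch(analysis$case,
    three_real_distinct = {
      r <- analysis$roots
      gaps <- c(r[2] - r[1], r[3] - r[2])
      merge_tol <- 1e-3 * max(1, abs(r))
      if (min(gaps) < merge_tol) {
        # a close (but not numerically repeated) pair: the partial-fraction
        # denominators cancel catastrophically, so evaluate the pair
        # through its merged sinh form instead
        if (gaps[1] <= gaps[2]) {
          .kernels_pair(r[3], mean(r[1:2]), gaps[1] / 2)
        } else {
          .kernels_pair(r[1], mean(r[2:3]), gaps[2] / 2)
        }
      } else {
        r1 <- r[1]; r2 <- r[2]; r3 <- r[3]
        d1 <- (r1 - r2) * (r1 - r3)
        d2 <- (r2 - r3) * (r2 - r1)
        d3 <- (r3 - r1) * (r3 - r2)
        list(
          V0 = function(t) r2 * r3 * exp(r1 * t) / d1 + r3 * r1 * exp(r2 * t) / d2 +
            r1 * r2 * exp(r3 * t) / d3,
          V1 = function(t) (r2 + r3) * exp(r1 * t) / d1 + (r3 + r1) * exp(r2 * t) / d2 +
            (r1 + r2) * exp(r3 * t) / d3,
          V2 = function(t) exp(r1 * t) / d1 + exp(r2 * t) / d2 + exp(r3 * t) / d3,
          dV2 = function(t) r1 * exp(r1 * t) / d1 + r2 * exp(r2 * t) / d2 +
            r3 * exp(r3 * t) / d3
        )
      }
    },
    one_real_pair_complex = {
      r1 <- analysis$roots[1]; al <- analysis$alpha; be <- analysis$beta
      D <- (al - r1)^2 + be^2
      list(
        V0 = function(t) ((al^2 + be^2) * exp(r1 * t) + exp(al * t) / be *
          (-be * (2 * al * r1 - r1^2) * cos(be * t) +
             r1 * (al^2 - be^2 - al * r1) * sin(be * t))) / D,
        V1 = function(t) (2 * al * exp(r1 * t) + exp(al * t) / be *
          (-2 * al * be * cos(be * t) +
             (al^2 - be^2 - r1^2) * sin(be * t))) / D,
        V2 = function(t) (exp(r1 * t) + exp(al * t) / be *
          (-be * cos(be * t) + (al - r1) * sin(be * t))) / D,
        dV2 = function(t) (r1 * exp(r1 * t) + exp(al * t) *
          (-r1 * cos(be * t) + (al^2 - al * r1 + be^2) / be * sin(be * t))) / D
      )
    },
    repeated_double = {
      r1 <- analysis$roots[1]; r <- analysis$roots[2]
      g <- (r1 - r)^2
      list(
        V0 = function(t) r^2 * (exp(r1 * t) - exp(r * t)) / g + exp(r * t) +
          r1 * r * t * exp(r * t) / (r - r1),
        V1 = function(t) 2 * r * (exp(r1 * t) - exp(r * t)) / g +
          (r + r1) * t * exp(r * t) / (r - r1),
        V2 = function(t) (exp(r1 * t) - exp(r * t)) / g + t * exp(r * t) / (r - r1),
        dV2 = function(t) (r1 * exp(r1 * t) - r * exp(r * t)) / g +
          (1 + r * t) * exp(r * t) / (r - r1)
      )
    },
    triple = {
      r <- analysis$roots[1]
      list(
        V0 = function(t) (1 - r * t + r^2 * t^2 / 2) * exp(r * t),
        V1 = function(t) (-t + r * t^2) * exp(r * t),
        V2 = function(t) t^2 / 2 * exp(r * t),
        dV2 = function(t) (t + r * t^2 / 2) * exp(r * t)
      )
    },
    stop("unknown cubic case: ", analysis$case)
  )
  structure(out, class = "kernel_triple")
}

#' Modal response from initial data and optional forcing
#'
#' Evaluates
#' \eqn{B_n(t) = V_0(t) B_n(0) - V_1(t) \dot B_n(0) + V_2(t) \ddot B_n(0)
#' + \frac{1}{a}\int_0^t f(\eta) V_2(t - \eta) \mathrm{d}\eta,}
#' the general solution of the mode equation for given initial data and a
#' smooth forcing `f`.  The convolution is evaluated by adaptive
#' quadrature; step loads do not come through here (their distributional
#' forcing is absorbed into the closed-form combination used by
#' [mode_amplitude()]).
#'
#' @param analysis a `cubic_analysis` object.
#' @param B0,Bdot0,Bddot0 initial value, slope and curvature of the mode.
#' @param t evaluation times (vectorised), `t >= 0`.
#' @param forcing optional vectorised function `f(t)` (smooth; units of the
#'   original, non-monic equation -- the \eqn{1/a} factor is applied here).
#' @return \eqn{B_n(t)}, same length as `t`.
#' @export
mode_response <- function(analysis, B0, Bdot0, Bddot0, t, forcing = NULL) {
  kf <- kernel_functions(analysis)
  out <- kf$V0(t) * B0 - kf$V1(t) * Bdot0 + kf$V2(t) * Bddot0
  if (!is.null(forcing)) {
    conv <- vapply(t, function(ti) {
      if (ti == 0) return(0)
      stats::integrate(function(eta) forcing(eta) * kf$V2(ti - eta),
                       0, ti, rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1))
    out <- out + conv / analysis$a
  }
  out
}
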