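#' Bio-heat conduction model object
#'
#' Central constructor of the package: binds a validated parameter set and
#' a series truncation into a model object whose methods evaluate the
#' solution.  `predict()` returns the temperature field on any grid,
#' `summary()` reports the derived physical quantities (steady decay
#' rate, thermal wave speed, per-mode root structure), and `plot()` draws
#' probe histories or profiles.
#'
#' The modal machinery (eigenvalues, projection coefficients, cubic root
#' classification) is precomputed at construction; field evaluation then
#' only sums kernels over the requested grid.
#'
#' @param params a [bioheat_params()] parameter set.
#' @param n_terms series truncation (default 300).
#' @return object of class `bioheat_model`.
#' @examples
#' m <- bioheat_model(bioheat_params())
#' summary(m)
#' fld <- predict(m, x = 0.0045, t = seq(0, 100, 1))
#' @export
bioheat_model <- function(params = bioheat_params(), n_terms = 300) {
  validate_params(params)
  es <- eigensystem(params$load$case, params$geom$L, n_terms)
  co <- cubic_coefficients(params, es$lambda)
  analyses <- NULL
  if (co$a[1] > 0) {
    analyses <- lapply(seq_len(n_terms), function(i)
      classify_cubic(lapply(co[c("a", "b", "c", "d")], `[`, i)))
  }
  structure(list(params = params, n_terms = n_terms,
                 eigensystem = es,
                 c_n = projection_coefficient(params, seq_len(n_terms)),
                 steady = steady_profile(params),
                 analyses = analyses),
            class = "bioheat_model")
}

#' @export
print.bioheat_model <- function(x, ...) {
  cat(sprintf("<bioheat_model> %s, %s, N = %d modes\n",
              x$params$variant, x$params$load$case, x$n_terms))
  print(x$params)
  invisible(x)
}

#' @rdname bioheat_model
#' @param object a `bioheat_model`.
#' @param ... unused.
#' @export
summary.bioheat_model <- function(object, ...) {
  p <- object$params
  vs <- if (p$lags$tau_q > 0) {
    sqrt(p$tissue$k / (p$lags$tau_q * .rtct(p)))
  } else Inf
  cases <- if (is.null(object$analyses)) {
    c(first_order = object$n_terms)
  } else {
    table(vapply(object$analyses, `[[`, character(1), "case"))
  }
  slowest <- if (is.null(object$analyses)) {
    mu1 <- (.wbcb(p) + p$tissue$k * object$eigensystem$lambda[1]^2) / .rtct(p)
    -mu1
  } else {
    max(vapply(object$analyses, function(a) {
      if (a$case == "one_real_pair_complex") max(a$roots[1], a$alpha)
      else max(a$roots)
    }, numeric(1)))
  }
  structure(list(params = p, n_terms = object$n_terms,
                 lambda_s = object$steady$lambda_s,
                 wave_speed = vs,
                 surface_steady = object$steady$phi(0),
                 midpoint_steady = object$steady$phi(p$geom$L / 2),
                 root_cases = cases,
                 slowest_rate = slowest),
            class = "summary.bioheat_model")
}

#' @export
print.summary.bioheat_model <- function(x, ...) {
  p <- x$params
  cat(sprintf("Bio-heat model: %s, %s, N = %d\n",
              p$variant, p$load$case, x$n_terms))
  cat(sprintf("  steady decay rate lambda = %.4g 1/m\n", x$lambda_s))
  if (is.finite(x$wave_speed)) {
    cat(sprintf("  C-V wave speed           = %.4g m/s\n", x$wave_speed))
  } else {
    cat("  C-V wave speed           = Inf (Pennes: instantaneous)\n")
  }
  cat(sprintf("  steady increment: surface %.4g C, midpoint %.4g C\n",
              x$surface_steady, x$midpoint_steady))
  cat(sprintf("  slowest modal decay rate = %.4g 1/s (time scale %.4g s)\n",
              x$slowest_rate, -1 / x$slowest_rate))
  cat("  modal root configurations:\n")
  for (nm in names(x$root_cases))
    cat(sprintf("    %-22s %d\n", nm, as.integer(x$root_cases[[nm]])))
  invisible(x)
}

#' @rdname bioheat_model
#' @param x positions (m).
#' @param t times (s).
#' @export
predict.bioheat_model <- function(object, x, t, ...) {
  temperature_field(object$params, x_grid = x, t_grid = t,
                    n_terms = object$n_terms)
}

#' @rdname bioheat_model
#' @param at probe position (m) for history plots, probe time (s) for
#'   profile plots.
#' @param type `"history"` or `"profile"`.
#' @export
plot.bioheat_model <- function(x, type = c("history", "profile"),
                               at = NULL, t = NULL, ...) {
  type <- match.arg(type)
  L <- x$params$geom$L
  if (type == "history") {
    at <- if (is.null(at)) L / 2 else at
    t <- if (is.null(t)) seq(0, 300, 0.5) else t
    fld <- predict(x, x = at, t = t)
    plot(fld, type = "history", at = at, ...)
  } else {
    t <- if (is.null(t)) 50 else t
    fld <- predict(x, x = seq(0, L, length.out = 201), t = t)
    plot(fld, type = "profile", at = t, ...)
  }
}
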