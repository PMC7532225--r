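# Independent oracles used across the suite.  These deliberately avoid the
# package's own closed-form paths: kernels are checked against direct
# numerical integration of the mode ODE, projections against adaptive
# quadrature, roots against polyroot(), and the steady profile against a
# finite-difference boundary-value solve.

# reference skin-tissue parameter set used in the worked examples
ref_params <- function(...) bioheat_params(...)

# numerically integrate the monic third-order kernel ODE
#   y''' + (b/a) y'' + (c/a) y' + (d/a) y = 0
# from the given initial data; returns y(t) on the requested grid
ode_kernel_oracle <- function(a, b, cc, d, y0, t, rtol = 1e-10) {
  rhs <- function(tt, y, parms) {
    list(c(y[2], y[3], -(b * y[3] + cc * y[2] + d * y[1]) / a))
  }
  out <- deSolve::lsoda(y0, c(0, t[t > 0]), rhs, NULL,
                        rtol = rtol, atol = 1e-12)
  approx(out[, 1], out[, 2], xout = t)$y
}

# kernel initial data for (V0, V1, V2) under the package's sign convention
kernel_ics <- list(V0 = c(1, 0, 0), V1 = c(0, -1, 0), V2 = c(0, 0, 1))

# cubic coefficients (a, b, c, d) from prescribed roots
cubic_from_roots <- function(roots, a = 1) {
  e1 <- sum(roots)
  e2 <- roots[1] * roots[2] + roots[1] * roots[3] + roots[2] * roots[3]
  e3 <- prod(roots)
  list(a = a, b = -a * Re(e1), c = a * Re(e2), d = -a * Re(e3))
}

# random stable cubic of a requested root configuration; root magnitudes
# and separations are kept moderate so that the finite-difference identity
# checks are not dominated by their own truncation/roundoff trade-off
# (near-coincident roots have dedicated tests of their own)
random_stable_cubic <- function(case) {
  a <- runif(1, 0.5, 2)
  switch(case,
    three_real_distinct = {
      repeat {
        r <- -sort(runif(3, 0.05, 2))
        if (min(abs(diff(r))) > 0.2) break
      }
      cubic_from_roots(r, a)
    },
    one_real_pair_complex = {
      r1 <- -runif(1, 0.05, 2)
      al <- -runif(1, 0.05, 2)
      be <- runif(1, 0.1, 2)
      cubic_from_roots(c(r1, complex(real = al, imaginary = be),
                         complex(real = al, imaginary = -be)), a)
    },
    repeated_double = {
      repeat {
        r1 <- -runif(1, 0.05, 2); r <- -runif(1, 0.05, 2)
        if (abs(r1 - r) > 0.2) break
      }
      cubic_from_roots(c(r1, r, r), a)
    },
    triple = {
      r <- -runif(1, 0.05, 2)
      cubic_from_roots(c(r, r, r), a)
    })
}

# quadrature oracle for the eigenbasis projection of the steady profile
quad_projection <- function(params, n) {
  sp <- steady_profile(params)
  L <- params$geom$L
  if (params$load$case == "constant_temperature") {
    Y <- function(x) sin(n * pi / L * x)
  } else {
    Y <- function(x) cos((2 * n - 1) * pi / (2 * L) * x)
  }
  2 / L * stats::integrate(function(x) Y(x) * sp$phi(x), 0, L,
                           rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# finite-difference two-point boundary-value oracle for the steady
# equation phi'' = lambda^2 phi with phi(0) = th0, phi(L) = 0
bvp_steady_oracle <- function(params, x_eval, m = 800) {
  L <- params$geom$L
  lam2 <- decay_rate(params)^2
  h <- L / (m + 1)
  xi <- seq_len(m) * h
  A <- diag(-2 - lam2 * h^2, m)
  A[cbind(1:(m - 1), 2:m)] <- 1
  A[cbind(2:m, 1:(m - 1))] <- 1
  rhs <- numeric(m)
  rhs[1] <- -params$load$theta_0
  v <- solve(A, rhs)
  approx(c(0, xi, L), c(params$load$theta_0, v, 0), xout = x_eval)$y
}

# one-sided finite-difference derivatives at t = 0+ (first derivative
# O(h^4), second derivative O(h^3))
fd1_onesided <- function(f, h = 1e-4) {
  v <- f(h * 0:4)
  (-25 * v[1] + 48 * v[2] - 36 * v[3] + 16 * v[4] - 3 * v[5]) / (12 * h)
}
fd2_onesided <- function(f, h = 1e-3) {
  v <- f(h * 0:4)
  (35 * v[1] - 104 * v[2] + 114 * v[3] - 56 * v[4] + 11 * v[5]) / (12 * h^2)
}

# largest subsequent drop of a time history (0 for a monotone rise);
# the oscillation measure used for the thermal-displacement-lag checks
max_subsequent_drop <- function(h) {
  max(h - rev(cummin(rev(h))))
}
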