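test_that("eigensystems carry the right eigenvalues and orthogonality", {
  es1 <- eigensystem("constant_temperature", L = 0.009, N = 4)
  expect_equal(es1$lambda[1], pi / 0.009)
  es2 <- eigensystem("constant_flux", L = 0.009, N = 4)
  expect_equal(es2$lambda[1], pi / (2 * 0.009))
  # numerical orthogonality with L/2 normalisation (trapezoid, fine grid)
  for (es in list(es1, es2)) {
    np <- 20000
    xs <- seq(0, es$L, length.out = np + 1)
    w <- c(0.5, rep(1, np - 1), 0.5) * es$L / np
    Y <- es$Y(xs)
    G <- crossprod(Y, Y * w)
    expect_equal(unname(diag(G)), rep(es$L / 2, 4), tolerance = 1e-10)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-10 * es$L)
  }
})

test_that("modal amplitudes start at minus the projection and fade", {
  p <- ref_params()
  for (n in c(1, 7)) {
    cn <- projection_coefficient(p, n)
    expect_equal(mode_amplitude(p, n, 0), -cn, tolerance = 1e-10)
    expect_lt(abs(mode_amplitude(p, n, 2000)), 1e-8 * abs(cn))
  }
  # a zero load never moves
  p0 <- ref_params(theta_0 = 0)
  expect_equal(mode_amplitude(p0, 3, c(0, 10, 50)), c(0, 0, 0))
  # the Pennes degenerate path is a pure exponential decay
  pen <- reduce_model(ref_params(), "Pennes")
  mu1 <- (1.87e-3 * 1060 * 3770 + 0.235 * (pi / 0.009)^2) / (1190 * 3600)
  expect_equal(mode_amplitude(pen, 1, c(0, 5, 20)),
               -projection_coefficient(pen, 1) * exp(-mu1 * c(0, 5, 20)),
               tolerance = 1e-12)
})

test_that("modal amplitudes solve the mode equation (ramp oracle)", {
  # independent check of the step-load reading: replace the Heaviside by a
  # narrow smooth ramp r(t), integrate the mode equation from rest under
  # the explicit forcing -c_n [a r''' + b2 r'' + c2 r'], and compare once
  # the ramp has completed.  The distributional solution is the limit of
  # this construction as the ramp narrows.
  p <- ref_params()
  tr <- 0.1
  rd <- list(  # derivatives of the quintic smoothstep ramp
    d1 = function(t) ifelse(t <= 0 | t >= tr, 0,
      (30 * (t / tr)^2 - 60 * (t / tr)^3 + 30 * (t / tr)^4) / tr),
    d2 = function(t) ifelse(t <= 0 | t >= tr, 0,
      (60 * (t / tr) - 180 * (t / tr)^2 + 120 * (t / tr)^3) / tr^2),
    d3 = function(t) ifelse(t <= 0 | t >= tr, 0,
      (60 - 360 * (t / tr) + 360 * (t / tr)^2) / tr^3)
  )
  for (variant in c("TPL", "CV")) {
    pv <- if (variant == "TPL") p else reduce_model(p, variant)
    for (n in c(1, 3)) {
      es <- eigensystem("constant_temperature", pv$geom$L, n)
      co <- cubic_coefficients(pv, es$lambda[n])
      cn <- projection_coefficient(pv, n)
      br <- tplheat:::.step_bracket(pv)
      f <- function(t) -cn * (co$a * rd$d3(t) + br$b2 * rd$d2(t) +
                                br$c2 * rd$d1(t))
      rhs <- function(tt, y, parms) {
        list(c(y[2], y[3],
               (f(tt) - co$b * y[3] - co$c * y[2] - co$d * y[1]) / co$a))
      }
      tg <- c(seq(0, tr, tr / 50), seq(1, 200, 1))
      out <- deSolve::lsoda(c(0, 0, 0), tg, rhs, NULL,
                            rtol = 1e-10, atol = 1e-13)
      got <- mode_amplitude(pv, n, tg[tg >= 1])
      ref <- out[tg >= 1, 2]
      expect_equal(got, ref, tolerance = 5e-3)
    }
  }
})

test_that("temperature field honours boundary and initial conditions", {
  p <- ref_params()
  fld <- temperature_field(p, c(0, 0.003, 0.009), c(0, 10, 50), n_terms = 200)
  expect_equal(fld$theta[3, ], c(0, 0, 0))             # inner face exact
  expect_equal(fld$theta[1, ], c(43, 43, 43))          # heated face exact
  # interior start within truncation tolerance
  xs <- p$geom$L * seq_len(20) / 21
  f0 <- temperature_field(p, xs, 0, n_terms = 300)
  expect_lt(max(abs(f0$theta)), 0.01 * 43)
  expect_error(temperature_field(p, 0.0045, -1), "t_grid")
  expect_error(temperature_field(p, 0.02, 1))          # outside the slab
})

test_that("the field relaxes to the steady profile", {
  p <- ref_params()
  xs <- p$geom$L * seq_len(20) / 21
  fld <- temperature_field(p, xs, 600, n_terms = 300)
  sp <- steady_profile(p)
  expect_lt(max(abs(fld$theta[, 1] - sp$phi(xs))), 0.01 * 43)
})

test_that("wavefront detection finds the thermal wave where expected", {
  cvp <- validation_params("CV")
  tg <- seq(0, 60, 0.25)
  V <- cv_wave_speed(cvp)
  h2 <- temperature_field(cvp, 0.002, tg, 300)
  arr2 <- wavefront_arrival(tg, as.numeric(h2$theta), load_scale(cvp))
  expect_lt(abs(arr2 - 0.002 / V), 1)
  # doubling the depth doubles the arrival time (constant wave speed)
  h1 <- temperature_field(cvp, 0.001, tg, 300)
  arr1 <- wavefront_arrival(tg, as.numeric(h1$theta), load_scale(cvp))
  expect_lt(abs(arr2 / arr1 - 2), 0.1)
  # the literal first crossing detects the truncation precursor earlier
  arr_first <- wavefront_arrival(tg, as.numeric(h2$theta), load_scale(cvp),
                                 rule = "first")
  expect_lte(arr_first, arr2)
  # nothing arrives in a too-short window
  short <- temperature_field(cvp, 0.004, seq(0, 20, 0.25), 300)
  expect_true(is.na(wavefront_arrival(seq(0, 20, 0.25),
                                      as.numeric(short$theta),
                                      load_scale(cvp))))
  expect_error(wavefront_arrival(c(0, 1), c(0, 1), 43), "0.5 s")
})

test_that("model comparison aligns the four conduction models", {
  p <- ref_params()
  tg <- seq(0, 30, 1)
  cmpdf <- compare_models(p, x = p$geom$L, t_grid = tg, n_terms = 50)
  expect_setequal(unique(cmpdf$variant), c("TPL", "DPL", "CV", "Pennes"))
  expect_equal(cmpdf$theta_C, rep(0, nrow(cmpdf)))   # inner face, all models
})

test_that("truncation refinement converges monotonically at the probe", {
  p <- ref_params()
  rep1 <- convergence_report(p, probe_x = 0.0045,
                             probe_t = seq(0, 120, 2),
                             n_list = c(1, 200, 400))
  expect_gt(rep1$max_abs_diff[1], rep1$max_abs_diff[2])
  expect_s3_class(rep1, "convergence_report")
})
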