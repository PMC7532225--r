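test_that("parameter validation accepts physical sets and names offenders", {
  expect_no_warning(bioheat_params())            # tau_v < tau_T < tau_q
  expect_no_warning(bioheat_params(tau_q = 0, tau_T = 0, tau_v = 0,
                                   k_star = 0, variant = "Pennes"))
  # ordering violation with all lags positive is a warning, not an error
  expect_warning(bioheat_params(tau_v = 7), "ordering")
  expect_error(bioheat_params(L = 0), "geom\\$L")
  expect_error(bioheat_params(k = -0.2), "tissue\\$k")
  expect_error(bioheat_params(rho_t = 0), "rho_t")
  expect_error(bioheat_params(R_d = 1.2), "R_d")
  # variant labels must match the lag/conductivity structure
  expect_error(bioheat_params(variant = "DPL"), "k_star")
  expect_error(bioheat_params(variant = "CV", k_star = 0), "tau_T")
})

test_that("C-V wave speed matches direct arithmetic and scaling laws", {
  # validation-scenario configuration, quoted to three significant figures
  p <- bioheat_params(k = 0.2, tau_q = 20, rho_t = 1000, c_t = 4200,
                      rho_b = 1000, c_b = 4200, omega_b = 0.5e-3,
                      k_star = 0, tau_T = 0, tau_v = 0, variant = "CV")
  expect_equal(cv_wave_speed(p), 4.88e-5, tolerance = 0.005 / 4.88)
  # direct arithmetic oracle on the reference skin set
  p2 <- reduce_model(ref_params(), "CV")
  expect_equal(cv_wave_speed(p2), sqrt(0.235 / (16 * 1190 * 3600)),
               tolerance = 1e-12)
  # quadrupling the flux lag halves the speed
  p4 <- p; p4$lags$tau_q <- 4 * p$lags$tau_q
  expect_equal(cv_wave_speed(p4), cv_wave_speed(p) / 2, tolerance = 1e-12)
  # no flux lag: instantaneous propagation
  pen <- reduce_model(p, "Pennes")
  expect_warning(v <- cv_wave_speed(pen), "infinite")
  expect_identical(v, Inf)
})

test_that("model reduction zeroes the right parameters and is idempotent", {
  tpl <- ref_params()
  cv <- reduce_model(tpl, "CV")
  expect_identical(cv$tissue$k_star, 0)
  expect_identical(cv$lags$tau_T, 0)
  expect_identical(cv$lags$tau_v, 0)
  expect_identical(cv$lags$tau_q, tpl$lags$tau_q)  # flux lag preserved
  pen <- reduce_model(tpl, "Pennes")
  expect_true(all(unlist(pen$lags) == 0) && pen$tissue$k_star == 0)
  expect_identical(reduce_model(cv, "CV"), cv)
  dpl <- reduce_model(tpl, "DPL")
  expect_identical(dpl$lags$tau_T, tpl$lags$tau_T)
  expect_identical(dpl$tissue$k_star, 0)
})

test_that("cubic coefficients match a term-by-term arithmetic oracle", {
  p <- ref_params()
  lam1 <- pi / p$geom$L
  co <- cubic_coefficients(p, lam1)
  # independent evaluation, term by term
  rtct <- 1190 * 3600; wbcb <- 1.87e-3 * 1060 * 3770
  kq <- 1 + 16 * 0.1 / 0.235
  expect_equal(co$a, 16 * rtct, tolerance = 1e-14)
  expect_equal(co$b, rtct * kq + 16 * wbcb + 0.235 * 6 * lam1^2,
               tolerance = 1e-14)
  expect_equal(co$c, rtct * 0.1 / 0.235 + wbcb * kq + (0.235 + 0.1 * 2) * lam1^2,
               tolerance = 1e-14)
  expect_equal(co$d, wbcb * 0.1 / 0.235 + 0.1 * lam1^2, tolerance = 1e-14)
  expect_equal(co$k_q, kq, tolerance = 1e-14)
})

test_that("zero rate of conductivity kills the constant term exactly", {
  cv <- reduce_model(ref_params(), "CV")
  co <- cubic_coefficients(cv, c(100, 1000, 5000))
  expect_identical(co$d, c(0, 0, 0))
})

test_that("the no-perfusion C-V limit gives pure telegraph coefficients", {
  p <- bioheat_params(omega_b = 0, tau_T = 0, tau_v = 0, k_star = 0,
                      variant = "CV")
  lam <- 500
  co <- cubic_coefficients(p, lam)
  expect_equal(co$b, p$tissue$rho_t * p$tissue$c_t, tolerance = 1e-14)
  expect_equal(co$c, p$tissue$k * lam^2, tolerance = 1e-14)
  expect_identical(co$d, 0)
})

test_that("cubic coefficients are non-decreasing in the eigenvalue", {
  p <- ref_params()
  lam <- seq(100, 2e5, length.out = 40)
  co <- cubic_coefficients(p, lam)
  expect_true(all(diff(co$b) >= 0))
  expect_true(all(diff(co$c) >= 0))
  expect_true(all(diff(co$d) >= 0))
  # dimensional sanity: a over the volumetric heat capacity is the flux
  # lag (seconds); b over it is dimensionless and >= 1
  expect_equal(co$a[1] / (p$tissue$rho_t * p$tissue$c_t), p$lags$tau_q)
  expect_true(all(co$b / (p$tissue$rho_t * p$tissue$c_t) >= 1))
})
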