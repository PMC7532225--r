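test_that("cubic classification recovers known factorizations", {
  # (r-1)(r-2)(r-3): three real distinct roots
  an <- classify_cubic(list(a = 1, b = -6, c = 11, d = -6))
  expect_identical(an$case, "three_real_distinct")
  expect_equal(sort(an$roots), c(1, 2, 3), tolerance = 1e-10)
  # r^3: triple root at 0
  an0 <- classify_cubic(list(a = 1, b = 0, c = 0, d = 0))
  expect_identical(an0$case, "triple")
  expect_equal(an0$p, 0)
  expect_equal(an0$q, 0)
  expect_equal(an0$Delta, 0)
  expect_equal(an0$roots, c(0, 0, 0))
  # (r+1)(r^2+4r+13): one real root and the pair -2 +/- 3i
  anc <- classify_cubic(list(a = 1, b = 5, c = 17, d = 13))
  expect_identical(anc$case, "one_real_pair_complex")
  expect_equal(anc$roots[1], -1, tolerance = 1e-10)
  expect_equal(anc$alpha, -2, tolerance = 1e-10)
  expect_equal(anc$beta, 3, tolerance = 1e-10)
  # (r+1)(r+2)^2: double root
  and <- classify_cubic(cubic_from_roots(c(-1, -2, -2)))
  expect_identical(and$case, "repeated_double")
  expect_equal(and$roots, c(-1, -2, -2), tolerance = 1e-8)
  expect_error(classify_cubic(list(a = 0, b = 1, c = 1, d = 1)), "tau_q")
})

test_that("roots agree with the polynomial-root oracle on random cubics", {
  set.seed(7)
  for (i in 1:25) {
    co <- random_stable_cubic(sample(c("three_real_distinct",
                                       "one_real_pair_complex"), 1))
    an <- classify_cubic(co)
    ref <- polyroot(c(co$d, co$c, co$b, co$a))
    mine <- if (an$case == "one_real_pair_complex") {
      c(complex(real = an$roots[1]),
        complex(real = an$alpha, imaginary = an$beta),
        complex(real = an$alpha, imaginary = -an$beta))
    } else as.complex(an$roots)
    expect_equal(sort(Re(mine)), sort(Re(ref)), tolerance = 1e-7)
    expect_equal(sort(abs(Im(mine))), sort(abs(Im(ref))), tolerance = 1e-7)
  }
})

test_that("every modal root of the reference set satisfies the cubic", {
  p <- ref_params()
  es <- eigensystem("constant_temperature", p$geom$L, 300)
  co <- cubic_coefficients(p, es$lambda)
  worst_res <- 0
  all_stable <- TRUE
  for (i in 1:300) {
    an <- classify_cubic(lapply(co[c("a", "b", "c", "d")], `[`, i))
    worst_res <- max(worst_res, cubic_residual(an))
    re_parts <- if (an$case == "one_real_pair_complex") {
      c(an$roots[1], an$alpha)
    } else an$roots
    all_stable <- all_stable && all(re_parts < 0)
  }
  expect_lt(worst_res, 1e-8)
  expect_true(all_stable)   # prerequisite of the steady-state limit
})

test_that("kernel functions carry the Green-function initial data", {
  set.seed(11)
  cases <- c("three_real_distinct", "one_real_pair_complex",
             "repeated_double", "triple")
  for (case in cases) {
    kf <- kernel_functions(classify_cubic(random_stable_cubic(case)))
    expect_equal(kf$V0(0), 1, tolerance = 1e-12)
    expect_equal(fd1_onesided(kf$V0), 0, tolerance = 1e-6)
    expect_equal(fd2_onesided(kf$V0), 0, tolerance = 1e-6)
    expect_equal(kf$V1(0), 0, tolerance = 1e-12)
    expect_equal(fd1_onesided(kf$V1), -1, tolerance = 1e-6)
    expect_equal(kf$V2(0), 0, tolerance = 1e-12)
    expect_equal(fd1_onesided(kf$V2), 0, tolerance = 1e-6)
    expect_equal(fd2_onesided(kf$V2), 1, tolerance = 1e-6)
    expect_equal(kf$dV2(0), 0, tolerance = 1e-12)
  }
})

test_that("kernels reproduce numerically integrated mode responses", {
  tg <- seq(0, 50, 0.5)
  # three distinct roots {-1,-2,-3}: V2 is the impulse response of
  # y''' + 6 y'' + 11 y' + 6 y = 0 started with unit curvature
  co <- cubic_from_roots(c(-1, -2, -3))
  kf <- kernel_functions(classify_cubic(co))
  ref <- ode_kernel_oracle(co$a, co$b, co$c, co$d, kernel_ics$V2, tg)
  expect_equal(kf$V2(tg), ref, tolerance = 1e-7)
  # triple root -2: closed polynomial-exponential form
  expect_equal(kernel_functions(classify_cubic(cubic_from_roots(c(-2, -2, -2))))$V2(tg),
               tg^2 / 2 * exp(-2 * tg), tolerance = 1e-10)
  # complex pair: oscillatory kernels against the same oracle
  coc <- cubic_from_roots(c(-0.5, complex(real = -0.2, imaginary = 1.3),
                            complex(real = -0.2, imaginary = -1.3)))
  kfc <- kernel_functions(classify_cubic(coc))
  for (k in c("V0", "V1", "V2")) {
    ref <- ode_kernel_oracle(coc$a, coc$b, coc$c, coc$d, kernel_ics[[k]], tg)
    expect_equal(kfc[[k]](tg), ref, tolerance = 1e-7)
  }
})

test_that("mode response combines initial data linearly and decays", {
  an <- classify_cubic(cubic_from_roots(c(-1, -2, -3)))
  tg <- seq(0, 200, 1)
  expect_equal(mode_response(an, 0, 0, 0, tg), rep(0, length(tg)))
  kf <- kernel_functions(an)
  expect_equal(mode_response(an, 1, 0, 0, tg), kf$V0(tg))
  resp <- mode_response(an, 1, 0.5, -0.2, tg)
  ref <- ode_kernel_oracle(1, 6, 11, 6, c(1, 0.5, -0.2), tg)
  expect_equal(resp, ref, tolerance = 1e-7)
  expect_lt(abs(resp[length(tg)]), 1e-10)   # all roots decay
})

test_that("forced mode response matches the convolution oracle", {
  co <- cubic_from_roots(c(-1, -2, -3), a = 2)
  an <- classify_cubic(co)
  f <- function(t) sin(0.3 * t)
  tg <- c(0, 1, 5, 10)
  resp <- mode_response(an, 0, 0, 0, tg, forcing = f)
  rhs <- function(tt, y, parms) {
    list(c(y[2], y[3],
           (f(tt) - co$b * y[3] - co$c * y[2] - co$d * y[1]) / co$a))
  }
  out <- deSolve::lsoda(c(0, 0, 0), tg, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(resp, out[, 2], tolerance = 1e-7)
})

test_that("kernels vary continuously across the discriminant boundary", {
  # family r^3 + 3 r^2 + 3 r + d has a triple root at d = 1; bracket the
  # crossing and shrink it by bisection
  v2_at <- function(d) kernel_functions(classify_cubic(
    list(a = 1, b = 3, c = 3, d = d)))$V2(1.5)
  gap <- vapply(c(1e-3, 1e-5, 1e-7), function(eps) {
    abs(v2_at(1 + eps) - v2_at(1 - eps))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 1e-6)
})

test_that("nearly coincident roots fall back to the repeated formulas", {
  co <- cubic_from_roots(c(-1, -2, -2 - 1e-9))
  an <- classify_cubic(co)
  expect_identical(an$case, "repeated_double")
  kf <- kernel_functions(an)
  tg <- seq(0, 20, 0.25)
  ref <- ode_kernel_oracle(co$a, co$b, co$c, co$d, kernel_ics$V2, tg)
  expect_equal(kf$V2(tg), ref, tolerance = 1e-6)
})
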