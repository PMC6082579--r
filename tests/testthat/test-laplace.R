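test_that("Laplace flux matches the frozen reference value", {
  # arbitrary-precision reference computed once during development
  expect_equal(laplace_flux(0.01, r0 = 17, D = 2.5), 0.265911884398,
               tolerance = 1e-10)
})

test_that("Laplace flux limits: certain absorption and release on the target", {
  expect_equal(laplace_flux(0, 17, 2.5), 1)
  expect_equal(laplace_flux(c(0, 1e-12), 17, 2.5)[1], 1)
  expect_equal(laplace_flux(c(0.1, 2), 5, 2.5), c(1, 1))   # r0 = ra
  # lambda -> 0 continuity
  expect_equal(laplace_flux(1e-10, 17, 2.5), 1, tolerance = 1e-6)
  expect_error(laplace_flux(-1, 17, 2.5), "nonnegative")
  expect_error(laplace_flux(0.1, 30, 2.5), "outside the allowed range")
})

test_that("Bessel route equals the hyperbolic route across the sweep", {
  lam <- 10^seq(-4, 2, length.out = 25)
  for (r0 in c(6, 11, 14, 17, 20, 24)) {
    a <- laplace_flux(lam, r0, 2.5)
    b <- laplace_flux_bessel(lam, r0, 2.5)
    expect_lt(max(abs(a - b) / abs(a)), 1e-10)
  }
  expect_error(laplace_flux_bessel(0, 17, 2.5), "lambda > 0")
})

test_that("large-lambda flux follows the free-space exponential", {
  # for q(R - r0) >> 1 the wall is invisible: P -> (ra/r0) e^{-(r0-ra) q}
  lam <- c(50, 100, 400)
  for (r0 in c(11, 17, 20)) {
    q <- sqrt(lam / 2.5)
    free <- (5 / r0) * exp(-(r0 - 5) * q)
    got <- laplace_flux(lam, r0, 2.5)
    expect_equal(got, free, tolerance = 1e-8)
  }
})

test_that("small-lambda flux expands as 1 - lambda * MFPT", {
  for (r0 in c(11, 17, 20)) {
    lam <- 1e-7
    expect_equal(laplace_flux(lam, r0, 2.5), 1 - lam * mfpt(r0, 2.5),
                 tolerance = 1e-8)
  }
})

test_that("reduced rate polynomial has the exact stated coefficients", {
  p <- slow_rate_poly()
  expect_identical(p[["constant"]], -46875)
  expect_equal(p[["linear"]], 122375 / 30)
  expect_identical(p[["quadratic"]], 0)
  expect_identical(p[["cubic"]], -1.5)
})

test_that("slow rate has the frozen value and is linear in D", {
  # 1/k = 355.3255 s at r0 = 17, D = 2.5 (exact rational: k = 1275/453040 * 2.5/2.5)
  expect_equal(slow_rate(17, 2.5), 2.5 * 17 / 15101.33333333333,
               tolerance = 1e-12)
  expect_equal(1 / slow_rate(17, 2.5), 355.3255, tolerance = 1e-6)
  expect_equal(slow_rate(17, 5.0) / slow_rate(17, 2.5), 2)
  expect_error(slow_rate(5, 2.5), "outside the allowed range")
})

test_that("regime densities are normalised as stated", {
  # slow: integrates to 1
  k <- slow_rate(17, 2.5)
  expect_equal(integrate(slow_pdf, 0, Inf, r0 = 17, D = 2.5)$value, 1,
               tolerance = 1e-7)
  expect_equal(slow_pdf(1 / k, 17, 2.5), k * exp(-1))
  expect_equal(slow_pdf(355.3255, 17, 2.5), 1.03533e-3, tolerance = 1e-5)
  # fast: total mass is the transient hitting probability ra/r0
  for (r0 in c(11, 17, 20))
    expect_equal(integrate(fast_pdf, 0, Inf, r0 = r0, D = 2.5,
                           rel.tol = 1e-10)$value, 5 / r0, tolerance = 1e-8)
})

test_that("fast density has its mode at (r0 - ra)^2 / (6 D)", {
  expect_equal((20 - 5)^2 / (6 * 2.5), 15)
  opt <- optimize(fast_pdf, c(1, 100), r0 = 20, D = 2.5, maximum = TRUE)
  expect_equal(opt$maximum, 15, tolerance = 1e-4)
  expect_equal(fast_pdf(0, 20, 2.5), 0)
  expect_equal(fast_pdf(5, 20, 2.5), 6.647773e-4, tolerance = 1e-6)
})

test_that("accumulation curves rise correctly between their limits", {
  t <- c(0, 1, 10, 100, 1e4, 1e6)
  nsd <- nsd_curve(t, 17, 2.5)
  expect_equal(nsd[1], 0)
  expect_true(all(diff(nsd) > 0))
  expect_equal(nsd[length(nsd)], 1, tolerance = 1e-10)
  nfd <- nfd_curve(t, 20, 2.5)
  expect_equal(nfd[1], 0)
  expect_true(all(diff(nfd) >= 0))
  # plateau of the fast curve is ra/r0
  expect_equal(nfd_curve(1e12, 20, 2.5), 5 / 20, tolerance = 1e-4)
  # frozen value at the regime bound
  expect_equal(nfd_curve(27, 20, 2.5), 0.0491764, tolerance = 1e-5)
})

test_that("d/dt of the fast accumulation equals the fast density", {
  t <- c(2, 5, 10, 27)
  h <- 1e-5
  num <- (nfd_curve(t + h, 20, 2.5) - nfd_curve(t - h, 20, 2.5)) / (2 * h)
  expect_equal(num, fast_pdf(t, 20, 2.5), tolerance = 1e-6)
})

test_that("closed-form MFPT matches the stated values and the transform", {
  expect_equal(mfpt(11, 2.5), 220.8727, tolerance = 1e-6)
  expect_equal(mfpt(14, 2.5), 256.4571, tolerance = 1e-6)
  expect_equal(mfpt(17, 2.5), 276.5176, tolerance = 1e-6)
  expect_equal(mfpt(20, 2.5), 287.5)
  # MFPT = -dP/dlambda at 0 (forward difference; the transform is smooth
  # in lambda, so the O(h) bias is ~h * E[T^2] ~ 1e-4 s at h = 1e-9)
  h <- 1e-9
  for (r0 in c(11, 17, 20)) {
    d <- (1 - laplace_flux(h, r0, 2.5)) / h
    expect_equal(d, mfpt(r0, 2.5), tolerance = 1e-5)
  }
})

test_that("slow-rate mean time and exact MFPT are distinct, documented values", {
  expect_equal(1 / slow_rate(17, 2.5), 355.33, tolerance = 1e-4)
  expect_equal(mfpt(17, 2.5), 276.52, tolerance = 1e-4)
  expect_gt(1 / slow_rate(17, 2.5), mfpt(17, 2.5))
})
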