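test_that("histogram mass and censored fraction sum to one", {
  ens <- fpt_ensemble(times = c(1, 3, 7, 42, 100),
                      censored = c(FALSE, FALSE, FALSE, FALSE, TRUE),
                      horizon = 100, r0 = 17)
  h <- fpt_histogram(ens)
  expect_equal(sum(h$density * diff(h$breaks)) + h$censored_fraction, 1)
  expect_equal(h$censored_fraction, 0.2)
})

test_that("a single sample in a 2 s bin has density 1/(n * width)", {
  ens <- fpt_ensemble(times = c(5, 100), censored = c(FALSE, TRUE),
                      horizon = 100, r0 = 17)
  h <- fpt_histogram(ens)
  widths <- diff(h$breaks)
  i <- findInterval(5, h$breaks)
  expect_equal(h$density[i], 1 / (2 * widths[i]))
  expect_equal(sum(h$counts), 1)
})

test_that("histograms of fully censored ensembles are an error", {
  ens <- fpt_ensemble(times = c(10, 10), censored = c(TRUE, TRUE),
                      horizon = 10)
  expect_error(fpt_histogram(ens), "empty histogram")
  expect_error(fpt_histogram(fpt_ensemble(5, FALSE, 10), breaks = c(3, 2)),
               "increasing")
})

test_that("accumulated curves count arrivals over total replicas", {
  ens <- fpt_ensemble(times = c(10, 20, 30, 90),
                      censored = c(FALSE, FALSE, FALSE, TRUE),
                      horizon = 90, r0 = 17)
  cv <- accumulate(ens, time_s = c(0, 10, 15, 25, 35, 90))
  expect_s3_class(cv, "recruitment_curve")
  expect_equal(cv$fraction, c(0, 1, 1, 2, 3, 3) / 4)
  # final fraction + censored fraction = 1
  expect_equal(cv$fraction[nrow(cv)] + mean(ens$censored), 1)
  expect_true(all(diff(cv$fraction) >= 0))
})

test_that("empirical accumulation converges to the exact distribution (DKW)", {
  spec <- synthetic_spec(protein_defaults("NBS1"), true_mean = 17, sd = 0,
                         half_range = 0, seed = 31)
  grid <- seq(0, 1500, by = 10)
  exact <- invert_flux_numeric(grid, 17, 2.5, what = "cdf")
  sup <- vapply(c(300L, 1200L), function(n) {
    ens <- generate_fpt_samples(spec, n, horizon = 1e5)
    max(abs(accumulate(ens, grid)$fraction - exact))
  }, numeric(1))
  # Dvoretzky-Kiefer-Wolfowitz band at alpha = 1e-3
  bound <- sqrt(log(2 / 1e-3) / (2 * c(300, 1200)))
  expect_true(all(sup < bound))
  # and the nested refinement got closer
  expect_lt(sup[2], sup[1])
})

test_that("averaging over a point mass returns the curve itself", {
  grid <- seq(0, 600, by = 20)
  cv <- averaged_curve(grid, 17, 2.5)
  got <- average_over_start(list(`17` = cv),
                            start_distribution(17, sd = 0, lower = 17,
                                               upper = 17))
  expect_equal(got$fraction, cv$fraction)
})

test_that("averaged curves are convex mixtures of their components", {
  grid <- seq(0, 600, by = 20)
  curves <- lapply(c(14, 17, 20), function(r0) averaged_curve(grid, r0, 2.5))
  names(curves) <- c(14, 17, 20)
  dist <- start_distribution(17, sd = 1, lower = 14, upper = 20)
  mix <- average_over_start(curves, dist)
  lo <- pmin(curves[[1]]$fraction, curves[[2]]$fraction, curves[[3]]$fraction)
  hi <- pmax(curves[[1]]$fraction, curves[[2]]$fraction, curves[[3]]$fraction)
  expect_true(all(mix$fraction >= lo - 1e-12 & mix$fraction <= hi + 1e-12))
  # symmetric weights around the mean: 14 and 20 get equal weight
  manual <- (dnorm(0) * curves[[2]]$fraction +
             dnorm(3) * (curves[[1]]$fraction + curves[[3]]$fraction)) /
    (dnorm(0) + 2 * dnorm(3))
  expect_equal(mix$fraction, manual)
})

test_that("curves on different grids refuse to be averaged", {
  a <- averaged_curve(seq(0, 600, 20), 17, 2.5)
  b <- averaged_curve(seq(0, 600, 30), 17, 2.5)
  expect_error(average_over_start(list(a, b)), "alignment error")
})

test_that("recruitment-curve validation enforces the provenance contract", {
  expect_error(recruitment_curve(c(0, 1, 1), c(0, 0.1, 0.2)), "increasing")
  expect_error(recruitment_curve(c(0, 1, 2), c(0, 0.3, 0.2),
                                 kind = "analytic"), "monotone")
  expect_error(recruitment_curve(c(0, 1), c(0, 1.2), kind = "analytic"),
               "\\[0, 1\\]")
  # synthetic curves may be non-monotone and overshoot to 1.05
  cv <- recruitment_curve(c(0, 1, 2), c(0.02, 0.01, 1.04), kind = "synthetic")
  expect_s3_class(cv, "recruitment_curve")
  expect_error(recruitment_curve(c(0, 1), c(0, 1.2), kind = "synthetic"),
               "\\[0, 1.05\\]")
})

test_that("start distributions integrate to one and respect their support", {
  d <- start_distribution(17, 1, 14, 20)
  expect_equal(sum(d$weights), 1)
  expect_true(all(d$nodes >= 14 & d$nodes <= 20))
  expect_error(start_distribution(7, 1, 4, 10), "inside")
  expect_error(start_distribution(23, 1, 20, 26), "inside")
  set.seed(4)
  x <- fptrecruit:::sample_start(d, 500)
  expect_true(all(x >= 14 & x <= 20))
  expect_lt(abs(mean(x) - 17), 0.15)
})
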