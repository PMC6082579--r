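test_that("a noiseless curve returns its own mean exactly (self-consistency)", {
  nbs1 <- protein_defaults("NBS1")
  spec <- synthetic_spec(nbs1, true_mean = 17, noise_sd = 0, seed = 1)
  fit <- fit_start_mean(generate_curve(spec)$curve, nbs1)
  expect_equal(fit$estimate, 17)
  expect_true(fit$diagnostics$converged)
  expect_true(isTRUE(fit$diagnostics$locally_convex))
  # residuals at the optimum are only the family-interpolation error
  expect_lt(sqrt(mean(residuals(fit)^2)), 1e-3)
})

test_that("the fit recovers the mean across the plausible range (noiseless)", {
  nbs1 <- protein_defaults("NBS1")
  grid_t <- seq(0, 600, by = 5)
  fam <- model_family(seq(11, 23, by = 0.25), grid_t, nbs1$D)
  for (truth in c(14.5, 16, 18.5)) {
    spec <- synthetic_spec(nbs1, true_mean = truth, noise_sd = 0, seed = 1)
    fit <- fit_start_mean(generate_curve(spec)$curve, nbs1, fam = fam)
    expect_lt(abs(fit$estimate - truth), 0.5)
  }
})

test_that("fit diagnostics flag a flat (non-identifiable) objective", {
  nbs1 <- protein_defaults("NBS1")
  # deep in the saturated regime every candidate curve is exactly 1, so a
  # constant observation carries no information about the mean
  grid_t <- seq(4e5, 4e5 + 100, by = 5)
  flat <- recruitment_curve(grid_t, rep(1, length(grid_t)), kind = "observed")
  fam <- model_family(seq(11, 23, 0.5), grid_t, nbs1$D, family = "nsd")
  fit <- suppressWarnings(
    fit_start_mean(flat, nbs1, fam = fam, family = "nsd"))
  expect_false(fit$diagnostics$identifiable)
  expect_warning(fit_start_mean(flat, nbs1, fam = fam, family = "nsd"),
                 "non-identifiable")
})

test_that("fit methods expose the estimate, curves and residuals", {
  nbs1 <- protein_defaults("NBS1")
  spec <- synthetic_spec(nbs1, true_mean = 17, seed = 5)
  fit <- fit_start_mean(generate_curve(spec)$curve, nbs1)
  expect_named(coef(fit), "r0_mean_um")
  expect_length(residuals(fit), fit$diagnostics$n_points)
  pr <- predict(fit)
  expect_s3_class(pr, "recruitment_curve")
  expect_equal(pr$time_s, fit$observed$time_s)
  pr2 <- predict(fit, time_s = c(0, 100, 300))
  expect_equal(nrow(pr2), 3)
  expect_output(print(fit), "Starting-radius fit")
  expect_output(print(summary(fit)), "residual RMSE")
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})

test_that("search intervals too close to the boundaries are rejected", {
  nbs1 <- protein_defaults("NBS1")
  spec <- synthetic_spec(nbs1, true_mean = 17, seed = 5)
  cv <- generate_curve(spec)$curve
  expect_error(fit_start_mean(cv, nbs1, search = c(6, 20)),
               "search interval")
  expect_error(fit_start_mean(cv, nbs1, search = c(14, 23)),
               "search interval")
})

test_that("plateau-normalised observations are fitted on the plateau scale", {
  nbs1 <- protein_defaults("NBS1")
  spec <- synthetic_spec(nbs1, true_mean = 17, noise_sd = 0.01,
                         normalization = "plateau", seed = 9)
  fit <- fit_start_mean(generate_curve(spec)$curve, nbs1)
  expect_true(fit$diagnostics$plateau_normalized)
  expect_lt(abs(fit$estimate - 17), 1)
})

test_that("protein comparison is antisymmetric and reports the flag", {
  nbs1 <- protein_defaults("NBS1")
  mre11 <- protein_defaults("MRE11")
  fa <- fit_start_mean(generate_curve(synthetic_spec(nbs1, true_mean = 17,
                                                     seed = 11))$curve, nbs1)
  fb <- fit_start_mean(generate_curve(synthetic_spec(mre11, true_mean = 14,
                                                     seed = 12))$curve, mre11)
  ab <- compare_proteins(fa, fb, n_boot = 100, seed = 3)
  ba <- compare_proteins(fb, fa, n_boot = 100, seed = 3)
  expect_equal(ab$difference, -ba$difference)
  expect_true(ab$faster_has_larger_start)   # D(NBS1) > D(MRE11), 17 > 14
  expect_true(ba$faster_has_larger_start)   # flag is order-invariant
  expect_lt(ab$ci[1], ab$difference + ab$boot_se * 4)
  expect_gt(ab$ci[2], ab$difference - ab$boot_se * 4)
})

test_that("comparison refuses non-converged fits", {
  nbs1 <- protein_defaults("NBS1")
  fa <- fit_start_mean(generate_curve(synthetic_spec(nbs1, true_mean = 17,
                                                     seed = 11))$curve, nbs1)
  fb <- fa
  fb$diagnostics$converged <- FALSE
  expect_error(compare_proteins(fa, fb), "non-converged")
})

test_that("the simulated-ensemble model also recovers the mean", {
  nbs1 <- protein_defaults("NBS1")
  spec <- synthetic_spec(nbs1, true_mean = 17, noise_sd = 0.01,
                         time_s = seq(0, 600, by = 20), seed = 21)
  cv <- generate_curve(spec)$curve
  lat <- lattice_preset("coarse", D = nbs1$D)
  fit <- fit_start_mean(cv, nbs1, model = "simulated", step = 1,
                        n_replicas = 120L, lattice = lat, base_seed = 5000)
  expect_lt(abs(fit$estimate - 17), 2)
  expect_error(fit_start_mean(cv, nbs1, model = "simulated"),
               "base_seed")
})
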