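coarse25 <- lattice_preset("coarse", D = 2.5)

test_that("walkers initialise on the starting sphere", {
  set.seed(99)
  rads <- replicate(2000, walker_radius(init_walker(17, coarse25), coarse25))
  # nearest-site rounding error is at most half a lattice diagonal
  expect_lt(max(abs(rads - 17)), sqrt(3) / 2 * 0.1 + 1e-9)
  expect_lt(abs(mean(rads) - 17), 0.05)
  # z-coordinate of the start is uniform in [-1, 1] * r0: mean near 0
  expect_error(init_walker(4, coarse25), "exceed the nucleus radius")
  expect_error(init_walker(30, coarse25), "exits the box")
})

test_that("each step moves the walker by at most one site along one axis", {
  set.seed(7)
  w <- init_walker(17, coarse25)
  for (i in 1:200) {
    w2 <- walker_step(w, coarse25)
    expect_lte(sum(abs(w2$pos - w$pos)), 1L)
    expect_equal(w2$steps, w$steps + 1L)
    w <- w2
  }
})

test_that("the six move directions are equally likely", {
  lat <- make_lattice(cell_geometry(), 100, c(50, 50, 45), D = 2.5)
  set.seed(123)
  n <- 12000L
  start <- as.integer(round(lat$center))
  path <- fptrecruit:::kmc_path_cpp(start, lat$n_units, lat$unit_um,
                                    lat$center, lat$R, n)
  steps <- diff(rbind(start, path))
  # no rejections this deep inside the membrane
  expect_true(all(rowSums(abs(steps)) == 1))
  counts <- c(sum(steps[, 1] == -1), sum(steps[, 1] == 1),
              sum(steps[, 2] == -1), sum(steps[, 2] == 1),
              sum(steps[, 3] == -1), sum(steps[, 3] == 1))
  expect_equal(sum(counts), n)
  sigma <- sqrt(n * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - n / 6) < 4 * sigma))
})

test_that("box faces reflect: the walker never leaves the box", {
  lat <- make_lattice(cell_geometry(), 500, c(11, 11, 11), D = 2.5,
                      confine = "box")
  set.seed(5)
  start <- c(0L, 0L, 0L)   # a corner site
  path <- fptrecruit:::kmc_path_cpp(start, lat$n_units, lat$unit_um,
                                    lat$center, -1, 5000L)
  expect_true(all(path >= 0L))
  expect_true(all(sweep(path, 2, lat$n_units, "<")))
})

test_that("the spherical membrane reflects: site centres stay within R", {
  lat <- lattice_preset("coarse", D = 2.5)
  set.seed(11)
  # start just inside the membrane
  start <- as.integer(round(lat$center + c(24.9 / lat$unit_um[1], 0, 0)))
  path <- fptrecruit:::kmc_path_cpp(start, lat$n_units, lat$unit_um,
                                    lat$center, lat$R, 20000L)
  d <- sqrt(colSums((t(sweep(path, 2, lat$center)) * lat$unit_um)^2))
  expect_true(all(d <= lat$R + 1e-9))
})

test_that("free-lattice mean squared displacement grows as n u^2", {
  lat <- make_lattice(cell_geometry(), 100, c(50, 50, 45), D = 2.5,
                      confine = "box")
  n_steps <- 500L
  n_paths <- 3000L
  start <- as.integer(round(lat$center))
  set.seed(202)
  sq <- replicate(n_paths, {
    p <- fptrecruit:::kmc_path_cpp(start, lat$n_units, lat$unit_um,
                                   lat$center, -1, n_steps)
    sum((p[n_steps, ] - start)^2)
  })
  se <- sd(sq) / sqrt(n_paths)
  expect_lt(abs(mean(sq) - n_steps), 3 * se)
  # physical MSD = 6 D t with the diffusive clock (exact identity by
  # construction of the step time)
  expect_equal(n_steps * lat$unit_um[1]^2, 6 * lat$D * n_steps * lat$dt)
})

test_that("a walker released inside the nucleus is absorbed immediately", {
  lat <- coarse25
  res <- fptrecruit:::kmc_run_cpp(as.integer(round(lat$center)), lat$n_units,
                                  lat$unit_um, lat$center, lat$ra, lat$R,
                                  1e6, TRUE)
  expect_true(res$absorbed)
  expect_equal(res$steps, 0)
})

test_that("replicas censor at the horizon and report conserved outcomes", {
  r <- run_replica(17, coarse25, horizon = 1, seed = 1)
  expect_true(r$censored)
  expect_equal(r$time, 1)
  ens <- run_ensemble(protein_defaults("NBS1"), coarse25, 40,
                      horizon = 120, base_seed = 300)
  expect_equal(sum(!ens$censored) + sum(ens$censored), ens$n)
  expect_true(all(ens$times[!ens$censored] <= 120))
  expect_true(all(ens$times[ens$censored] == 120))
})

test_that("ensembles are bit-reproducible from the base seed", {
  p <- protein_defaults("NBS1")
  a <- run_ensemble(p, coarse25, 25, horizon = 400, base_seed = 77)
  b <- run_ensemble(p, coarse25, 25, horizon = 400, base_seed = 77)
  expect_identical(a$times, b$times)
  expect_identical(a$censored, b$censored)
  c <- run_ensemble(p, coarse25, 25, horizon = 400, base_seed = 78)
  expect_false(identical(a$times, c$times))
  # sampled-start mode draws radii inside the protein's range
  s <- run_ensemble(p, coarse25, 25, horizon = 400, base_seed = 77,
                    start_mode = "sampled")
  expect_true(all(s$r0 >= 14 & s$r0 <= 20))
  s2 <- run_ensemble(p, coarse25, 25, horizon = 400, base_seed = 77,
                     start_mode = "sampled")
  expect_identical(s$times, s2$times)
  expect_error(run_ensemble(p, coarse25, 25, horizon = 400),
               "base_seed is required")
})
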