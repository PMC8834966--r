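test_that("one deterministic Euler step matches hand arithmetic", {
  p <- make_params(1, 1, rho_plus = matrix(0.2, 1, 1),
                   alpha = matrix(1, 1, 1), beta = matrix(0.1, 1, 1))
  cfg <- sim_config(sigma = 0, eps = 0, t_max = 1, t0 = 0)
  tr <- integrate_trajectory("M", p, x0 = 0.5, c0 = 0.001, config = cfg)
  # F = 0.07 at x = 0.5, so x + F dt = 0.5 + 0.07 * 0.025
  expect_equal(unname(tr$states[2, 1]), 0.50175)
})

test_that("noise-free logistic converges to the closed-form equilibrium", {
  # fixed point of r (1 - x/K) x - delta x = 0 is K (1 - delta / r)
  for (r in c(0.1, 0.3)) {
    p <- single_species_params(r = r)
    cfg <- sim_config(sigma = 0, eps = 0)
    tr <- integrate_trajectory("M", p, x0 = 0.5, c0 = 0, config = cfg)
    expect_equal(unname(tail(tr$states[, 1], 1)), 1 - 0.01 / r,
                 tolerance = 1e-3)
    expect_equal(tr$xhat, 1 - 0.01 / r, tolerance = 1e-3)
  }
})

test_that("trajectories are reproducible from the seed and non-negative", {
  set.seed(20)
  p <- sample_mediator_params()
  x0 <- runif(10, 1e-6, 1e-5)
  cfg <- sim_config(t_max = 2000, t0 = 500, sigma = 2)
  t1 <- withr::with_seed(99, integrate_trajectory("Mprime", p, x0,
                                                  config = cfg))
  t2 <- withr::with_seed(99, integrate_trajectory("Mprime", p, x0,
                                                  config = cfg))
  expect_identical(t1$states, t2$states)
  expect_true(all(t1$states >= 0))
})

test_that("deterministic trajectories are equivariant to species relabeling", {
  set.seed(21)
  p <- sample_mediator_params()
  x0 <- runif(10, 0.01, 0.1)
  cfg <- sim_config(t_max = 500, t0 = 100, sigma = 0)
  perm <- sample(10)
  t1 <- integrate_trajectory("Mprime", p, x0, config = cfg)
  t2 <- integrate_trajectory("Mprime", mednetbench:::permute_params(p, perm),
                             x0[perm], config = cfg)
  expect_equal(t2$states[, 1:10], t1$states[, perm], ignore_attr = TRUE)
  expect_equal(t2$states[, 11:15], t1$states[, 11:15], ignore_attr = TRUE)
})

test_that("total abundance under M' stays bounded by n K after transient", {
  set.seed(22)
  p <- sample_mediator_params()
  # no chemical effects: pure shared logistic with dilution
  p$rho_plus[] <- 0; p$rho_minus[] <- 0
  cfg <- sim_config(t_max = 4000, t0 = 1000, sigma = 0)
  tr <- integrate_trajectory("Mprime", p, x0 = runif(10, 0.05, 0.15),
                             config = cfg)
  totals <- rowSums(tr$states[1001:4001, 1:10])
  expect_true(all(totals <= 10 * p$K + 1e-6))
})

test_that("resample_tail selects the printed source steps", {
  p <- single_species_params()
  cfg <- sim_config(sigma = 0, eps = 0)
  tr <- integrate_trajectory("M", p, x0 = 0.5, c0 = 0, config = cfg)
  s <- resample_tail(tr, tau = 40)
  expect_equal(attr(s, "steps"), seq(6040, 10000, by = 40))
  expect_equal(nrow(s), 100)
  # tau = 80 spans 99 * 80 * 0.025 = 198 days: the 200-day design window
  s80 <- resample_tail(tr, tau = 80)
  expect_equal(diff(range(attr(s80, "steps"))) * cfg$dt, 198)
  # identity case: n_points = full tail at tau = 1
  cfg2 <- sim_config(sigma = 0, eps = 0, t_max = 99, t0 = 0)
  tr2 <- integrate_trajectory("M", p, x0 = 0.5, c0 = 0, config = cfg2)
  s1 <- resample_tail(tr2, tau = 1, n_points = 100)
  expect_equal(unclass(s1)[, 1], tr2$states[, 1], ignore_attr = TRUE)
  expect_error(resample_tail(tr2, tau = 2), "too short")
})

test_that("series TSV round trip preserves values and steps", {
  p <- single_species_params()
  cfg <- sim_config(sigma = 0, eps = 0, t_max = 500, t0 = 100)
  tr <- integrate_trajectory("M", p, 0.5, 0, config = cfg)
  s <- resample_tail(tr, tau = 5, n_points = 50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_series_tsv(s, path)
  s2 <- read_series_tsv(path)
  expect_equal(unclass(s2), unclass(s), ignore_attr = TRUE)
  expect_equal(attr(s2, "steps"), attr(s, "steps"))
})
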