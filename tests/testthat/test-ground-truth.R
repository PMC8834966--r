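test_that("jacobian blocks match hand differentiation of the Hill term", {
  p <- worked_example_params()
  jb <- jacobian_blocks("M", p, x = c(0.5, 0.5), c = 0.001)
  # d/dc of c/(c + kappa) = kappa/(c + kappa)^2 = 0.001/0.002^2 = 250
  expect_equal(jb$JF_c[1, 1], 0.5 * 0.2 * 0.001 / 0.002^2)  # 25
  expect_equal(jb$JF_c[2, 1], 0)
  expect_equal(jb$JG_x[1, 2], 0.1)
  expect_equal(jb$JG_x[1, 1], 0)
})

test_that("zero coupling gives zero cross blocks", {
  p <- make_params(3, 2)
  jb <- jacobian_blocks("M", p, x = runif(3), c = runif(2))
  expect_true(all(jb$JF_c == 0))
  expect_true(all(jb$JG_x == 0))
})

test_that("analytic jacobians agree with finite differences", {
  set.seed(31)
  for (rep in 1:25) {
    model <- sample(c("M", "Mprime"), 1)
    p <- sample_mediator_params(n = 5, m = 3)
    x <- runif(5, 0.1, 1)
    cc <- runif(3, 1e-4, 1e-2)
    Ja <- stacked_jacobian(jacobian_blocks(model, p, x, cc))
    Jf <- mednetbench:::fd_jacobian(model, p, x, cc)
    expect_lt(max(abs(Ja - Jf)) / max(1, max(abs(Ja))), 1e-6)
  }
  # direct models too
  for (rep in 1:10) {
    model <- sample(c("D", "Dprime"), 1)
    p <- sample_mediator_params(n = 5, m = 3)
    dp <- derive_direct_matrix(p)
    x <- runif(5, 0.1, 1)
    Ja <- jacobian_blocks(model, dp, x)$JF_x
    Jf <- mednetbench:::fd_jacobian(model, dp, x)
    expect_lt(max(abs(Ja - Jf)) / max(1, max(abs(Ja))), 1e-6)
  }
})

test_that("effective matrix reproduces the worked block product", {
  p <- worked_example_params()
  em <- effective_interaction_matrix("M", p, c(0.5, 0.5), 0.001)
  expect_equal(em$values[1, 2], 2.5)
  expect_equal(sum(em$values != 0), 1L)
  expect_true(em$presence[1, 2])
  expect_equal(sum(em$presence), 1L)
})

test_that("effective matrix is permutation equivariant and guarded", {
  set.seed(32)
  p <- sample_mediator_params()
  x <- runif(10, 0.1, 1); cc <- runif(5, 1e-4, 1e-2)
  perm <- sample(10)
  a <- effective_interaction_matrix("M", p, x, cc)$values
  b <- effective_interaction_matrix(
    "M", mednetbench:::permute_params(p, perm), x[perm], cc)$values
  expect_equal(b, a[perm, perm])
  expect_error(effective_interaction_matrix("D", p, x, cc), "direct_truth")
})

test_that("structural presence matches the state-evaluated sparsity", {
  set.seed(33)
  for (rep in 1:100) {
    p <- sample_mediator_params(n = 6, m = 3)
    sp <- structural_presence(p)
    em <- effective_interaction_matrix("Mprime", p, runif(6, 0.1, 1),
                                       runif(3, 1e-4, 1e-2))
    offd <- row(sp) != col(sp)
    expect_equal(sp[offd], em$presence[offd])
  }
})

test_that("structural presence enumerates the existential condition", {
  # single mediator produced only by species 2, sensed only by species 1
  p <- make_params(3, 1, rho_plus = matrix(c(0.2, 0, 0), 3, 1),
                   beta = matrix(c(0, 0.1, 0), 1, 3))
  sp <- structural_presence(p)
  expect_true(sp[1, 2])
  expect_equal(sum(sp), 1L)
  # dense coupling: everything off-diagonal present
  pd <- make_params(3, 2, rho_plus = matrix(0.3, 3, 2),
                    beta = matrix(0.1, 2, 3))
  spd <- structural_presence(pd)
  expect_true(all(spd[row(spd) != col(spd)]))
  expect_false(any(diag(spd)))
})

test_that("direct truth uses the off-diagonal nonzero pattern of A", {
  p <- make_params(2, 1,
                   rho_plus = matrix(c(0.2, 0), 2, 1),
                   rho_minus = matrix(c(0, 0.1), 2, 1),
                   beta = matrix(c(0.1, 0.05), 1, 2))
  dt <- direct_truth(derive_direct_matrix(p))
  expect_true(dt$presence[1, 2] && dt$presence[2, 1])
  expect_false(any(diag(dt$presence)))
  # diagonal-only A has no interactions
  dp <- structure(list(A = diag(c(-1, -2)), r = c(0.1, 0.1), K = 1,
                       delta = 0.01, n = 2), class = "direct_params")
  expect_equal(sum(direct_truth(dp)$presence), 0L)
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(dt, path)
  dt2 <- read_truth_json(path)
  expect_equal(dt2$values, dt$values)
  expect_equal(dt2$presence, dt$presence)
})
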