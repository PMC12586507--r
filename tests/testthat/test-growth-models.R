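test_that("treatment hazard follows the step/decay formula with H(0) = 1", {
  p <- tumor_params(r = 0.1, K = 1000, N0 = 100, alpha = 0.1, n_doses = 2)
  expect_equal(treatment_hazard(-1, p), 0)
  expect_equal(treatment_hazard(8, p), 0.2)
  # dose active from its start time inclusive
  expect_equal(treatment_hazard(0, p), 0.1)
  expect_equal(treatment_hazard(7, p), 0.2)

  p2 <- tumor_params(r = 0.1, K = 1000, N0 = 100, alpha = 0.2, beta = 0.1)
  expect_equal(treatment_hazard(7, p2, treatment_course(taus = 0)),
               0.2 * exp(-0.7), tolerance = 1e-12)
  # vectorized over t
  expect_equal(treatment_hazard(c(-1, 0, 8), p), c(0, 0.1, 0.2))
  # mismatched alpha length is a structural error
  p3 <- tumor_params(r = 0.1, K = 1000, N0 = 100, alpha = c(0.1, 0.2, 0.3))
  expect_error(treatment_hazard(1, p3), "n_doses")
})

test_that("model constraints are enforced per the nested taxonomy", {
  expect_error(check_params <- simulate_tumor(
    model_spec("logistic"),
    tumor_params(r = 0.1, K = 1000, N0 = 100, alpha = 0.1, n_doses = 2)),
    "alpha")
  expect_error(simulate_tumor(
    model_spec("linear"),
    tumor_params(r = 0.1, K = 1000, N0 = 100, alpha = c(0.1, 0.2))),
    "shared alpha")
  expect_error(simulate_tumor(
    model_spec("cumulative"),
    tumor_params(r = 0.1, K = 1000, N0 = 100, alpha = c(0.1, 0.2),
                 beta = 0.5)),
    "beta")
  expect_error(tumor_params(r = -1, K = 1000, N0 = 100))
  expect_error(tumor_params(r = 0.1, K = 1000, N0 = 100, sigma = 0))
  expect_error(treatment_course(taus = c(7, 0)), "increasing")
})

test_that("RK4 reproduces the closed-form logistic solution", {
  # fixed point N0 = K
  s <- simulate_tumor(model_spec("logistic"),
                      tumor_params(r = 0.3, K = 100, N0 = 100),
                      times = c(0, 7, 14))
  expect_equal(s$volume, rep(100, 3), tolerance = 1e-10)

  s2 <- simulate_tumor(model_spec("logistic"),
                       tumor_params(r = 0.1, K = 1000, N0 = 100),
                       times = c(0, 14))
  expect_equal(s2$volume[2], logistic_closed(14, 0.1, 1000, 100),
               tolerance = 1e-8)

  # near-exponential regime with one dose: decaying exponential oracle
  s3 <- simulate_tumor(model_spec("linear"),
                       tumor_params(r = 0.1, K = 1e9, N0 = 100, alpha = 0.2,
                                    n_doses = 1),
                       treatment_course(taus = 0), times = c(0, 7))
  expect_equal(s3$volume[2], 100 * exp(-0.7), tolerance = 1e-6)
})

test_that("nested models agree where their constraints coincide", {
  course <- treatment_course()
  times <- c(0, 3.5, 7, 10, 14)
  lin <- simulate_tumor(model_spec("linear"),
                        tumor_params(r = 0.15, K = 1500, N0 = 120,
                                     alpha = 0.2, n_doses = 2),
                        course, times)
  expd <- simulate_tumor(model_spec("expdecay"),
                         tumor_params(r = 0.15, K = 1500, N0 = 120,
                                      alpha = 0.2, beta = 0, n_doses = 2),
                         course, times)
  expect_identical(lin$volume, expd$volume)

  cum <- simulate_tumor(model_spec("cumulative"),
                        tumor_params(r = 0.15, K = 1500, N0 = 120,
                                     alpha = c(0.2, 0.2)),
                        course, times)
  expect_equal(lin$volume, cum$volume, tolerance = 1e-12)
})

test_that("day-14 volume is non-increasing in each dose's death rate", {
  course <- treatment_course()
  day14 <- function(a1, a2) {
    simulate_tumor(model_spec("cumulative"),
                   tumor_params(r = 0.2, K = 1500, N0 = 120,
                                alpha = c(a1, a2)),
                   course, times = c(0, 14), dt = 0.05)$volume[2]
  }
  grid <- seq(0, 0.3, by = 0.075)
  for (a2 in c(0, 0.15)) {
    v <- vapply(grid, day14, 0, a2 = a2)
    expect_true(all(diff(v) <= 1e-9))
  }
  v2 <- vapply(grid, function(a2) day14(0.1, a2), 0)
  expect_true(all(diff(v2) <= 1e-9))
})

test_that("trajectories stay within [0, max(N0, K)]", {
  course <- treatment_course()
  set.seed(42)
  for (i in 1:20) {
    p <- tumor_params(r = runif(1, 0.03, 0.5), K = runif(1, 200, 3000),
                      N0 = runif(1, 1, 600),
                      alpha = runif(2, 0, 0.3))
    s <- simulate_tumor(model_spec("cumulative"), p, course,
                        times = 0:14, dt = 0.05)
    expect_true(all(s$volume >= 0))
    expect_true(all(s$volume <= max(p$N0, p$K) + 1e-8))
  }
})

test_that("simulation is deterministic and rejects bad time grids", {
  p <- tumor_params(r = 0.1, K = 1000, N0 = 100)
  a <- simulate_tumor(model_spec("logistic"), p, times = c(0, 7, 14))
  b <- simulate_tumor(model_spec("logistic"), p, times = c(0, 7, 14))
  expect_identical(a, b)
  expect_error(simulate_tumor(model_spec("logistic"), p, times = c(-1, 7)),
               "day 0")
  expect_error(simulate_tumor(model_spec("logistic"), p, times = c(7, 7)))
})
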