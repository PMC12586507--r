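test_that("Gaussian log-likelihood matches direct arithmetic", {
  expect_equal(log_likelihood(c(1, 2, 3), c(1, 2, 3), 1),
               -1.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(log_likelihood(c(1, 2), c(0, 0), 2),
               -(log(2 * pi) + log(4) + 0.625), tolerance = 1e-12)
  # strictly decreases as any residual grows
  base <- log_likelihood(c(10, 20), c(9, 18), 2)
  expect_lt(log_likelihood(c(10, 20), c(8, 18), 2), base)
  expect_error(log_likelihood(1, 1, 0), "sigma")
  expect_error(log_likelihood(1, 1, -2), "sigma")
})

test_that("ensemble sampler recovers a known bivariate Gaussian", {
  lp <- function(theta, unit) {
    -0.5 * ((theta[, 1] - 1)^2 / 0.25 + (theta[, 2] + 2)^2 / 4)
  }
  set.seed(11)
  sam <- tumordyn:::run_sampler(lp, lower = c(-10, -10), upper = c(10, 10),
                                n_units = 1,
                                mcmc = mcmc_control(n_samples = 4000,
                                                    seed = 11,
                                                    act_check = FALSE))
  d <- sam$draws[[1]]
  expect_equal(mean(d[, 1]), 1, tolerance = 0.1)
  expect_equal(mean(d[, 2]), -2, tolerance = 0.2)
  expect_equal(stats::sd(d[, 1]), 0.5, tolerance = 0.1)
  expect_equal(stats::sd(d[, 2]), 2, tolerance = 0.3)
})

test_that("fits honor the prior box, the 2n chain rule, and reproducibility", {
  g <- make_arm(n = 2, frac = 1, seed = 3)
  f <- tumor_fit(g$cohort, "linear", K = 1400, mcmc = fast_mcmc(n_samples = 200))
  pri <- tumor_priors()
  for (d in f$draws) {
    expect_true(all(d[, "r"] >= pri$r[1] & d[, "r"] <= pri$r[2]))
    expect_true(all(d[, "alpha"] >= 0 & d[, "alpha"] <= 0.3))
    expect_true(all(d[, "N0"] >= 0 & d[, "N0"] <= 600))
    expect_true(all(d[, "sigma"] >= 1 & d[, "sigma"] <= 200))
  }
  # 2n walkers for n = 4 mouse-level parameters
  expect_equal(f$sampler$n_walkers, 8)
  expect_gte(f$sampler$retained_per_chain, 200)
  expect_equal(f$Z, 2 * 4)
  expect_equal(f$n_obs, 6)
  f2 <- tumor_fit(g$cohort, "linear", K = 1400,
                  mcmc = fast_mcmc(n_samples = 200))
  expect_identical(f$draws, f2$draws)
})

test_that("noiseless data are matched by the maximum-likelihood estimate", {
  g <- make_arm(n = 2, frac = 1, noise_frac = NULL, noise_sd = 0, seed = 71)
  f <- tumor_fit(g$cohort, "linear", K = 1400,
                 mcmc = fast_mcmc(n_samples = 400, seed = 3, refine = TRUE))
  for (u in seq_along(f$mouse_ids)) {
    th <- f$theta_hat[u, ]
    s <- simulate_tumor(model_spec("linear"),
                        tumor_params(r = th[["r"]], K = 1400,
                                     N0 = th[["N0"]], alpha = th[["alpha"]],
                                     n_doses = 2),
                        times = c(0, 7, 14), dt = 0.25)
    D <- g$cohort$volume_mm3[g$cohort$mouse_id == f$mouse_ids[u]]
    expect_lt(max(abs(s$volume - D)), 1e-3)
  }
})

test_that("control fit estimates a shared K and treated fits a shared beta", {
  cfg <- cohort_config(group_sizes = c(control = 3),
                       responder_fraction = c(control = 0),
                       resistivity_truth = c(control = 1), seed = 21)
  g <- generate_cohort(cfg)
  f <- tumor_fit(g$cohort, "logistic", mcmc = fast_mcmc(n_samples = 300))
  expect_named(f$shared, "K")
  expect_true(all(f$shared$K >= 1 & f$shared$K <= 3000))
  expect_true(all(f$draws[[1]][, "r"] >= 0 & f$draws[[1]][, "r"] <= 0.5))
  expect_equal(f$Z, 1 + 3 * 3)
  expect_gt(control_K(f), 1)
  # truth coverage of the mouse-level parameters (weakly informative data,
  # wide posteriors): most central intervals contain the truth
  sm <- f$summaries
  hit <- 0; tot <- 0
  for (p in c("r", "N0")) {
    s <- sm[sm$parameter == p, ]
    truth <- g$truth[[if (p == "r") "r" else "N0"]][
      match(s$mouse_id, g$truth$mouse_id)]
    hit <- hit + sum(truth >= s$lo95 & truth <= s$hi95)
    tot <- tot + nrow(s)
  }
  expect_gte(hit / tot, 0.75)

  pri2 <- r_prior_from_control(tumor_priors(), f)
  expect_true(pri2$r[1] >= 0 && pri2$r[2] <= 0.5 && pri2$r[1] < pri2$r[2])

  g2 <- make_arm(n = 2, frac = 1, seed = 31)
  f2 <- tumor_fit(g2$cohort, "expdecay", K = 1400,
                  mcmc = fast_mcmc(n_samples = 200))
  expect_named(f2$shared, "beta")
  expect_true(all(f2$shared$beta >= 0 & f2$shared$beta <= 2))
  expect_equal(f2$Z, 1 + 2 * 4)
})

test_that("fit input errors are caught", {
  g <- make_arm(n = 2, seed = 3)
  expect_error(tumor_fit(g$cohort, "linear", mcmc = fast_mcmc()),
               "carrying capacity")
  expect_error(tumor_fit(g$cohort[0, ], "linear", K = 1400,
                         mcmc = fast_mcmc()))
  one_pt <- g$cohort[g$cohort$day == 0, ]
  expect_error(tumor_fit(one_pt, "linear", K = 1400, mcmc = fast_mcmc()),
               "fewer than 2")
})

test_that("fit methods are coherent", {
  g <- make_arm(n = 2, frac = 1, seed = 13)
  f <- tumor_fit(g$cohort, "linear", K = 1400, mcmc = fast_mcmc(n_samples = 250))
  cm <- coef(f)
  expect_equal(dim(cm), c(2, 4))
  expect_equal(rownames(cm), f$mouse_ids)
  ll <- logLik(f)
  expect_equal(stats::BIC(ll), bic(f$lnL_hat, f$Z, f$n_obs), tolerance = 1e-12)
  p <- predict(f, times = c(0, 7, 14), ndraws = 100)
  expect_equal(nrow(p), 6)
  expect_true(all(p$lo <= p$median & p$median <= p$hi))
  r <- residuals(f, ndraws = 100)
  expect_length(r, 6)
  sim <- simulate(f, nsim = 1, seed = 4)
  expect_equal(nrow(sim), 6)
  expect_true(all(sim$volume_mm3 > 0))
  expect_output(print(f), "linear")
  expect_output(print(summary(f)), "BIC")
})
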