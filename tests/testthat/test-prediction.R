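test_that("responder classification is strict", {
  expect_equal(classify_responder(100, 80), "responder")
  expect_equal(classify_responder(100, 100), "non-responder")
  expect_equal(classify_responder(100, 332), "non-responder")
  expect_equal(classify_responder(100, c(80, 120)),
               c("responder", "non-responder"))
})

test_that("group resistivity is the pooled per-draw ratio", {
  d <- matrix(c(2, 2, 1, 1), 2, 2, dimnames = list(NULL, c("alpha1", "alpha2")))
  fit <- fake_cumulative_fit(list(m1 = d, m2 = d))
  rs <- group_resistivity(fit)
  expect_equal(rs$median, 2)
  expect_equal(rs$mean, 2)
  d2 <- d; d2[, "alpha2"] <- d2[, "alpha1"]
  expect_equal(group_resistivity(fake_cumulative_fit(list(m = d2)))$median, 1)
  d3 <- d; d3[, "alpha2"] <- 0
  expect_error(group_resistivity(fake_cumulative_fit(list(m = d3))),
               "undefined")
  # floor guards the ratio, and mouse subsetting excludes held-out blocks
  rs2 <- group_resistivity(fit, mice = "m1")
  expect_equal(rs2$n_mice, 1)
})

test_that("mouse-specific predictions never see day 14", {
  g <- make_arm(n = 2, frac = 1, seed = 41)
  mc <- fast_mcmc(n_samples = 200)
  p <- predict_mouse_specific(g$cohort, g$truth$mouse_id[1], K = 1400,
                              mcmc = mc, n_draws = 100)
  expect_true(all(p$days_used %in% c(0, 7)))
  expect_s3_class(p, "tumor_prediction")
  expect_equal(unname(p$point["14"]), unname(stats::median(p$draws[, "14"])))
  expect_true(all(p$draws >= 0))
  pg <- predict_group_informed(g$cohort, g$truth$mouse_id[1], resistivity = 2,
                               K = 1400, mcmc = mc, n_draws = 100)
  expect_true(all(pg$days_used %in% c(0, 7)))
})

test_that("group-informed with R = 1 equals the mouse-specific scheme", {
  g <- make_arm(n = 2, frac = 1, seed = 43)
  id <- g$truth$mouse_id[1]
  mc <- fast_mcmc(n_samples = 300, seed = 17)
  pm <- predict_mouse_specific(g$cohort, id, K = 1400, mcmc = mc,
                               n_draws = 200)
  pg <- predict_group_informed(g$cohort, id, resistivity = 1, K = 1400,
                               mcmc = mc, n_draws = 200)
  expect_equal(unname(pm$draws), unname(pg$draws), tolerance = 1e-12)
  expect_equal(pm$responder_call, pg$responder_call)
})

test_that("an effectively infinite ratio removes the second dose", {
  g <- make_arm(n = 2, frac = 1, seed = 44)
  id <- g$truth$mouse_id[1]
  mc <- fast_mcmc(n_samples = 300, seed = 18)
  p1 <- predict_group_informed(g$cohort, id, resistivity = 1, K = 1400,
                               mcmc = mc, n_draws = 200)
  pinf <- predict_group_informed(g$cohort, id, resistivity = 1e9, K = 1400,
                                 mcmc = mc, n_draws = 200)
  # without the second dose the day-7 to day-14 segment regrows
  expect_gt(unname(pinf$point["14"]), unname(p1$point["14"]))
  expect_error(predict_group_informed(g$cohort, id, resistivity = 0,
                                      K = 1400, mcmc = mc), "R must be")
})

test_that("self-consistency on the generating model with an informative r prior", {
  # noiseless mouse from the constant-effect model; tight r prior makes the
  # r-alpha ridge short, so the day-14 point prediction lands near truth
  tr <- list(r = 0.1, K = 1400, N0 = 100, alpha = 0.2)
  s <- simulate_tumor(model_spec("linear"),
                      tumor_params(r = tr$r, K = tr$K, N0 = tr$N0,
                                   alpha = tr$alpha, n_doses = 2),
                      times = c(0, 7, 14))
  co <- one_mouse(s$volume)
  pri <- tumor_priors(r = c(0.08, 0.12))
  p <- predict_mouse_specific(co, "m1", priors = pri, K = 1400,
                              mcmc = mcmc_control(n_samples = 2000, seed = 5,
                                                  max_extend = 2),
                              n_draws = 1000)
  expect_lt(abs(p$point[["14"]] - s$volume[3]) / s$volume[3], 0.05)
  expect_equal(p$responder_call, "responder")
})

test_that("dose-2 attenuation makes the constant-effect prediction under-kill", {
  # truth has alpha2 = alpha1 / 3; assuming alpha2 = alpha1 predicts more
  # kill in week two, so the predicted day-14 volume falls below the truth
  p0 <- tumor_params(r = 0.1, K = 1400, N0 = 100, alpha = c(0.24, 0.08))
  s <- simulate_tumor(model_spec("cumulative"), p0, times = c(0, 7, 14))
  co <- one_mouse(s$volume)
  pri <- tumor_priors(r = c(0.08, 0.12))
  p <- predict_mouse_specific(co, "m1", priors = pri, K = 1400,
                              mcmc = mcmc_control(n_samples = 1500, seed = 6,
                                                  max_extend = 2),
                              n_draws = 1000)
  expect_lt(unname(p$point["14"]), s$volume[3])
})

test_that("leave-one-out predictions pool the other mice's posteriors", {
  g <- make_arm(n = 4, frac = 1, seed = 45)
  mc <- fast_mcmc(n_samples = 300, seed = 19)
  id <- g$truth$mouse_id[1]
  set.seed(1)
  p <- predict_leave_one_out(g$cohort, id, K = 1400, mcmc = mc,
                             n_draws = 500)
  expect_setdiff <- setdiff(p$donors, id)
  expect_equal(length(p$donors), 3)
  expect_false(id %in% p$donors)
  # draws start from the held-out mouse's observed day-0 volume
  d0 <- g$cohort$volume_mm3[g$cohort$mouse_id == id & g$cohort$day == 0]
  expect_true(all(abs(p$observed[["0"]] - d0) < 1e-12))
  # degenerate single-draw prediction is deterministic under a seed
  set.seed(2)
  p1 <- predict_leave_one_out(g$cohort, id, K = 1400, mcmc = mc, n_draws = 1)
  set.seed(2)
  p2 <- predict_leave_one_out(g$cohort, id, K = 1400, mcmc = mc, n_draws = 1)
  expect_identical(p1$draws, p2$draws)
  one <- g$cohort[g$cohort$mouse_id == id, ]
  expect_error(predict_leave_one_out(one, id, K = 1400, mcmc = mc),
               "single-mouse")
})

test_that("predict_arm equals the per-mouse calls", {
  g <- make_arm(n = 3, frac = 1, seed = 47)
  mc <- fast_mcmc(n_samples = 200, seed = 23)
  arm <- predict_arm(g$cohort, "mouse", K = 1400, mcmc = mc, n_draws = 50)
  expect_length(arm, 3)
  expect_named(arm, g$truth$mouse_id)
  expect_true(all(vapply(arm, function(p)
    all(p$days_used %in% c(0, 7)), TRUE)))
})
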