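test_that("agreement metrics match their closed forms", {
  m <- fit_quality(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$ccc, 1)
  expect_equal(m$pcc, 1)
  expect_equal(m$mape, 0)

  m2 <- fit_quality(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m2$pcc, 1, tolerance = 1e-12)
  expect_equal(m2$ccc, 4 / 7, tolerance = 1e-12)

  m3 <- fit_quality(c(100, 200), c(90, 220))
  expect_equal(m3$mape, 10, tolerance = 1e-12)

  expect_warning(mz <- fit_quality(c(1, 1, 1), c(1, 2, 3)), "PCC undefined")
  expect_true(is.na(mz$pcc))
})

test_that("CCC is permutation-invariant and attenuates PCC", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(20, 100, 30); y <- x * runif(1, 0.5, 1.5) + rnorm(20, 5, 10)
    m <- fit_quality(x, y)
    perm <- sample(20)
    mp <- fit_quality(x[perm], y[perm])
    expect_equal(m$ccc, mp$ccc, tolerance = 1e-12)
    if (!is.na(m$pcc) && m$pcc > 0) expect_lte(m$ccc, m$pcc + 1e-12)
  }
})

test_that("responder accuracy reproduces the arithmetic cases", {
  expect_equal(responder_accuracy(rep(TRUE, 5), rep(TRUE, 5))$accuracy, 100)
  truth <- c(rep("responder", 6), rep("non-responder", 12))
  pred17 <- truth; pred17[1] <- "non-responder"
  expect_equal(responder_accuracy(truth, pred17)$accuracy, 100 * 17 / 18,
               tolerance = 1e-12)
  pred15 <- truth
  pred15[1] <- "non-responder"; pred15[7] <- "responder"; pred15[8] <- "responder"
  expect_equal(responder_accuracy(truth, pred15)$accuracy, 100 * 15 / 18,
               tolerance = 1e-12)
  cf <- responder_accuracy(truth, pred17)$confusion
  expect_equal(sum(cf), 18)
  expect_equal(unname(cf["responder", "non-responder"]), 1)
})

test_that("Mann-Whitney comparisons are two-tailed with Bonferroni control", {
  same <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4), m_comparisons = 3)
  expect_equal(same$p_adjusted, 1)
  # completely separated samples, n = m = 5: exact two-tailed p = 2/252
  sep <- compare_groups(1:5, 11:15, m_comparisons = 1)
  expect_equal(sep$p, 2 / choose(10, 5), tolerance = 1e-12)
  # Bonferroni arithmetic: never decreases, capped at 1
  cg <- compare_groups(1:5, 11:15, m_comparisons = 5)
  expect_equal(cg$p_adjusted, min(1, 5 * cg$p), tolerance = 1e-12)
  expect_gte(cg$p_adjusted, cg$p)
  cg2 <- compare_groups(1:5, 11:15, m_comparisons = 1e6)
  expect_equal(cg2$p_adjusted, 1)
})

test_that("paired growth test matches the closed-form t statistic", {
  # differences (1, 2, 3): t = mean / (sd / sqrt(3)) = 2 sqrt(3)
  out <- paired_growth_test(c(10, 20, 30), c(11, 22, 33))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(out$df, 2)
  expect_equal(out$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)
  # symmetric differences summing to zero
  out0 <- paired_growth_test(c(1, 2), c(2, 1))
  expect_equal(out0$t, 0, tolerance = 1e-12)
  expect_equal(out0$p, 1, tolerance = 1e-12)
  expect_error(paired_growth_test(c(1, 2, 3), c(2, 3, 4)), "degenerate")
})

test_that("ICC and CV summarize inter-mouse variability", {
  flat <- list(m1 = cbind(r = rep(0.1, 10)), m2 = cbind(r = rep(0.1, 10)))
  expect_warning(out <- icc_cv(flat), "constant")
  expect_equal(out$icc, 0)
  expect_equal(out$cv, 0)

  set.seed(2)
  wide <- list(m1 = cbind(r = rnorm(200, 1, 0.001)),
               m2 = cbind(r = rnorm(200, 5, 0.001)))
  out2 <- icc_cv(wide)
  expect_gt(out2$icc, 0.99)

  meds <- list(m1 = cbind(r = rep(1, 5)), m2 = cbind(r = rep(3, 5)))
  out3 <- icc_cv(meds)
  expect_equal(out3$icc, 1)
  # sample-sd convention on the per-mouse medians: sd(c(1,3))/2
  expect_equal(out3$cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_error(icc_cv(list(m1 = cbind(r = 1:5))))
})

test_that("prediction metrics pool the day-14 comparisons", {
  mk <- function(id, pred, obs0, obs14) {
    structure(list(mouse_id = id, scheme = "mouse-specific",
                   times = c(7, 14),
                   draws = matrix(pred, 5, 2,
                                  dimnames = list(NULL, c("7", "14"))),
                   point = c("7" = pred, "14" = pred),
                   responder_call = classify_responder(obs0, pred),
                   observed = c("0" = obs0, "7" = NA, "14" = obs14),
                   days_used = c(0, 7)),
              class = "tumor_prediction")
  }
  preds <- list(mk("a", 90, 100, 95), mk("b", 250, 120, 240),
                mk("c", 150, 110, 160))
  out <- prediction_metrics(preds)
  expect_equal(out$table$predicted, c(90, 250, 150))
  expect_equal(out$accuracy, 100)
  expect_gt(out$metrics$ccc, 0.9)
})
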