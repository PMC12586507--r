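#' Responder classification
#'
#' A responder is a mouse whose tumor volume at the end of the experimental
#' regime is strictly lower than its volume at the start of treatment; ties
#' are non-responders.
#'
#' @param v_start starting volume(s), mm^3 (>= 0).
#' @param v_end final volume(s), mm^3 (>= 0); vectorized.
#' @return character vector, `"responder"` or `"non-responder"`.
#' @export
classify_responder <- function(v_start, v_end) {
  stopifnot(all(v_start >= 0), all(v_end >= 0))
  ifelse(v_end < v_start, "responder", "non-responder")
}

new_prediction <- function(mouse_id, scheme, times, draws, observed,
                           days_used, extra = list()) {
  point <- apply(draws, 2, stats::median)
  call <- classify_responder(observed[["0"]], point[length(point)])
  structure(c(list(
    mouse_id = mouse_id, scheme = scheme, times = times, draws = draws,
    point = point, responder_call = unname(call), observed = observed,
    days_used = days_used), extra),
    class = "tumor_prediction")
}

#' @export
print.tumor_prediction <- function(x, ...) {
  cat(sprintf("Prediction (%s) for %s\n", x$scheme, x$mouse_id))
  for (i in seq_along(x$times))
    cat(sprintf("  day %2g: median %.1f mm^3 (95%% PI %.1f - %.1f)%s\n",
                x$times[i], x$point[i],
                stats::quantile(x$draws[, i], 0.025),
                stats::quantile(x$draws[, i], 0.975),
                if (!is.na(x$observed[as.character(x$times[i])]))
                  sprintf("   observed %.1f",
                          x$observed[as.character(x$times[i])]) else ""))
  cat(sprintf("  call: %s\n", x$responder_call))
  invisible(x)
}

mouse_observed <- function(cohort, mouse_id, days = c(0, 7, 14)) {
  rows <- cohort[cohort$mouse_id == mouse_id, ]
  if (!nrow(rows)) stop(sprintf("mouse %s not found in cohort", mouse_id))
  v <- rows$volume_mm3[match(days, rows$day)]
  stats::setNames(v, as.character(days))
}

#' Mouse-specific prediction of the final tumor volume
#'
#' Fits the constant-effect treatment model (mouse-specific `r`, `alpha`,
#' `N0`, `sigma`; `K` fixed) to the mouse's day-0 and day-7 measurements
#' only, then propagates each posterior draw forward to day 14. The point
#' prediction is the posterior median; the responder call compares it with
#' the observed day-0 volume.
#'
#' @param cohort cohort data frame containing the mouse.
#' @param mouse_id mouse to predict.
#' @param priors,K,course,mcmc passed to [tumor_fit()].
#' @param n_draws posterior draws propagated forward.
#' @param t_fit days used for fitting (must include day 7).
#' @param t_pred days predicted.
#' @param day7_fit optional precomputed constant-effect `"tumor_fit"` of the
#'   arm restricted to the fitting window (see [predict_arm()]); because the
#'   treated-model posterior factorizes over mice, its block for this mouse
#'   equals a single-mouse fit.
#' @return a `"tumor_prediction"` object.
#' @export
predict_mouse_specific <- function(cohort, mouse_id, priors = tumor_priors(),
                                   K, course = treatment_course(),
                                   mcmc = mcmc_control(), n_draws = 1000,
                                   t_fit = c(0, 7), t_pred = c(7, 14),
                                   day7_fit = NULL) {
  obs <- mouse_observed(cohort, mouse_id)
  if (any(is.na(obs[as.character(t_fit)])))
    stop(sprintf("mouse %s lacks a measurement in the fitting window",
                 mouse_id))
  if (is.null(day7_fit)) {
    sub <- cohort[cohort$mouse_id == mouse_id & cohort$day %in% t_fit, ]
    fit <- tumor_fit(sub, "linear", priors = priors, K = K, course = course,
                     mcmc = mcmc)
  } else {
    fit <- check_day7_fit(day7_fit, mouse_id, t_fit)
  }
  times <- sort(unique(c(0, t_pred)))
  sim <- fit_draw_paths(fit, times, ndraws = n_draws, mice = mouse_id,
                        dt = 0.01)
  draws <- sim$paths[[mouse_id]][, match(t_pred, times), drop = FALSE]
  colnames(draws) <- as.character(t_pred)
  new_prediction(mouse_id, "mouse-specific", t_pred, draws, obs,
                 fit$days_used, extra = list(fit = fit))
}

check_day7_fit <- function(fit, mouse_id, t_fit) {
  stopifnot(inherits(fit, "tumor_fit"), fit$model == "linear")
  if (!all(fit$days_used %in% t_fit))
    stop("day7_fit was fitted on days outside the prediction fitting window")
  if (!mouse_id %in% fit$mouse_ids)
    stop(sprintf("mouse %s not present in day7_fit", mouse_id))
  fit
}

#' Leave-one-out prediction from group information
#'
#' Fits the constant-effect model to every other mouse in the arm (the
#' held-out mouse's data are excluded entirely), then draws `n_draws`
#' parameter sets uniformly from the pooled posterior (chain, iteration and
#' mouse block sampled uniformly), initializes `N0` at the held-out mouse's
#' observed day-0 volume, and simulates the tumor volumes at days 7 and 14.
#'
#' @param cohort cohort data frame for one treatment arm (>= 2 mice).
#' @param mouse_id held-out mouse.
#' @param priors,K,course,mcmc passed to [tumor_fit()].
#' @param n_draws posterior draws (default 1000).
#' @param arm_fit optional precomputed `"tumor_fit"` of the constant-effect
#'   model to this arm; its draws for the held-out mouse are discarded. When
#'   the arm posterior factorizes over mice this equals refitting without the
#'   held-out mouse.
#' @return a `"tumor_prediction"` object.
#' @export
predict_leave_one_out <- function(cohort, mouse_id, priors = tumor_priors(),
                                  K, course = treatment_course(),
                                  mcmc = mcmc_control(), n_draws = 1000,
                                  arm_fit = NULL) {
  obs <- mouse_observed(cohort, mouse_id)
  others <- setdiff(unique(cohort$mouse_id), mouse_id)
  if (!length(others)) stop("cannot leave one out of a single-mouse arm")
  if (is.null(arm_fit)) {
    sub <- cohort[cohort$mouse_id != mouse_id, ]
    arm_fit <- tumor_fit(sub, "linear", priors = priors, K = K,
                         course = course, mcmc = mcmc)
  } else {
    stopifnot(inherits(arm_fit, "tumor_fit"), arm_fit$model == "linear")
  }
  donors <- intersect(arm_fit$mouse_ids, others)
  pick_m <- sample(donors, n_draws, replace = TRUE)
  r <- al <- numeric(n_draws)
  for (d in donors) {
    w <- which(pick_m == d)
    if (!length(w)) next
    i <- sample.int(nrow(arm_fit$draws[[d]]), length(w), replace = TRUE)
    r[w] <- arm_fit$draws[[d]][i, "r"]
    al[w] <- arm_fit$draws[[d]][i, "alpha"]
  }
  t_pred <- c(7, 14)
  v <- rk4_paths(c(0, t_pred), r, rep(K, n_draws),
                 rep(obs[["0"]], n_draws), cbind(al, al),
                 rep(0, n_draws), course$taus, dt = 0.01)
  draws <- v[, 2:3, drop = FALSE]
  colnames(draws) <- as.character(t_pred)
  new_prediction(mouse_id, "leave-one-out", t_pred, draws, obs,
                 arm_fit$days_used, extra = list(donors = donors))
}

#' Treatment resistivity of a group
#'
#' The resistivity `alpha1/alpha2` is the ratio of the first-dose to the
#' second-dose death rate: a ratio of 2 means the first dose is twice as
#' effective as the second. Ratios are computed per posterior draw and per
#' mouse from a cumulative two-dose fit, pooled across the group, and
#' summarized by the median (default) and mean. `alpha2` draws are floored
#' at `floor` (per day) before division to avoid ratio blow-ups.
#'
#' @param fit a `"tumor_fit"` of the cumulative two-dose model.
#' @param mice optional subset of mice to pool (e.g. excluding a held-out
#'   mouse).
#' @param floor lower bound applied to `alpha2` draws.
#' @return an object of class `"resistivity_stat"`: list with `ratios`,
#'   `median`, `mean`, `n_mice`.
#' @export
group_resistivity <- function(fit, mice = NULL, floor = 1e-4) {
  stopifnot(inherits(fit, "tumor_fit"), fit$model == "cumulative")
  if (is.null(mice)) mice <- fit$mouse_ids
  ratios <- unlist(lapply(fit$draws[mice], function(d) {
    a2 <- d[, "alpha2"]
    if (all(a2 < floor)) return(NULL)
    d[, "alpha1"] / pmax(a2, floor)
  }), use.names = FALSE)
  if (is.null(ratios) || !length(ratios))
    stop("all alpha2 draws below floor: resistivity ratio undefined")
  structure(list(ratios = ratios, median = stats::median(ratios),
                 mean = mean(ratios), n_mice = length(mice)),
            class = "resistivity_stat")
}

#' @export
print.resistivity_stat <- function(x, ...) {
  cat(sprintf(
    "Treatment resistivity (alpha1/alpha2) over %d mice: median %.3f, mean %.3f\n",
    x$n_mice, x$median, x$mean))
  invisible(x)
}

#' Group-informed mouse-specific prediction
#'
#' The hybrid scheme: fit `r`, `alpha1`, `N0`, `sigma` to the mouse's day-0
#' and day-7 data (only the first dose interval is active there), then set
#' each draw's second-dose death rate from the group's treatment resistivity,
#' `alpha2 = alpha1 / R`, and simulate the cumulative two-dose model forward
#' to day 14. With `R = 1` this reduces to the mouse-specific scheme.
#'
#' @param cohort cohort data frame for one treatment arm.
#' @param mouse_id mouse to predict.
#' @param resistivity the group ratio `R`: a `"resistivity_stat"`, a number,
#'   or `NULL` to estimate it here from a cumulative fit of the arm.
#' @param priors,K,course,mcmc passed to [tumor_fit()].
#' @param n_draws posterior draws propagated forward.
#' @param cumulative_fit optional precomputed cumulative-model fit of the arm
#'   used when `resistivity` is `NULL`.
#' @param day7_fit optional precomputed constant-effect fit of the arm
#'   restricted to days 0-7 (see [predict_mouse_specific()]).
#' @param exclude_target when estimating `R`, exclude the target mouse's
#'   blocks from the pooled ratio (leave-one-out; the default). Set `FALSE`
#'   to use the whole group.
#' @param summary which resistivity summary to use, `"median"` (default) or
#'   `"mean"`.
#' @return a `"tumor_prediction"` object (field `R` records the ratio used).
#' @export
predict_group_informed <- function(cohort, mouse_id, resistivity = NULL,
                                   priors = tumor_priors(), K,
                                   course = treatment_course(),
                                   mcmc = mcmc_control(), n_draws = 1000,
                                   cumulative_fit = NULL, day7_fit = NULL,
                                   exclude_target = TRUE,
                                   summary = c("median", "mean")) {
  summary <- match.arg(summary)
  obs <- mouse_observed(cohort, mouse_id)
  if (is.null(resistivity)) {
    if (is.null(cumulative_fit)) {
      sub <- if (exclude_target) cohort[cohort$mouse_id != mouse_id, ]
             else cohort
      cumulative_fit <- tumor_fit(sub, "cumulative", priors = priors, K = K,
                                  course = course, mcmc = mcmc)
    }
    mice <- if (exclude_target)
      setdiff(cumulative_fit$mouse_ids, mouse_id) else cumulative_fit$mouse_ids
    resistivity <- group_resistivity(cumulative_fit, mice = mice)
  }
  R <- if (inherits(resistivity, "resistivity_stat")) resistivity[[summary]]
       else as.numeric(resistivity)
  if (!is.finite(R) || R <= 0) stop("resistivity ratio R must be > 0")

  t_fit <- c(0, 7)
  if (any(is.na(obs[as.character(t_fit)])))
    stop(sprintf("mouse %s lacks a measurement in the fitting window",
                 mouse_id))
  if (is.null(day7_fit)) {
    sub1 <- cohort[cohort$mouse_id == mouse_id & cohort$day %in% t_fit, ]
    fit <- tumor_fit(sub1, "linear", priors = priors, K = K, course = course,
                     mcmc = mcmc)
  } else {
    fit <- check_day7_fit(day7_fit, mouse_id, t_fit)
  }
  d <- fit$draws[[mouse_id]]
  i <- if (nrow(d) <= n_draws) seq_len(nrow(d))
       else sample.int(nrow(d), n_draws)
  a1 <- d[i, "alpha"]
  a2 <- a1 / R
  t_pred <- c(7, 14)
  v <- rk4_paths(c(0, t_pred), d[i, "r"], rep(K, length(i)), d[i, "N0"],
                 cbind(a1, a2), rep(0, length(i)), course$taus, dt = 0.01)
  draws <- v[, 2:3, drop = FALSE]
  colnames(draws) <- as.character(t_pred)
  new_prediction(mouse_id, "group-informed", t_pred, draws, obs,
                 fit$days_used, extra = list(R = R, fit = fit))
}

#' Run one prediction scheme for every mouse in an arm
#'
#' Convenience wrapper producing the per-mouse predictions of a treatment
#' arm under one scheme, computing the shared fits once: the day-0/7
#' constant-effect fit for the mouse-specific and group-informed schemes
#' (the treated-model posterior factorizes over mice, so one batched arm fit
#' equals the per-mouse fits), the full-course arm fit for leave-one-out,
#' and the cumulative-model fit behind the resistivity ratio.
#'
#' @param cohort cohort data frame for one treatment arm.
#' @param scheme `"mouse"`, `"loo"` or `"group"`.
#' @param priors,K,course,mcmc passed to [tumor_fit()].
#' @param n_draws posterior draws per mouse prediction.
#' @param mice mice to predict (default: all with day-0 and day-7 data).
#' @param cumulative_fit optional precomputed cumulative fit (scheme
#'   `"group"`).
#' @param exclude_target,summary resistivity options (scheme `"group"`), see
#'   [predict_group_informed()].
#' @return list of `"tumor_prediction"` objects, named by mouse.
#' @export
predict_arm <- function(cohort, scheme = c("mouse", "loo", "group"),
                        priors = tumor_priors(), K,
                        course = treatment_course(), mcmc = mcmc_control(),
                        n_draws = 1000, mice = NULL, cumulative_fit = NULL,
                        exclude_target = TRUE,
                        summary = c("median", "mean")) {
  scheme <- match.arg(scheme)
  summary <- match.arg(summary)
  if (is.null(mice)) {
    ids <- unique(cohort$mouse_id)
    mice <- ids[vapply(ids, function(i)
      all(c(0, 7) %in% cohort$day[cohort$mouse_id == i]), TRUE)]
  }
  if (scheme == "loo") {
    arm_fit <- tumor_fit(cohort, "linear", priors = priors, K = K,
                         course = course, mcmc = mcmc)
    preds <- lapply(mice, function(i)
      predict_leave_one_out(cohort, i, priors = priors, K = K,
                            course = course, mcmc = mcmc,
                            n_draws = n_draws, arm_fit = arm_fit))
  } else {
    day7 <- cohort[cohort$day %in% c(0, 7) & cohort$mouse_id %in% mice, ]
    day7_fit <- tumor_fit(day7, "linear", priors = priors, K = K,
                          course = course, mcmc = mcmc)
    if (scheme == "mouse") {
      preds <- lapply(mice, function(i)
        predict_mouse_specific(cohort, i, priors = priors, K = K,
                               course = course, mcmc = mcmc,
                               n_draws = n_draws, day7_fit = day7_fit))
    } else {
      if (is.null(cumulative_fit))
        cumulative_fit <- tumor_fit(cohort, "cumulative", priors = priors,
                                    K = K, course = course, mcmc = mcmc)
      preds <- lapply(mice, function(i)
        predict_group_informed(cohort, i, priors = priors, K = K,
                               course = course, mcmc = mcmc,
                               n_draws = n_draws,
                               cumulative_fit = cumulative_fit,
                               day7_fit = day7_fit,
                               exclude_target = exclude_target,
                               summary = summary))
    }
  }
  stats::setNames(preds, mice)
}
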