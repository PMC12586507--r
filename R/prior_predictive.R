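#' Prior predictive ensemble
#'
#' Monte-Carlo approximation of the prior predictive distribution: draws
#' parameter sets from the uniform priors and forward-simulates the noiseless
#' model solution on the measurement grid (the predictive band reflects
#' trajectory spread only; no noise draw enters). Deterministic under `seed`.
#'
#' @param priors a [tumor_priors()].
#' @param model model name as in [model_spec()].
#' @param course a [treatment_course()].
#' @param times measurement grid, days.
#' @param n number of prior draws (>= 1000 recommended; default 10000).
#' @param control use the control prior box for `r` and draw `K` from its
#'   prior (as for the untreated arm) instead of fixing it.
#' @param K fixed carrying capacity for treated-model checks with
#'   `control = FALSE`; if `NULL`, `K` is drawn from `priors$K`.
#' @param seed RNG seed.
#' @param dt RK4 step, days.
#' @return an object of class `"prior_predictive"`: list with `theta` (draw
#'   matrix), `y` (n x length(times) trajectory matrix), `times`.
#' @export
prior_predictive <- function(priors = tumor_priors(),
                             model = "logistic",
                             course = treatment_course(),
                             times = c(0, 7, 14), n = 10000,
                             control = model == "logistic",
                             K = NULL, seed = 1L, dt = 0.05) {
  stopifnot(inherits(priors, "tumor_priors"), n >= 1)
  set.seed(seed)
  ru <- function(b) stats::runif(n, b[1], b[2])
  r <- if (control) ru(priors$r_control) else ru(priors$r)
  Kv <- if (!is.null(K)) rep(K, n) else ru(priors$K)
  N0 <- ru(priors$N0)
  theta <- cbind(r = r, K = Kv, N0 = N0)
  taus <- course$taus
  a <- matrix(0, n, length(taus))
  beta_v <- rep(0, n)
  if (model %in% c("linear", "expdecay")) {
    al <- ru(priors$alpha)
    a <- matrix(al, n, length(taus))
    theta <- cbind(theta, alpha = al)
  } else if (model == "cumulative") {
    a1 <- ru(priors$alpha); a2 <- ru(priors$alpha)
    a <- cbind(a1, a2)
    theta <- cbind(theta, alpha1 = a1, alpha2 = a2)
  }
  if (model == "expdecay") {
    beta_v <- ru(priors$beta)
    theta <- cbind(theta, beta = beta_v)
  }
  y <- rk4_paths(times, r, Kv, N0, a, beta_v, taus, dt = dt)
  structure(list(theta = theta, y = y, times = times, model = model, n = n),
            class = "prior_predictive")
}

#' Prior predictive coverage
#'
#' At each observation day, forms the central `level` empirical interval of
#' the prior predictive ensemble (linear-interpolation quantiles; a point
#' exactly on a bound counts as inside) and returns the percentage of
#' observed data points lying within their day's interval. A coverage near
#' 100% indicates the priors generate dynamics at least as dispersed as the
#' data; a low value flags an over-restrictive prior box.
#'
#' @param ensemble a [prior_predictive()] object.
#' @param cohort cohort data frame with columns `day` and `volume_mm3`.
#' @param level central predictive mass (default 0.95).
#' @return coverage percentage in `[0, 100]`.
#' @export
coverage <- function(ensemble, cohort, level = 0.95) {
  stopifnot(inherits(ensemble, "prior_predictive"),
            all(c("day", "volume_mm3") %in% names(cohort)),
            level > 0, level <= 1)
  days <- unique(cohort$day)
  if (!all(days %in% ensemble$times))
    stop("observation day missing from the prior predictive grid")
  inside <- 0L; total <- 0L
  for (d in days) {
    col <- ensemble$y[, which(ensemble$times == d)]
    q <- stats::quantile(col, c((1 - level) / 2, (1 + level) / 2),
                         names = FALSE, type = 7)
    v <- cohort$volume_mm3[cohort$day == d]
    inside <- inside + sum(v >= q[1] & v <= q[2])
    total <- total + length(v)
  }
  100 * inside / total
}
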