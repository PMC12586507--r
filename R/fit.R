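#' Gaussian log-likelihood of observed tumor volumes
#'
#' \deqn{\ln \pi(D\mid\theta) = -\tfrac12 \sum_{i=1}^{N_T}
#'   [\ln(2\pi) + \ln(\sigma^2) + (D_i - Y_i)^2/\sigma^2],}
#' the additive-Gaussian measurement model used for all fits. Strictly
#' decreases as any residual grows in magnitude.
#'
#' @param observed measured volumes, mm^3.
#' @param predicted model solution at the observation times, mm^3.
#' @param sigma measurement-noise s.d., mm^3 (> 0).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(observed, predicted, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  stopifnot(length(observed) == length(predicted))
  -0.5 * sum(log(2 * pi) + log(sigma^2) + (observed - predicted)^2 / sigma^2)
}

param_names_for <- function(model) {
  switch(model,
    logistic = c("r", "N0", "sigma"),
    linear = c("r", "alpha", "N0", "sigma"),
    expdecay = c("r", "alpha", "N0", "sigma"),
    cumulative = c("r", "alpha1", "alpha2", "N0", "sigma"))
}

mouse_bounds_for <- function(model, priors, control = FALSE) {
  r <- if (control) priors$r_control else priors$r
  b <- switch(model,
    logistic = rbind(r, priors$N0, priors$sigma),
    linear = rbind(r, priors$alpha, priors$N0, priors$sigma),
    expdecay = rbind(r, priors$alpha, priors$N0, priors$sigma),
    cumulative = rbind(r, priors$alpha, priors$alpha, priors$N0, priors$sigma))
  rownames(b) <- param_names_for(model)
  b
}

# Split a cohort data frame into per-mouse observation sets on a common grid.
cohort_obs <- function(cohort, days_use = NULL) {
  need <- c("mouse_id", "day", "volume_mm3")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns mouse_id, day, volume_mm3")
  if (!is.null(days_use)) cohort <- cohort[cohort$day %in% days_use, ]
  ids <- unique(cohort$mouse_id)
  grid <- sort(unique(cohort$day))
  D <- matrix(NA_real_, length(ids), length(grid),
              dimnames = list(ids, as.character(grid)))
  for (i in seq_along(ids)) {
    rows <- cohort[cohort$mouse_id == ids[i], ]
    D[i, match(rows$day, grid)] <- rows$volume_mm3
  }
  n_per <- rowSums(!is.na(D))
  if (any(n_per < 2))
    stop(sprintf("mouse %s has fewer than 2 measurements",
                 ids[which(n_per < 2)[1]]))
  list(ids = ids, grid = grid, D = D, n_per = n_per,
       group = if ("group" %in% names(cohort))
         cohort$group[match(ids, cohort$mouse_id)] else rep(NA_character_,
                                                            length(ids)))
}

# Profiled-sigma maximum likelihood for one mouse's shape parameters:
# bounded Levenberg-Marquardt least squares on the trajectory residuals.
# The noise s.d. has the analytic profile optimum sqrt(SS / N_T), clamped to
# its prior bounds. Tries each start, keeps the best.
refine_mouse <- function(starts, lower_s, upper_s, resid_fn, nT, sig_bounds) {
  best <- NULL
  for (st in starts) {
    o <- try(minpack.lm::nls.lm(
      par = pmin(pmax(st, lower_s), upper_s), fn = resid_fn,
      lower = lower_s, upper = upper_s,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(o, "try-error")) next
    SS <- sum(o$fvec^2)
    sig <- min(max(sqrt(SS / nT), sig_bounds[1]), sig_bounds[2])
    lnL <- -0.5 * (nT * log(2 * pi) + 2 * nT * log(sig) + SS / sig^2)
    if (is.null(best) || lnL > best$lnL)
      best <- list(shape = o$par, sigma = sig, lnL = lnL)
  }
  best
}

# Batched Gaussian log-likelihood: pred k x G, rows matched to mice via unit.
batch_loglik <- function(pred, sigma, D, n_per, unit) {
  Dm <- D[unit, , drop = FALSE]
  resid2 <- (Dm - pred)^2
  rs <- rowSums(resid2, na.rm = TRUE)
  nT <- n_per[unit]
  -0.5 * (nT * log(2 * pi) + 2 * nT * log(sigma) + rs / sigma^2)
}

#' Fit a tumor growth model to a cohort by ensemble MCMC
#'
#' The single entry point for Bayesian parameter estimation. All parameters
#' carry uniform priors (see [tumor_priors()]); the posterior is sampled with
#' an affine-invariant ensemble (stretch move) sampler using 2n chains for n
#' free parameters.
#'
#' The hierarchical structure follows the study design:
#' \describe{
#' \item{`"logistic"` (control arm)}{one population-level carrying capacity
#'   `K` shared across mice, with mouse-specific `r`, `N0` and noise `sigma`,
#'   sampled jointly. The posterior median of `K` is fixed downstream.}
#' \item{`"linear"`, `"cumulative"`}{mouse-specific parameters with `K`
#'   fixed; the posterior factorizes over mice, so mice are sampled as
#'   independent units in one batched run.}
#' \item{`"expdecay"`}{one protocol-level decay rate `beta` shared across the
#'   arm plus mouse-specific blocks, sampled jointly.}
#' }
#'
#' @param cohort cohort data frame (`mouse_id`, `group`, `day`, `volume_mm3`).
#' @param model one of `"logistic"`, `"linear"`, `"expdecay"`, `"cumulative"`.
#' @param priors a [tumor_priors()]. Treated models use `priors$r`; in the
#'   full workflow tighten it first with [r_prior_from_control()].
#' @param K fixed carrying capacity, mm^3; required for treated models,
#'   ignored (estimated) for `"logistic"`.
#' @param course a [treatment_course()].
#' @param mcmc an [mcmc_control()].
#' @param days_use optional subset of measurement days to fit (e.g. `c(0, 7)`
#'   for prediction fits that must not see day 14).
#' @return an object of class `"tumor_fit"`; see Details. Key fields:
#'   `draws` (per-mouse posterior draw matrices), `shared` (draws of `K` or
#'   `beta` where applicable), `lnL_hat` (maximum log-likelihood), `Z`
#'   (number of estimated parameters), `n_obs`, `converged`.
#' @seealso [bic()], [select_model()], [predict_mouse_specific()]
#' @export
tumor_fit <- function(cohort, model = c("logistic", "linear", "expdecay",
                                        "cumulative"),
                      priors = tumor_priors(), K = NULL,
                      course = treatment_course(), mcmc = mcmc_control(),
                      days_use = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "tumor_priors"), inherits(mcmc, "mcmc_control"))
  obs <- cohort_obs(cohort, days_use)
  M <- length(obs$ids)
  if (M < 1) stop("empty cohort")
  if (model != "logistic" && (is.null(K) || !is.numeric(K) || K <= 0))
    stop("treated models require a fixed carrying capacity K > 0")
  grid <- obs$grid
  taus <- course$taus
  dt <- mcmc$dt
  pn <- param_names_for(model)
  npar_m <- length(pn)
  mb <- mouse_bounds_for(model, priors, control = model == "logistic")

  set.seed(mcmc$seed)

  if (model %in% c("linear", "cumulative")) {
    lower <- mb[, 1]; upper <- mb[, 2]
    n_alpha <- if (model == "cumulative") 2L else 1L
    log_post <- function(theta, unit) {
      r <- theta[, 1]
      if (model == "linear") a <- cbind(theta[, 2], theta[, 2])
      else a <- theta[, 2:3, drop = FALSE]
      N0 <- theta[, npar_m - 1L]
      sigma <- theta[, npar_m]
      pred <- rk4_paths(grid, r, rep(K, nrow(theta)), N0, a,
                        rep(0, nrow(theta)), taus, dt = dt)
      batch_loglik(pred, sigma, obs$D, obs$n_per, unit)
    }
    sam <- run_sampler(log_post, lower, upper, M, mcmc)
    draws <- lapply(sam$draws, function(d) { colnames(d) <- pn; d })
    loglik <- sam$logpost
    shared <- NULL
    Z <- M * npar_m
    lnL_mcmc <- sum(vapply(loglik, max, 0))
    lnL_hat <- lnL_mcmc
    theta_hat <- t(vapply(seq_len(M), function(u)
      draws[[u]][which.max(loglik[[u]]), ], numeric(npar_m)))
    colnames(theta_hat) <- pn
    if (mcmc$refine) {
      shape_idx <- seq_len(npar_m - 1L)   # all but sigma (profiled)
      midbox <- (mb[shape_idx, 1] + mb[shape_idx, 2]) / 2
      tot <- 0
      for (u in seq_len(M)) {
        have <- which(!is.na(obs$D[u, ]))
        Du <- obs$D[u, have]
        resid_fn <- function(sh) {
          a <- if (model == "linear") matrix(sh[2], 1, length(taus))
               else matrix(sh[2:3], 1)
          Du - rk4_paths(grid, sh[1], K, sh[npar_m - 1L], a, 0, taus,
                         dt = dt)[1, have]
        }
        # corner starts cross the r-alpha ridge from both sides
        lo_s <- mb[shape_idx, 1]; hi_s <- mb[shape_idx, 2]
        w <- hi_s - lo_s
        c1 <- lo_s + 0.2 * w; c2 <- hi_s - 0.2 * w
        c1[npar_m - 1L] <- c2[npar_m - 1L] <- Du[1]   # N0 at observed day 0
        c1[1] <- lo_s[1] + 0.8 * w[1]                 # high r, low alpha
        c2[1] <- lo_s[1] + 0.2 * w[1]                 # low r, high alpha
        ref <- refine_mouse(list(theta_hat[u, shape_idx], midbox, c1, c2),
                            lo_s, hi_s, resid_fn,
                            obs$n_per[u], priors$sigma)
        if (!is.null(ref) && ref$lnL > max(loglik[[u]])) {
          tot <- tot + ref$lnL
          theta_hat[u, ] <- c(ref$shape, ref$sigma)
        } else tot <- tot + max(loglik[[u]])
      }
      lnL_hat <- max(tot, lnL_mcmc)
    }
  } else {
    # joint fits: logistic (shared K) or expdecay (shared beta)
    shared_name <- if (model == "logistic") "K" else "beta"
    shared_bounds <- if (model == "logistic") priors$K else priors$beta
    lower <- c(shared_bounds[1], rep(mb[, 1], M))
    upper <- c(shared_bounds[2], rep(mb[, 2], M))
    log_post <- function(theta, unit) {
      k <- nrow(theta)
      sh <- theta[, 1]
      blocks <- theta[, -1, drop = FALSE]
      # expand to k*M trajectories, mouse index fastest
      idx <- rep(seq_len(M), times = k)
      rows <- rep(seq_len(k), each = M)
      getp <- function(j) blocks[cbind(rows, (idx - 1L) * npar_m + j)]
      r <- getp(1L)
      if (model == "logistic") {
        a <- matrix(0, k * M, length(taus))
        beta_v <- rep(0, k * M)
        Kv <- sh[rows]
        N0 <- getp(2L); sigma <- getp(3L)
      } else {
        av <- getp(2L)
        a <- matrix(av, k * M, length(taus))
        beta_v <- sh[rows]
        Kv <- rep(K, k * M)
        N0 <- getp(3L); sigma <- getp(4L)
      }
      pred <- rk4_paths(grid, r, Kv, N0, a, beta_v, taus, dt = dt)
      ll <- batch_loglik(pred, sigma, obs$D, obs$n_per, idx)
      as.vector(rowsum(ll, rows))
    }
    sam <- run_sampler(log_post, lower, upper, 1L, mcmc)
    joint <- sam$draws[[1]]
    shared <- stats::setNames(list(joint[, 1]), shared_name)
    draws <- lapply(seq_len(M), function(u) {
      d <- joint[, 1L + (u - 1L) * npar_m + seq_len(npar_m), drop = FALSE]
      colnames(d) <- pn
      d
    })
    loglik <- rep(sam$logpost, M)
    Z <- 1L + M * npar_m
    lnL_mcmc <- max(sam$logpost[[1]])
    lnL_hat <- lnL_mcmc
    th_best <- joint[which.max(sam$logpost[[1]]), ]
    theta_hat <- matrix(th_best[-1], M, npar_m, byrow = TRUE,
                        dimnames = list(NULL, pn))
    attr(theta_hat, "shared") <- th_best[1]
    if (mcmc$refine) {
      # Mouse blocks factorize given the shared parameter: profile the
      # likelihood over the shared parameter, refining each mouse block by
      # bounded least squares (sigma profiled analytically) at each value.
      th <- joint[which.max(sam$logpost[[1]]), ]
      shape_idx <- seq_len(npar_m - 1L)
      blo <- mb[shape_idx, 1]; bhi <- mb[shape_idx, 2]
      midbox <- (blo + bhi) / 2
      blocks_of <- function(th) lapply(seq_len(M), function(u)
        th[1L + (u - 1L) * npar_m + shape_idx])
      resid_u <- function(u, sh) {
        have <- which(!is.na(obs$D[u, ]))
        Du <- obs$D[u, have]
        function(shp) {
          if (model == "logistic")
            pred <- rk4_paths(grid, shp[1], sh, shp[2],
                              matrix(0, 1, length(taus)), 0, taus, dt = dt)
          else
            pred <- rk4_paths(grid, shp[1], K, shp[3],
                              matrix(shp[2], 1, length(taus)), sh, taus,
                              dt = dt)
          Du - pred[1, have]
        }
      }
      opt_blocks <- function(sh, blocks, multistart = FALSE) {
        val <- 0
        sigs <- numeric(M)
        for (u in seq_len(M)) {
          starts <- list(blocks[[u]])
          if (multistart) starts <- c(starts, list(midbox))
          ref <- refine_mouse(starts, blo, bhi, resid_u(u, sh),
                              obs$n_per[u], priors$sigma)
          if (is.null(ref)) return(list(blocks = blocks, val = -Inf))
          blocks[[u]] <- ref$shape
          sigs[u] <- ref$sigma
          val <- val + ref$lnL
        }
        list(blocks = blocks, val = val, sigs = sigs)
      }
      # profile the likelihood over the shared parameter on a coarse grid
      # (warm-starting the mouse blocks), then shrink the grid locally
      width <- shared_bounds[2] - shared_bounds[1]
      sh_grid <- unique(c(shared_bounds[1] + 1e-6 * width, th[1],
                          seq(shared_bounds[1], shared_bounds[2],
                              length.out = 7)[-c(1, 7)]))
      blocks <- blocks_of(th)
      best <- list(val = -Inf, sh = th[1])
      first <- TRUE
      for (sh in sh_grid) {
        cur <- opt_blocks(sh, blocks, multistart = first)
        first <- FALSE
        blocks <- cur$blocks
        if (cur$val > best$val) { best <- cur; best$sh <- sh }
      }
      step <- width / 6
      for (round in 1:3) {
        step <- step / 3
        for (sh in pmin(pmax(best$sh + c(-step, step), shared_bounds[1]),
                        shared_bounds[2])) {
          cur <- opt_blocks(sh, best$blocks)
          if (cur$val > best$val) { cur$sh <- sh; best <- cur }
        }
      }
      if (best$val > lnL_mcmc) {
        theta_hat <- cbind(do.call(rbind, best$blocks), best$sigs)
        colnames(theta_hat) <- pn
        attr(theta_hat, "shared") <- best$sh
      }
      lnL_hat <- max(lnL_mcmc, best$val)
    }
  }

  names(draws) <- obs$ids
  summaries <- do.call(rbind, lapply(seq_len(M), function(u) {
    q <- apply(draws[[u]], 2, stats::quantile, c(0.5, 0.025, 0.975))
    data.frame(mouse_id = obs$ids[u], group = obs$group[u], parameter = pn,
               median = q[1, ], lo95 = q[2, ], hi95 = q[3, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  structure(list(
    model = model, spec = model_spec(model), course = course,
    priors = priors, K = if (model == "logistic") NULL else K,
    mouse_ids = obs$ids, group = obs$group, obs = obs,
    days_used = grid, draws = draws, shared = shared, loglik = loglik,
    theta_hat = theta_hat,
    lnL_hat = lnL_hat, lnL_hat_mcmc = lnL_mcmc, Z = Z,
    n_obs = sum(obs$n_per), summaries = summaries,
    converged = sam$converged, tau = sam$tau,
    sampler = list(n_walkers = sam$n_walkers, n_steps = sam$n_steps,
                   retained_per_chain = sam$retained_per_chain,
                   extensions = sam$extensions, seed = mcmc$seed,
                   dt = mcmc$dt)),
    class = "tumor_fit")
}

#' Posterior median of the control carrying capacity
#'
#' @param fit a logistic-model `"tumor_fit"` of the control arm.
#' @return the posterior median of `K`, mm^3, to be fixed in treated-arm fits.
#' @export
control_K <- function(fit) {
  stopifnot(inherits(fit, "tumor_fit"), fit$model == "logistic")
  stats::median(fit$shared$K)
}
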