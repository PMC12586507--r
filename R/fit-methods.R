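# Forward-simulate posterior draws for selected mice of a fit.
# Returns a list (one element per mouse) of ndraws x length(times) volume
# matrices, plus the draw indices used. Draw rows are aligned across mice
# (important for joint fits, where shared K/beta draws live on the same row).
fit_draw_paths <- function(fit, times, ndraws = 500, mice = NULL,
                           idx = NULL, dt = 0.01) {
  stopifnot(inherits(fit, "tumor_fit"))
  if (is.null(mice)) mice <- fit$mouse_ids
  n_total <- nrow(fit$draws[[1]])
  if (is.null(idx)) {
    ndraws <- min(ndraws, n_total)
    idx <- if (ndraws == n_total) seq_len(n_total)
           else sample.int(n_total, ndraws)
  }
  k <- length(idx)
  M <- length(mice)
  taus <- fit$course$taus
  r <- N0 <- sig <- numeric(k * M)
  a <- matrix(0, k * M, length(taus))
  beta_v <- numeric(k * M)
  Kv <- numeric(k * M)
  for (j in seq_len(M)) {
    d <- fit$draws[[mice[j]]][idx, , drop = FALSE]
    rows <- (j - 1L) * k + seq_len(k)
    r[rows] <- d[, "r"]
    N0[rows] <- d[, "N0"]
    sig[rows] <- d[, "sigma"]
    if (fit$model %in% c("linear", "expdecay"))
      a[rows, ] <- d[, "alpha"]
    if (fit$model == "cumulative")
      a[rows, ] <- d[, c("alpha1", "alpha2")]
    Kv[rows] <- if (fit$model == "logistic") fit$shared$K[idx] else fit$K
    beta_v[rows] <- if (fit$model == "expdecay") fit$shared$beta[idx] else 0
  }
  v <- rk4_paths(times, r, Kv, N0, a, beta_v, taus, dt = dt)
  paths <- lapply(seq_len(M), function(j)
    v[(j - 1L) * k + seq_len(k), , drop = FALSE])
  names(paths) <- mice
  list(paths = paths, idx = idx, sigma = split(sig, rep(seq_len(M), each = k)))
}

#' @export
print.tumor_fit <- function(x, ...) {
  cat(sprintf("Tumor growth model fit: %s\n", x$model))
  cat(sprintf("  mice: %d   observations: %d   estimated parameters (Z): %d\n",
              length(x$mouse_ids), x$n_obs, x$Z))
  cat(sprintf("  chains: %d   steps: %d   retained/chain: %d%s\n",
              x$sampler$n_walkers, x$sampler$n_steps,
              x$sampler$retained_per_chain,
              if (all(x$converged)) "" else "   [convergence flagged]"))
  cat(sprintf("  max log-likelihood: %.3f   BIC: %.2f\n",
              x$lnL_hat, bic(x$lnL_hat, x$Z, x$n_obs)))
  if (!is.null(x$shared))
    cat(sprintf("  shared %s posterior median: %.4g\n",
                names(x$shared)[1], stats::median(x$shared[[1]])))
  invisible(x)
}

#' @export
summary.tumor_fit <- function(object, ...) {
  out <- list(model = object$model, summaries = object$summaries,
              shared = if (!is.null(object$shared))
                lapply(object$shared, stats::quantile,
                       c(0.025, 0.5, 0.975)) else NULL,
              lnL_hat = object$lnL_hat, Z = object$Z, n_obs = object$n_obs,
              bic = bic(object$lnL_hat, object$Z, object$n_obs),
              converged = object$converged)
  class(out) <- "summary.tumor_fit"
  out
}

#' @export
print.summary.tumor_fit <- function(x, ...) {
  cat(sprintf("Model: %s   lnL^ = %.3f   Z = %d   n = %d   BIC = %.2f\n\n",
              x$model, x$lnL_hat, x$Z, x$n_obs, x$bic))
  if (!is.null(x$shared)) {
    for (nm in names(x$shared)) {
      q <- x$shared[[nm]]
      cat(sprintf("Shared %s: median %.4g  (95%% CI %.4g - %.4g)\n",
                  nm, q[2], q[1], q[3]))
    }
    cat("\n")
  }
  print(x$summaries, digits = 4)
  invisible(x)
}

#' Posterior-median parameter estimates
#'
#' @param object a `"tumor_fit"`.
#' @param ... unused.
#' @return matrix of per-mouse posterior medians (mice in rows); shared
#'   parameters (`K` or `beta`) are appended as an attribute `"shared"`.
#' @export
coef.tumor_fit <- function(object, ...) {
  m <- t(vapply(object$draws, function(d) apply(d, 2, stats::median),
                numeric(ncol(object$draws[[1]]))))
  if (!is.null(object$shared))
    attr(m, "shared") <- vapply(object$shared, stats::median, 0)
  m
}

#' @export
logLik.tumor_fit <- function(object, ...) {
  structure(object$lnL_hat, df = object$Z, nobs = object$n_obs,
            class = "logLik")
}

#' Posterior predictive tumor-volume trajectories
#'
#' Forward-simulates posterior draws and summarizes the predictive
#' distribution of the (noiseless) model solution per mouse.
#'
#' @param object a `"tumor_fit"`.
#' @param times output times, days.
#' @param ndraws number of posterior draws to propagate.
#' @param level central predictive-interval mass.
#' @param ... unused.
#' @return data frame with columns `mouse_id`, `time`, `median`, `lo`, `hi`.
#' @export
predict.tumor_fit <- function(object, times = c(0, 7, 14), ndraws = 500,
                              level = 0.95, ...) {
  sim <- fit_draw_paths(object, times, ndraws = ndraws)
  qs <- c(0.5, (1 - level) / 2, (1 + level) / 2)
  do.call(rbind, lapply(names(sim$paths), function(id) {
    q <- apply(sim$paths[[id]], 2, stats::quantile, qs)
    data.frame(mouse_id = id, time = times, median = q[1, ],
               lo = q[2, ], hi = q[3, ], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' @export
fitted.tumor_fit <- function(object, ndraws = 500, ...) {
  p <- predict(object, times = object$obs$grid, ndraws = ndraws)
  D <- object$obs$D
  out <- do.call(rbind, lapply(seq_along(object$mouse_ids), function(u) {
    id <- object$mouse_ids[u]
    have <- which(!is.na(D[u, ]))
    pm <- p[p$mouse_id == id, ]
    data.frame(mouse_id = id, day = object$obs$grid[have],
               observed = D[u, have],
               fitted = pm$median[match(object$obs$grid[have], pm$time)],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' @export
residuals.tumor_fit <- function(object, ...) {
  f <- fitted(object, ...)
  stats::setNames(f$observed - f$fitted,
                  paste0(f$mouse_id, "_d", f$day))
}

#' Simulate posterior predictive datasets
#'
#' Draws parameter sets from the posterior, solves the model at the observed
#' measurement days, and adds Gaussian measurement noise using each draw's
#' own `sigma` (volumes truncated below at 1 mm^3).
#'
#' @param object a `"tumor_fit"`.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` cohort data frames.
#' @export
simulate.tumor_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grid <- object$obs$grid
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    sim <- fit_draw_paths(object, grid, ndraws = 1)
    rows <- lapply(seq_along(object$mouse_ids), function(u) {
      id <- object$mouse_ids[u]
      have <- which(!is.na(object$obs$D[u, ]))
      mu <- sim$paths[[id]][1, have]
      sd <- sim$sigma[[u]][1]
      data.frame(mouse_id = id, group = object$group[u], day = grid[have],
                 volume_mm3 = pmax(stats::rnorm(length(have), mu, sd), 1),
                 censored = 0L, stringsAsFactors = FALSE)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  if (nsim == 1) out[[1]] else out
}

#' Plot fitted trajectories against the data
#'
#' @param x a `"tumor_fit"`.
#' @param ndraws posterior draws behind the plotted median curves.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tumor_fit <- function(x, ndraws = 200, ...) {
  tgrid <- seq(min(x$obs$grid), max(x$obs$grid), by = 0.5)
  p <- predict(x, times = tgrid, ndraws = ndraws)
  M <- length(x$mouse_ids)
  med <- sapply(x$mouse_ids, function(id) p$median[p$mouse_id == id])
  graphics::matplot(tgrid, med, type = "l", lty = 2,
                    col = seq_len(M), xlab = "time (days)",
                    ylab = expression(tumor ~ volume ~ (mm^3)),
                    main = sprintf("%s model fit", x$model), ...)
  for (u in seq_len(M)) {
    have <- which(!is.na(x$obs$D[u, ]))
    graphics::points(x$obs$grid[have], x$obs$D[u, have], col = u, pch = 19)
  }
  invisible(x)
}
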