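# Affine-invariant ensemble sampler (Goodman & Weare stretch move), run as
# n_units independent samplers in lockstep so that a single vectorized
# log-posterior call (one batched ODE solve) serves every unit's proposals.
# Used with one unit per mouse for factorized fits and with n_units = 1 for
# joint (shared-parameter) fits.
#
# log_post(theta, unit): theta is a k x dim matrix of in-box parameter rows,
# unit an integer vector of length k; returns a length-k numeric. The flat
# box prior is enforced by the sampler: out-of-box proposals are rejected
# without evaluating the likelihood.

# One batch of n_steps stretch moves from a given state.
# state[walker, param, unit]; lp[walker, unit].
stretch_run <- function(state, lp, log_post, lower, upper, n_steps, a = 2) {
  n_walkers <- dim(state)[1]; npar <- dim(state)[2]; n_units <- dim(state)[3]
  nh <- n_walkers %/% 2L
  halves <- list(seq_len(nh), (nh + 1L):n_walkers)
  draws <- array(NA_real_, c(n_steps, n_walkers, npar, n_units))
  lps <- array(NA_real_, c(n_steps, n_walkers, n_units))
  for (step in seq_len(n_steps)) {
    for (h in 1:2) {
      S1 <- halves[[h]]; S2 <- halves[[3 - h]]
      k1 <- length(S1)
      zm <- matrix(((a - 1) * stats::runif(k1 * n_units) + 1)^2 / a,
                   k1, n_units)
      jm <- matrix(sample.int(length(S2), k1 * n_units, replace = TRUE),
                   k1, n_units)
      prop <- array(NA_real_, c(k1, npar, n_units))
      for (u in seq_len(n_units)) {
        Xi <- state[S1, , u]; dim(Xi) <- c(k1, npar)
        Xj <- state[S2[jm[, u]], , u]; dim(Xj) <- c(k1, npar)
        prop[, , u] <- Xj + zm[, u] * (Xi - Xj)
      }
      flat <- matrix(aperm(prop, c(1, 3, 2)), k1 * n_units, npar)
      unit_of <- rep(seq_len(n_units), each = k1)
      inbox <- rowSums(flat < rep(lower, each = nrow(flat)) |
                       flat > rep(upper, each = nrow(flat))) == 0
      lp_new <- rep(-Inf, nrow(flat))
      if (any(inbox))
        lp_new[inbox] <- log_post(flat[inbox, , drop = FALSE], unit_of[inbox])
      lp_new <- matrix(lp_new, k1, n_units)
      logr <- (npar - 1) * log(zm) + lp_new - lp[S1, , drop = FALSE]
      acc <- log(matrix(stats::runif(k1 * n_units), k1, n_units)) < logr
      for (u in seq_len(n_units)) {
        w <- which(acc[, u])
        if (length(w)) {
          state[S1[w], , u] <- prop[w, , u]
          lp[S1[w], u] <- lp_new[w, u]
        }
      }
    }
    draws[step, , , ] <- state
    lps[step, , ] <- lp
  }
  list(draws = draws, logpost = lps, state = state, lp = lp)
}

# Uniform-in-box initialization, redrawing any walker that lands at zero
# posterior density.
stretch_init <- function(log_post, lower, upper, n_units, n_walkers) {
  npar <- length(lower)
  state <- array(NA_real_, c(n_walkers, npar, n_units))
  for (u in seq_len(n_units))
    state[, , u] <- matrix(stats::runif(n_walkers * npar, lower, upper),
                           n_walkers, npar, byrow = TRUE)
  flat <- matrix(aperm(state, c(1, 3, 2)), n_walkers * n_units, npar)
  lp <- matrix(log_post(flat, rep(seq_len(n_units), each = n_walkers)),
               n_walkers, n_units)
  for (tries in 1:50) {
    bad <- which(!is.finite(lp), arr.ind = TRUE)
    if (!nrow(bad)) break
    redraw <- matrix(stats::runif(nrow(bad) * npar, lower, upper),
                     nrow(bad), npar, byrow = TRUE)
    for (i in seq_len(nrow(bad))) state[bad[i, 1], , bad[i, 2]] <- redraw[i, ]
    lp[bad] <- log_post(redraw, bad[, 2])
  }
  if (any(!is.finite(lp)))
    stop("could not initialize walkers at finite posterior density")
  list(state = state, lp = lp)
}

# Integrated autocorrelation time of a chain matrix (steps x walkers), from
# the walker-averaged series, using Sokal's automatic windowing (c = 5).
integrated_act <- function(x) {
  y <- if (is.matrix(x)) rowMeans(x) else x
  n <- length(y)
  if (n < 8 || stats::var(y) == 0) return(1)
  rho <- stats::acf(y, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  tau <- 1
  for (w in seq_along(rho)) {
    tau <- 1 + 2 * sum(rho[seq_len(w)])
    if (w >= 5 * tau) break
  }
  max(tau, 1)
}

# Full sampling workflow: 2n-rule walker count, burn-in, thinning, the
# accepted-samples-per-chain target, and automatic extension until the chain
# length exceeds 50 tau (up to max_extend doublings; flagged otherwise).
# Returns per-unit retained draw matrices pooled across walkers.
run_sampler <- function(log_post, lower, upper, n_units, mcmc) {
  npar <- length(lower)
  stopifnot(length(upper) == npar, all(lower < upper))
  n_walkers <- max(4L, mcmc$walkers_per_dim * npar)
  n_walkers <- n_walkers + n_walkers %% 2L
  n_steps <- ceiling(mcmc$n_samples * mcmc$thin / (1 - mcmc$burn_frac))

  ini <- stretch_init(log_post, lower, upper, n_units, n_walkers)
  res <- stretch_run(ini$state, ini$lp, log_post, lower, upper, n_steps,
                     a = mcmc$stretch_a)
  total <- n_steps
  extensions <- 0L
  repeat {
    tau <- vapply(seq_len(n_units), function(u)
      max(vapply(seq_len(npar), function(d)
        integrated_act(res$draws[, , d, u]), 0)), 0)
    converged <- total > 50 * tau
    if (!mcmc$act_check || all(converged) || extensions >= mcmc$max_extend)
      break
    more <- stretch_run(res$state, res$lp, log_post, lower, upper, total,
                        a = mcmc$stretch_a)
    res <- list(
      draws = bind_steps(res$draws, more$draws),
      logpost = bind_steps(res$logpost, more$logpost),
      state = more$state, lp = more$lp)
    total <- dim(res$draws)[1]
    extensions <- extensions + 1L
  }
  burn <- floor(mcmc$burn_frac * total)
  keep <- seq(burn + 1L, total, by = mcmc$thin)
  draws <- lapply(seq_len(n_units), function(u) {
    d <- res$draws[keep, , , u]
    dim(d) <- c(length(keep) * n_walkers, npar)
    d
  })
  logpost <- lapply(seq_len(n_units), function(u)
    as.vector(res$logpost[keep, , u]))
  list(draws = draws, logpost = logpost, tau = tau, converged = converged,
       n_walkers = n_walkers, n_steps = total, extensions = extensions,
       retained_per_chain = length(keep))
}

bind_steps <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(NA_real_, c(da[1] + db[1], da[-1]))
  if (length(da) == 4) {
    out[seq_len(da[1]), , , ] <- a
    out[da[1] + seq_len(db[1]), , , ] <- b
  } else {
    out[seq_len(da[1]), , ] <- a
    out[da[1] + seq_len(db[1]), , ] <- b
  }
  out
}
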