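#' Uniform prior bounds for Bayesian parameter estimation
#'
#' All parameters carry independent uniform priors. Defaults for the
#' treatment arms are: initial volume `N0` ~ U(0, 600) mm^3, proliferation
#' rate `r` ~ U(0.03, 0.3) per day, treatment death rate `alpha` ~ U(0, 0.3)
#' per day, and treatment-effect decay `beta` ~ U(0, 2). The control arm uses
#' wider bounds validated by prior predictive checks: `r` ~ U(0, 0.5) per day,
#' carrying capacity `K` ~ U(1, 3000) mm^3, `N0` ~ U(0, 600) mm^3. The
#' measurement-noise s.d. `sigma` ~ U(1, 200) mm^3 is estimated per mouse.
#' In practice the treatment-arm `r` bounds are tightened to the central range
#' of the control posterior via [r_prior_from_control()].
#'
#' @param N0,r,alpha,beta,sigma,K,r_control length-2 numeric bounds `(a, b)`
#'   with `a < b`.
#' @return an object of class `"tumor_priors"`.
#' @export
tumor_priors <- function(N0 = c(0, 600), r = c(0.03, 0.3), alpha = c(0, 0.3),
                         beta = c(0, 2), sigma = c(1, 200), K = c(1, 3000),
                         r_control = c(0, 0.5)) {
  p <- list(N0 = N0, r = r, alpha = alpha, beta = beta, sigma = sigma,
            K = K, r_control = r_control)
  for (nm in names(p)) {
    b <- p[[nm]]
    if (!(is.numeric(b) && length(b) == 2 && b[1] < b[2]))
      stop(sprintf("prior bounds for %s must be numeric (a, b) with a < b", nm))
  }
  structure(p, class = "tumor_priors")
}

#' Derive treatment-arm r bounds from a control fit
#'
#' Sets the treatment-arm proliferation-rate prior to the central interval
#' (default 95%) of the pooled control posterior for `r`, the mechanism by
#' which control information constrains the treated-arm fits.
#'
#' @param priors a [tumor_priors()] object to update.
#' @param control_fit a `"tumor_fit"` of the logistic model to control data.
#' @param level central posterior mass defining the bounds.
#' @return the updated `"tumor_priors"`.
#' @export
r_prior_from_control <- function(priors, control_fit, level = 0.95) {
  stopifnot(inherits(priors, "tumor_priors"), inherits(control_fit, "tumor_fit"),
            control_fit$model == "logistic")
  r_all <- unlist(lapply(control_fit$draws, function(d) d[, "r"]))
  q <- stats::quantile(r_all, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  priors$r <- as.numeric(q)
  priors
}

#' MCMC sampler configuration
#'
#' Controls the affine-invariant ensemble (stretch move) sampler. The number
#' of chains (walkers) follows the 2n rule, n being the number of free
#' parameters; `n_samples` is the target number of retained (post burn-in)
#' samples per chain, with a default of 20,000. Convergence is assessed by
#' the integrated autocorrelation time; chains failing the length criterion
#' are extended up to `max_extend` times and otherwise flagged.
#'
#' @param n_samples retained samples per chain after burn-in.
#' @param burn_frac fraction of each chain discarded as burn-in.
#' @param walkers_per_dim walkers per free parameter (>= 2).
#' @param stretch_a stretch-move scale parameter (> 1).
#' @param thin retain every `thin`-th post burn-in step.
#' @param dt RK4 step size (days) used inside likelihood evaluations.
#' @param seed mandatory RNG seed; all fits are reproducible.
#' @param max_extend maximum automatic chain extensions when the
#'   autocorrelation-time criterion (chain length > 50 tau) fails.
#' @param act_check run the autocorrelation-time convergence check.
#' @param refine refine the maximum log-likelihood by bounded local
#'   optimization started from the best posterior draw. The default `FALSE`
#'   follows the sampled-posterior convention: `lnL^` is the maximum over
#'   retained draws, with no optimizer.
#' @return an object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_samples = 20000, burn_frac = 0.25,
                         walkers_per_dim = 2, stretch_a = 2, thin = 1,
                         dt = 0.25, seed = 1L, max_extend = 3,
                         act_check = TRUE, refine = FALSE) {
  stopifnot(n_samples > 0, burn_frac >= 0, burn_frac < 1,
            walkers_per_dim >= 2, stretch_a > 1, thin >= 1, dt > 0,
            is.numeric(seed))
  structure(list(n_samples = n_samples, burn_frac = burn_frac,
                 walkers_per_dim = walkers_per_dim, stretch_a = stretch_a,
                 thin = thin, dt = dt, seed = as.integer(seed),
                 max_extend = max_extend, act_check = act_check,
                 refine = refine),
            class = "mcmc_control")
}
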