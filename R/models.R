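#' Tumor growth model specification
#'
#' The four nested tumor-volume models share one equation,
#' \deqn{dN/dt = r N (1 - N/K) - N \sum_i \alpha_i e^{-\beta (t - \tau_i)} H(t - \tau_i),}
#' where \eqn{N(t)} is tumor volume (mm^3), \eqn{r} the proliferation rate
#' (per day), \eqn{K} the carrying capacity (mm^3), \eqn{\alpha_i} the death
#' rate due to the i-th dose interval (per day), \eqn{\beta} the decay rate of
#' the treatment effect (per day), \eqn{\tau_i} the dose-interval start times,
#' and \eqn{H} the Heaviside step with \eqn{H(0) = 1} (a dose is active from
#' its start time inclusive). Each named model is a constrained special case:
#'
#' \describe{
#'   \item{`"logistic"`}{all \eqn{\alpha_i = 0}, \eqn{\beta = 0} (untreated growth).}
#'   \item{`"linear"`}{\eqn{\beta = 0}, \eqn{\alpha_1 = \alpha_2 = \alpha}
#'     (constant treatment effect).}
#'   \item{`"expdecay"`}{\eqn{\alpha_1 = \alpha_2 = \alpha}, \eqn{\beta} free
#'     (decaying treatment effect).}
#'   \item{`"cumulative"`}{\eqn{\beta = 0}, \eqn{\alpha_1}, \eqn{\alpha_2} free
#'     (dose-specific treatment effect).}
#' }
#'
#' @param name one of `"logistic"`, `"linear"`, `"expdecay"`, `"cumulative"`.
#' @return an object of class `"model_spec"`.
#' @seealso [tumor_params()], [simulate_tumor()], [tumor_fit()]
#' @export
model_spec <- function(name = c("logistic", "linear", "expdecay", "cumulative")) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      treated = name != "logistic",
      beta_free = name == "expdecay",
      alpha_shared = name %in% c("linear", "expdecay")
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  lab <- c(
    logistic = "logistic growth (untreated; alpha_i = 0, beta = 0)",
    linear = "linear treatment (beta = 0, alpha_1 = alpha_2)",
    expdecay = "exponential-decay treatment (alpha_1 = alpha_2, beta free)",
    cumulative = "cumulative two-dose treatment (beta = 0, alpha_1 != alpha_2)"
  )
  cat("<model_spec>", unname(lab[x$name]), "\n")
  invisible(x)
}

#' Treatment dosing schedule
#'
#' Dose intervals start at times `taus` (days). The default schedule places
#' the two treatment administration intervals at days 0 and 7, matching tumor
#' volume measurements at days 0, 7, and 14 with a 7-day inter-dose interval.
#'
#' @param taus strictly increasing dose-interval start times, in days.
#' @param delta_t inter-dose interval in days (used by the sensitivity-analysis
#'   alpha adjustment); defaults to the spacing of `taus` when uniform.
#' @return an object of class `"treatment_course"` with fields `taus`,
#'   `n_doses`, `delta_t`.
#' @export
treatment_course <- function(taus = c(0, 7), delta_t = NULL) {
  stopifnot(is.numeric(taus), length(taus) >= 1, all(is.finite(taus)))
  if (is.unsorted(taus, strictly = TRUE))
    stop("dose-interval start times `taus` must be strictly increasing")
  if (is.null(delta_t)) {
    delta_t <- if (length(taus) >= 2) taus[2] - taus[1] else 7
  }
  stopifnot(delta_t > 0)
  structure(
    list(taus = as.numeric(taus), n_doses = length(taus), delta_t = delta_t),
    class = "treatment_course"
  )
}

#' Model parameter set
#'
#' Holds the parameters of the general treatment model. `alpha` may be a
#' scalar (recycled over dose intervals, as in the linear and
#' exponential-decay models) or a vector of per-dose death rates
#' (the cumulative model).
#'
#' @param r proliferation rate, per day (> 0).
#' @param K carrying capacity, mm^3 (> 0).
#' @param N0 initial tumor volume, mm^3 (>= 0).
#' @param alpha per-dose death rate(s), per day (>= 0).
#' @param beta treatment-effect decay rate, per day (>= 0).
#' @param sigma measurement-noise standard deviation, mm^3 (> 0); only used by
#'   likelihood computations and noisy simulation, not by the ODE itself.
#' @param n_doses number of dose intervals to recycle a scalar `alpha` over.
#' @return an object of class `"tumor_params"`.
#' @export
tumor_params <- function(r, K, N0, alpha = 0, beta = 0, sigma = 1, n_doses = NULL) {
  if (!is.null(n_doses) && length(alpha) == 1L) alpha <- rep(alpha, n_doses)
  stopifnot(
    is.numeric(r), length(r) == 1, r > 0,
    is.numeric(K), length(K) == 1, K > 0,
    is.numeric(N0), length(N0) == 1, N0 >= 0,
    is.numeric(alpha), all(alpha >= 0),
    is.numeric(beta), length(beta) == 1, beta >= 0,
    is.numeric(sigma), length(sigma) == 1, sigma > 0
  )
  structure(
    list(r = r, K = K, N0 = N0, alpha = as.numeric(alpha),
         beta = beta, sigma = sigma),
    class = "tumor_params"
  )
}

check_params_spec <- function(params, spec) {
  if (spec$name == "logistic" &&
      (any(params$alpha != 0) || params$beta != 0))
    stop("logistic model requires alpha_i = 0 and beta = 0")
  if (spec$alpha_shared && length(unique(params$alpha)) > 1)
    stop(sprintf("%s model requires a single shared alpha", spec$name))
  if (!spec$beta_free && params$beta != 0)
    stop(sprintf("%s model requires beta = 0", spec$name))
  invisible(TRUE)
}

#' Per-day treatment death rate at time t
#'
#' Evaluates the treatment hazard
#' \eqn{\sum_i \alpha_i e^{-\beta (t - \tau_i)} H(t - \tau_i)} with
#' \eqn{H(0) = 1}: a dose contributes from its start time inclusive. With
#' \eqn{\beta = 0} this reduces to a step-sum of the active \eqn{\alpha_i}.
#'
#' @param t time(s), days; vectorized.
#' @param params a [tumor_params()] object.
#' @param course a [treatment_course()] object.
#' @param spec optional [model_spec()]; when given, `params` is validated
#'   against the model's constraints.
#' @return per-day death rate, same length as `t`.
#' @export
treatment_hazard <- function(t, params, course = treatment_course(), spec = NULL) {
  stopifnot(inherits(params, "tumor_params"), inherits(course, "treatment_course"))
  if (!is.null(spec)) check_params_spec(params, spec)
  alpha <- params$alpha
  if (length(alpha) == 1L) alpha <- rep(alpha, course$n_doses)
  if (length(alpha) != course$n_doses)
    stop(sprintf("length(alpha) = %d does not match n_doses = %d",
                 length(alpha), course$n_doses))
  stopifnot(all(is.finite(t)))
  out <- numeric(length(t))
  for (i in seq_len(course$n_doses)) {
    active <- t >= course$taus[i]
    out[active] <- out[active] +
      alpha[i] * exp(-params$beta * (t[active] - course$taus[i]))
  }
  out
}

# Vectorized fixed-step RK4 over many parameter sets at once.
#
# r, K, N0, beta: numeric vectors (length m); alpha: m x n_doses matrix.
# Integration restarts exactly at each dose time so no step straddles the
# hazard discontinuity. Within a segment starting at a breakpoint, the active
# hazard is C * exp(-beta * t) with C = sum_active alpha_i * exp(beta * tau_i),
# which covers beta = 0 (constant step-sum) and beta > 0 uniformly.
# Volumes are clipped at 0 (absorbing) if a step undershoots.
#
# Returns an m x length(times) matrix of volumes.
rk4_paths <- function(times, r, K, N0, alpha, beta, taus, dt = 0.01) {
  m <- length(r)
  stopifnot(length(K) == m, length(N0) == m, length(beta) == m)
  alpha <- as.matrix(alpha)
  if (nrow(alpha) == 1L && m > 1L)
    alpha <- matrix(alpha, m, ncol(alpha), byrow = TRUE)
  stopifnot(nrow(alpha) == m, ncol(alpha) == length(taus))
  stopifnot(all(is.finite(times)), !is.unsorted(times, strictly = TRUE))
  if (times[1] < 0) stop("output times must start at day 0 or later")
  stopifnot(dt > 0, all(K > 0))

  t_end <- times[length(times)]
  breaks <- sort(unique(c(0, taus[taus > 0 & taus < t_end], times)))
  out <- matrix(NA_real_, m, length(times))
  N <- pmax(N0, 0)
  if (breaks[1] == 0 && any(times == 0)) out[, which(times == 0)] <- N

  for (s in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1L]
    active <- which(taus <= t0)
    if (length(active)) {
      # per-row: C = sum_i alpha_i * exp(beta * tau_i) over active doses
      C <- rowSums(alpha[, active, drop = FALSE] *
                     exp(outer(beta, taus[active])))
    } else {
      C <- numeric(m)
    }
    nstep <- max(1L, ceiling((t1 - t0) / dt))
    h <- (t1 - t0) / nstep
    tcur <- t0
    for (k in seq_len(nstep)) {
      haz1 <- C * exp(-beta * tcur)
      hazm <- C * exp(-beta * (tcur + h / 2))
      haz2 <- C * exp(-beta * (tcur + h))
      k1 <- r * N * (1 - N / K) - N * haz1
      N2 <- N + h / 2 * k1
      k2 <- r * N2 * (1 - N2 / K) - N2 * hazm
      N3 <- N + h / 2 * k2
      k3 <- r * N3 * (1 - N3 / K) - N3 * hazm
      N4 <- N + h * k3
      k4 <- r * N4 * (1 - N4 / K) - N4 * haz2
      N <- N + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      N[N < 0] <- 0
      tcur <- tcur + h
    }
    if (any(!is.finite(N))) {
      bad <- which(!is.finite(N))[1]
      stop(sprintf(
        "non-finite tumor volume during integration (set %d: r=%g, K=%g, N0=%g)",
        bad, r[bad], K[bad], N0[bad]))
    }
    hit <- which(times == t1)
    if (length(hit)) out[, hit] <- N
  }
  # times strictly between breaks cannot occur (all output times are breaks)
  out
}

#' Simulate a tumor-volume trajectory
#'
#' Solves the growth model by fixed-step fourth-order Runge-Kutta
#' (default step 0.01 days), restarting integration exactly at each dose time
#' so no step straddles the hazard discontinuity. Volumes are clipped at 0,
#' which is an absorbing state. Deterministic given its inputs.
#'
#' @param spec a [model_spec()].
#' @param params a [tumor_params()]; validated against `spec`.
#' @param course a [treatment_course()].
#' @param times strictly increasing output times in days, starting at day 0.
#' @param dt RK4 step size, days.
#' @return a data frame of class `"tumor_trajectory"` with columns `time`
#'   (days) and `volume` (mm^3).
#' @examples
#' spec <- model_spec("linear")
#' p <- tumor_params(r = 0.15, K = 1500, N0 = 100, alpha = 0.2, n_doses = 2)
#' simulate_tumor(spec, p, treatment_course(), times = c(0, 7, 14))
#' @export
simulate_tumor <- function(spec, params, course = treatment_course(),
                           times = c(0, 7, 14), dt = 0.01) {
  stopifnot(inherits(spec, "model_spec"), inherits(params, "tumor_params"))
  check_params_spec(params, spec)
  alpha <- params$alpha
  if (length(alpha) == 1L) alpha <- rep(alpha, course$n_doses)
  if (length(alpha) != course$n_doses)
    stop(sprintf("length(alpha) = %d does not match n_doses = %d",
                 length(alpha), course$n_doses))
  v <- rk4_paths(times, params$r, params$K, params$N0,
                 matrix(alpha, 1), params$beta, course$taus, dt = dt)
  structure(data.frame(time = times, volume = drop(v)),
            class = c("tumor_trajectory", "data.frame"))
}
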