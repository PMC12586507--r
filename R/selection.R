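#' Bayesian Information Criterion
#'
#' `BIC = Z ln(n) - 2 ln L^`, where `Z` is the number of parameters
#' estimated, `n` the number of observed values, and `ln L^` the maximum of
#' the log-likelihood. Lower is better. Under the per-protocol aggregation
#' used here, `n` is the total number of measurements across an arm's mice
#' and `Z` the total number of sampled parameters for that arm's fit
#' (mouse-level blocks, their noise terms, and a shared `beta` when present).
#'
#' @param lnL_hat maximum log-likelihood.
#' @param Z number of estimated parameters (>= 0).
#' @param n_obs number of observed values (>= 1).
#' @return scalar BIC.
#' @export
bic <- function(lnL_hat, Z, n_obs) {
  stopifnot(is.numeric(lnL_hat), is.numeric(Z), Z >= 0)
  if (!is.numeric(n_obs) || n_obs < 1) stop("n_obs must be >= 1")
  Z * log(n_obs) - 2 * lnL_hat
}

#' Score a fitted model for selection
#'
#' @param fit a `"tumor_fit"`.
#' @return a one-row data frame (`model`, `lnL_hat`, `Z`, `n_obs`, `bic`)
#'   of class `"model_score"`.
#' @export
model_score <- function(fit) {
  stopifnot(inherits(fit, "tumor_fit"))
  structure(data.frame(model = fit$model, lnL_hat = fit$lnL_hat, Z = fit$Z,
                       n_obs = fit$n_obs,
                       bic = bic(fit$lnL_hat, fit$Z, fit$n_obs),
                       stringsAsFactors = FALSE),
            class = c("model_score", "data.frame"))
}

#' Select the model with the lowest BIC
#'
#' Candidates must be scored on the same data (equal `n_obs`); ties are
#' broken toward the model with fewer parameters.
#'
#' @param scores a data frame of model scores (rows from [model_score()] or
#'   a hand-built table with columns `model`, `bic`, `Z`, `n_obs`), or a list
#'   of `"tumor_fit"` objects.
#' @return the selected model name (character).
#' @export
select_model <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores) &&
      all(vapply(scores, inherits, TRUE, "tumor_fit")))
    scores <- do.call(rbind, lapply(scores, model_score))
  stopifnot(is.data.frame(scores), nrow(scores) >= 2,
            all(c("model", "bic", "Z") %in% names(scores)))
  if ("n_obs" %in% names(scores) && length(unique(scores$n_obs)) > 1)
    stop("model scores computed on different n_obs are not comparable")
  ord <- order(scores$bic, scores$Z)
  scores$model[ord[1]]
}
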