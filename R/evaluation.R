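#' Agreement metrics between observed and predicted volumes
#'
#' Pearson correlation (PCC), Lin's concordance correlation coefficient
#' (CCC) computed with population (1/n) moments,
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' and the mean absolute percent error
#' \deqn{MAPE = \frac{100}{n} \sum_i |obs_i - pred_i| / obs_i.}
#' CCC penalizes scale and location shifts, so `CCC <= |PCC|`.
#'
#' @param observed observed volumes, mm^3 (> 0 for MAPE).
#' @param predicted predicted volumes, mm^3.
#' @return list of class `"metrics_report"`: `ccc`, `pcc`, `mape` (%), `n`.
#' @export
fit_quality <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  n <- length(observed)
  mx <- mean(observed); my <- mean(predicted)
  sx2 <- mean((observed - mx)^2)
  sy2 <- mean((predicted - my)^2)
  sxy <- mean((observed - mx) * (predicted - my))
  if (sx2 == 0 || sy2 == 0) {
    pcc <- NA_real_
    warning("zero variance in a vector: PCC undefined")
  } else {
    pcc <- sxy / sqrt(sx2 * sy2)
  }
  denom <- sx2 + sy2 + (mx - my)^2
  ccc <- if (denom == 0) NA_real_ else 2 * sxy / denom
  mape <- if (all(observed > 0)) 100 * mean(abs(observed - predicted) / observed)
          else NA_real_
  structure(list(ccc = ccc, pcc = pcc, mape = mape, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("CCC = %.4f   PCC = %.4f   MAPE = %.2f%%   (n = %d pairs)\n",
              x$ccc, x$pcc, x$mape, x$n))
  invisible(x)
}

#' Responder classification accuracy
#'
#' Accuracy is the number of correctly identified responders and
#' non-responders divided by the total number of mice, as a percentage,
#' with the confusion counts reported.
#'
#' @param truth true labels (`"responder"`/`"non-responder"` or logical).
#' @param predicted predicted labels, same encoding.
#' @return list: `accuracy` (%), `confusion` (2x2 table), `n`.
#' @export
responder_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1)
  to_lab <- function(x) {
    if (is.logical(x)) ifelse(x, "responder", "non-responder") else
      as.character(x)
  }
  truth <- factor(to_lab(truth), levels = c("responder", "non-responder"))
  predicted <- factor(to_lab(predicted),
                      levels = c("responder", "non-responder"))
  conf <- table(truth = truth, predicted = predicted)
  list(accuracy = 100 * sum(diag(conf)) / length(truth), confusion = conf,
       n = length(truth))
}

#' Two-group comparison by Mann-Whitney U with Bonferroni adjustment
#'
#' Two-tailed Mann-Whitney U (Wilcoxon rank-sum) test; exact for small
#' samples without ties, normal approximation with tie correction otherwise.
#' The Bonferroni-adjusted p-value `min(1, m p)` maintains the family-wise
#' 5% Type-I error over `m` comparisons.
#'
#' @param sample_a,sample_b the two samples.
#' @param m_comparisons number of comparisons in the family.
#' @return list: `U`, `p`, `p_adjusted`, `m`.
#' @export
compare_groups <- function(sample_a, sample_b, m_comparisons = 1) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1, m_comparisons >= 1)
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       p_adjusted = min(1, m_comparisons * wt$p.value), m = m_comparisons)
}

#' Paired t-test on start vs end volumes
#'
#' Standard paired two-tailed t-test on per-mouse volume differences, used
#' to demonstrate within-group growth (e.g. that untreated tumors grow).
#' Exactly constant differences make the statistic degenerate and raise an
#' error.
#'
#' @param v_start,v_end paired volumes, mm^3.
#' @return list: `t`, `df`, `p`.
#' @export
paired_growth_test <- function(v_start, v_end) {
  stopifnot(length(v_start) == length(v_end), length(v_start) >= 2)
  d <- v_end - v_start
  if (stats::var(d) == 0)
    stop("zero-variance paired differences: t statistic degenerate")
  tt <- stats::t.test(v_end, v_start, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Inter-individual variability of estimated parameters
#'
#' For each parameter, a one-way random-effects intra-class correlation
#' (mice as classes, posterior draws as repeated measures; between-mouse
#' variance over total variance, ICC(1,1) from the one-way ANOVA mean
#' squares) and the coefficient of variation of the per-mouse posterior
#' medians (sample s.d. over mean, the documented convention).
#'
#' @param draws_by_mouse list of per-mouse posterior draw matrices with
#'   identical column names (e.g. the `draws` field of a `"tumor_fit"`).
#' @return data frame with columns `parameter`, `icc`, `cv`.
#' @export
icc_cv <- function(draws_by_mouse) {
  stopifnot(is.list(draws_by_mouse), length(draws_by_mouse) >= 2)
  pn <- colnames(draws_by_mouse[[1]])
  out <- lapply(pn, function(p) {
    vals <- lapply(draws_by_mouse, function(d) d[, p])
    if (any(vapply(vals, length, 0L) < 2))
      stop("ICC requires >= 2 draws per mouse")
    y <- unlist(vals, use.names = FALSE)
    g <- factor(rep(seq_along(vals), vapply(vals, length, 0L)))
    if (stats::var(y) == 0) {
      warning(sprintf("parameter %s constant across mice and draws; ICC 0", p))
      icc <- 0
    } else {
      ms <- summary(stats::aov(y ~ g))[[1]]$`Mean Sq`
      k <- mean(tabulate(g))       # draws per class (balanced in practice)
      icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
      icc <- max(0, icc)
    }
    med <- vapply(vals, stats::median, 0)
    cv <- if (mean(med) == 0) NA_real_ else stats::sd(med) / mean(med)
    data.frame(parameter = p, icc = icc, cv = cv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate a set of predictions against observed outcomes
#'
#' Pools a list of per-mouse predictions from one scheme, compares the
#' day-14 point predictions with the observed day-14 volumes (CCC, PCC,
#' MAPE) and the responder calls with the observed labels (day-14 vs day-0).
#'
#' @param predictions list of `"tumor_prediction"` objects.
#' @return list: `metrics` (a `"metrics_report"`), `accuracy`, `confusion`,
#'   `table` (per-mouse data frame).
#' @export
prediction_metrics <- function(predictions) {
  stopifnot(length(predictions) >= 2,
            all(vapply(predictions, inherits, TRUE, "tumor_prediction")))
  tab <- do.call(rbind, lapply(predictions, function(p) {
    data.frame(mouse_id = p$mouse_id, scheme = p$scheme,
               predicted = unname(p$point[as.character(14)]),
               observed = unname(p$observed[["14"]]),
               day0 = unname(p$observed[["0"]]),
               call = p$responder_call, stringsAsFactors = FALSE)
  }))
  if (any(is.na(tab$observed)))
    stop("observed day-14 volumes required to evaluate predictions")
  truth <- classify_responder(tab$day0, tab$observed)
  acc <- responder_accuracy(truth, tab$call)
  list(metrics = fit_quality(tab$observed, tab$predicted),
       accuracy = acc$accuracy, confusion = acc$confusion, table = tab)
}
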