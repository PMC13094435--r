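# Failure-rate statistics: Wilson score intervals, two-proportion z-tests
# with Holm correction, TOST equivalence tests for proportions, and OLS
# trade-off slopes.

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval: center (p + z^2/2n) / (1 + z^2/n),
#' half-width z sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n), with z the
#' two-sided normal quantile for the requested confidence (taken at full
#' double precision, not rounded to 1.96).
#'
#' @param failures number of events (0 <= failures <= n).
#' @param n number of trials (>= 1).
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return named numeric `c(lower, upper)`, a subset of [0, 1] containing
#'   the observed proportion.
#' @export
wilson_ci <- function(failures, n, confidence = 0.95) {
  if (n < 1 || failures < 0 || failures > n) stop("invalid counts")
  if (confidence <= 0 || confidence >= 1) stop("invalid confidence level")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- failures / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # at the boundaries the score interval touches 0/1 exactly
  lower <- if (failures == 0) 0 else max(0, center - half)
  upper <- if (failures == n) 1 else min(1, center + half)
  c(lower = lower, upper = upper)
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' @param x1,n1 events and trials in group 1.
#' @param x2,n2 events and trials in group 2.
#' @return list with `z` and two-sided `p`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (min(n1, n2) < 1 || x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("invalid counts")
  }
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    stop("degenerate comparison: pooled proportion is 0 or 1")
  }
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Holm step-down adjustment of p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`; validates the
#' inputs and preserves names.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1) || any(!is.finite(p))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

#' TOST equivalence test for two proportions
#'
#' Two one-sided z-tests of H0: p1 - p2 <= -delta and H0: p1 - p2 >= delta
#' with the unpooled standard error; equivalence is concluded when both
#' one-sided p-values fall below alpha.
#'
#' @param x1,n1,x2,n2 counts.
#' @param delta equivalence margin on the proportion scale (> 0).
#' @param alpha one-sided significance level (default 0.05).
#' @return list with `p_lower`, `p_upper`, `equivalent`.
#' @export
tost_equivalence <- function(x1, n1, x2, n2, delta = 0.10, alpha = 0.05) {
  if (delta <= 0) stop("delta must be > 0")
  if (min(n1, n2) < 1 || x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("invalid counts")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se == 0) stop("degenerate variance: both proportions are 0 or 1")
  diff <- p1 - p2
  z_lower <- (diff + delta) / se   # H0: diff <= -delta
  z_upper <- (diff - delta) / se   # H0: diff >= +delta
  p_lower <- stats::pnorm(-z_lower)
  p_upper <- stats::pnorm(z_upper)
  list(p_lower = p_lower, p_upper = p_upper,
       equivalent = p_lower < alpha && p_upper < alpha)
}

#' Failure counts per robustness setting and criterion
#'
#' Aggregates the per-evaluation coverage flags (one row per patient x
#' setting x rCT) into a failure table: evaluations and failures per
#' (setting, criterion).
#'
#' @param flags data.frame with columns `setting`, `pri_D98_pass`,
#'   `pro_D98_pass`, `pri_D2_pass` (one row per rCT evaluation).
#' @return data.frame with `setting`, `criterion`, `n_evaluations`,
#'   `n_failures`, `rate`.
#' @export
failure_rates <- function(flags) {
  need <- c("setting", "pri_D98_pass", "pro_D98_pass", "pri_D2_pass")
  if (!all(need %in% names(flags))) {
    stop("flags must contain columns: ", paste(need, collapse = ", "))
  }
  crit <- c(pri_D98 = "pri_D98_pass", pro_D98 = "pro_D98_pass",
            pri_D2 = "pri_D2_pass")
  out <- do.call(rbind, lapply(unique(flags$setting), function(s) {
    sub <- flags[flags$setting == s, , drop = FALSE]
    do.call(rbind, lapply(names(crit), function(cn) {
      data.frame(setting = s, criterion = cn,
                 n_evaluations = nrow(sub),
                 n_failures = sum(!sub[[crit[cn]]]))
    }))
  }))
  out$rate <- out$n_failures / out$n_evaluations
  rownames(out) <- NULL
  out
}

#' Ordinary-least-squares trend slope
#'
#' @param xs predictor values (at least two distinct).
#' @param ys response values.
#' @return list with `slope`, `intercept`, `slope_se`.
#' @export
trend_slope <- function(xs, ys) {
  if (length(unique(xs)) < 2) stop("need at least two distinct x values")
  fit <- stats::lm(ys ~ xs)
  cf <- stats::coef(fit)
  # collinear input is legitimate here (e.g. three settings on a line),
  # so the perfect-fit warning from summary.lm is suppressed
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["xs"]])
  if (!is.finite(se)) se <- 0  # exact fit with zero residual df
  list(slope = unname(cf[["xs"]]), intercept = unname(cf[["(Intercept)"]]),
       slope_se = se)
}
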