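# Piecewise-constant baseline hazard on four age intervals and the
# excess-hazard-ratio (EHR) survival likelihood, in both its clustered form
# h_i(t) = h0(t) (1 + beta_{C_i}) and its regression form
# h_i(t) = h0(t) (1 + sum_k beta_k x_ik).
#
# All internal time arithmetic is in days; interval cutpoints are given in
# years of age and converted once.

#' Days per year used for all age conversions
#'
#' @export
YEAR_DAYS <- 365.25

#' Piecewise-constant baseline hazard
#'
#' Constructs the baseline hazard \eqn{h_0(t)} of the excess hazard ratio
#' disease sub-model: constant rates \eqn{\lambda_1,\ldots,\lambda_4} (events
#' per day) on the four age intervals delimited by 40, 55 and 70 years of age.
#' Intervals are half-open `[lower, upper)` in days, so an age exactly at a
#' cutpoint belongs to the older interval.
#'
#' @param rates numeric vector of four positive rates (events/day), youngest
#'   interval first.
#' @param cutpoints_years strictly increasing interior cutpoints in years of
#'   age; default `c(40, 55, 70)`.
#' @return An object of class `baseline_hazard` with elements `rates`,
#'   `cut_days` (interior cutpoints in days) and `lower`/`upper` interval
#'   bounds in days.
#' @examples
#' hz <- baseline_hazard(c(5e-8, 1.4e-6, 5.5e-6, 9.3e-6))
#' cum_base_hazard(hz, 0, 40 * YEAR_DAYS)
#' @export
baseline_hazard <- function(rates, cutpoints_years = c(40, 55, 70)) {
  if (length(rates) != length(cutpoints_years) + 1L)
    stop("need one rate per age interval")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("baseline hazard rates must be positive")
  if (is.unsorted(cutpoints_years, strictly = TRUE))
    stop("cutpoints must be strictly increasing")
  cut_days <- cutpoints_years * YEAR_DAYS
  structure(
    list(rates = as.numeric(rates),
         cut_days = cut_days,
         lower = c(0, cut_days),
         upper = c(cut_days, Inf)),
    class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat("Piecewise-constant baseline hazard (events/day)\n")
  lab <- sprintf("[%s, %s)", format(x$lower / YEAR_DAYS),
                 format(x$upper / YEAR_DAYS))
  print(stats::setNames(x$rates, lab))
  invisible(x)
}

#' Age-interval index of a time point
#'
#' @param t_days age(s) in days.
#' @param hazard a [baseline_hazard()].
#' @return integer interval indices in `1:4`.
#' @export
age_interval <- function(t_days, hazard) {
  findInterval(t_days, hazard$cut_days) + 1L
}

#' Cumulative baseline hazard over an age window
#'
#' \eqn{H_0(t_1, t_2) = \int_{t_1}^{t_2} h_0(u)\,du}, the sum over intervals of
#' rate times overlap. Vectorized over `t_entry`/`t_exit`.
#'
#' @param hazard a [baseline_hazard()].
#' @param t_entry,t_exit window bounds in days, `0 <= t_entry <= t_exit`.
#' @return nonnegative numeric vector.
#' @export
cum_base_hazard <- function(hazard, t_entry, t_exit) {
  if (any(t_exit < t_entry)) stop("t_exit must be >= t_entry")
  if (any(t_entry < 0)) stop("t_entry must be nonnegative")
  drop(person_time(hazard, t_entry, t_exit) %*% hazard$rates)
}

#' Person-time spent in each baseline-hazard age interval
#'
#' @inheritParams cum_base_hazard
#' @return numeric matrix, one row per window, one column per age interval
#'   (days of overlap).
#' @export
person_time <- function(hazard, t_entry, t_exit) {
  n <- max(length(t_entry), length(t_exit))
  t_entry <- rep_len(t_entry, n)
  t_exit <- rep_len(t_exit, n)
  k <- length(hazard$rates)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    out[, j] <- pmax(0, pmin(t_exit, hazard$upper[j]) -
                        pmax(t_entry, hazard$lower[j]))
  }
  out
}

#' Clustered EHR log-likelihood of survival records
#'
#' Censored-data log-likelihood under \eqn{h_i(t) = h_0(t)(1+\beta)} with
#' delayed entry (left truncation): person-time accrues from `entry` only.
#' For an event, contributes
#' \eqn{\log\{\lambda_{j(y)}(1+\beta)\} - (1+\beta) H_0(entry, y)}; for a
#' censored record the first term is dropped.
#'
#' @param y event/censoring age in days.
#' @param delta 0/1 event indicator.
#' @param entry entry age in days (`entry < y`).
#' @param beta cluster excess hazard ratio, `beta > -1` (scalar or per-record).
#' @param hazard a [baseline_hazard()].
#' @param truncate logical; if `FALSE`, person-time accrues from age 0
#'   (no left truncation).
#' @return numeric vector of per-record log-likelihood contributions.
#' @export
surv_loglik_cluster <- function(y, delta, entry, beta, hazard,
                                truncate = TRUE) {
  if (any(beta <= -1)) stop("beta must exceed -1")
  surv_loglik_mult(y, delta, entry, 1 + beta, hazard, truncate)
}

#' Regression EHR log-likelihood of survival records
#'
#' Censored-data log-likelihood under the no-clustering form
#' \eqn{h_i(t) = h_0(t)(1 + \beta^\top x_i)} with scaled exposures `x`.
#'
#' @param y,delta,entry,hazard,truncate as in [surv_loglik_cluster()].
#' @param x numeric matrix of (scaled) exposures, one row per record.
#' @param coefs numeric coefficient vector, one per column of `x`.
#' @return numeric vector of per-record log-likelihoods; an error is raised if
#'   any record's multiplier \eqn{1 + \beta^\top x_i} is nonpositive (the
#'   parameter point is inadmissible and must be rejected by the sampler).
#' @export
surv_loglik_reg <- function(y, delta, entry, x, coefs, hazard,
                            truncate = TRUE) {
  x <- as.matrix(x)
  mult <- 1 + drop(x %*% coefs)
  if (any(mult <= 0))
    stop("inadmissible coefficients: hazard multiplier <= 0 for some record")
  surv_loglik_mult(y, delta, entry, mult, hazard, truncate)
}

# Shared kernel: hazard multiplier form. mult must be positive.
surv_loglik_mult <- function(y, delta, entry, mult, hazard, truncate = TRUE) {
  if (any(y <= entry)) stop("y must exceed entry age")
  if (!all(delta %in% c(0, 1))) stop("delta must be 0/1")
  t0 <- if (truncate) entry else 0
  H <- cum_base_hazard(hazard, t0, y)
  lam_y <- hazard$rates[age_interval(y, hazard)]
  delta * (log(lam_y) + log(mult)) - mult * H
}
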