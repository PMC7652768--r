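# Exposure sub-model densities, truncated stick-breaking attribution
# sub-model, joint posterior density and allocation full conditionals.
#
# A mixture_state bundles everything the sampler iterates over: stick
# fractions V and implied weights phi, concentration alpha, per-component
# parameters (excess hazard ratio beta; lognormal location/scale for radon,
# gamma, dust and age at first exposure; category probabilities for job,
# mine and duration class), the four baseline rates, and the allocation of
# each exposed subject. Never-exposed subjects carry the reserved label 0
# with beta identically 0 and sit outside the mixture.

#' Stick-breaking construction of mixture weights
#'
#' Maps Beta stick fractions \eqn{V_1,\ldots,V_{C-1}} to mixture weights:
#' \eqn{\phi_c = V_c \prod_{k<c}(1-V_k)} and the final weight takes the
#' remaining stick, \eqn{\phi_C = 1 - \sum_{k<C} \phi_k}.
#'
#' @param V numeric vector of stick fractions in `[0, 1]`.
#' @return probability vector of length `length(V) + 1`.
#' @examples
#' stick_breaking(c(0.5, 0.5))  # 0.5, 0.25, 0.25
#' @export
stick_breaking <- function(V) {
  if (length(V) && (any(!is.finite(V)) || any(V < 0) || any(V > 1)))
    stop("stick fractions must lie in [0, 1]")
  if (!length(V)) return(1)
  rest <- cumprod(1 - V)
  phi <- c(V * c(1, rest[-length(rest)]), rest[length(rest)])
  phi[phi < 0] <- 0
  phi
}

#' Per-cluster exposure-profile log-likelihood
#'
#' Log-density of an exposed subject's covariate profile under one cluster's
#' exposure sub-model: lognormal terms for the three cumulative exposures and
#' age at first exposure plus categorical log-probabilities for job type,
#' mine group and duration class.
#'
#' @param cohort a `miner_cohort` (or conforming data.frame); all rows must
#'   be exposed (positive exposures) — zero exposures belong to the reference
#'   cluster and are an error here.
#' @param params list with `mu` and `sigma` (length-4, order radon, gamma,
#'   dust, age), `p_job` (5), `p_mine` (2), `p_dur` (4).
#' @return numeric vector of per-row log-likelihoods.
#' @export
exposure_loglik <- function(cohort, params) {
  x <- cbind(cohort$x_radon, cohort$x_gamma, cohort$x_dust,
             cohort$age_first_exposure)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("exposure_loglik applies to exposed subjects only; ",
         "route zero-exposure rows to the reference cluster")
  ll <- numeric(nrow(x))
  for (v in 1:4)
    ll <- ll + stats::dlnorm(x[, v], params$mu[v], params$sigma[v], log = TRUE)
  ll + log(params$p_job[cohort$job]) + log(params$p_mine[cohort$mine]) +
    log(params$p_dur[cohort$duration_class])
}

#' Construct a mixture state
#'
#' @param V stick fractions (length `C_max - 1`).
#' @param alpha stick-breaking concentration.
#' @param beta per-component excess hazard ratios (length `C_max`).
#' @param mu,sigma `C_max x 4` lognormal locations/scales (radon, gamma,
#'   dust, age).
#' @param p_job,p_mine,p_dur per-component category probabilities
#'   (`C_max x 5`, `C_max x 2`, `C_max x 4`).
#' @param lambda four baseline rates (events/day).
#' @param alloc integer allocations of the exposed subjects, in `1:C_max`.
#' @param hazard optional [baseline_hazard()] carrying the age cutpoints;
#'   defaults to `baseline_hazard(lambda)`.
#' @return an object of class `mixture_state` (with `phi` derived from `V`).
#' @export
mixture_state <- function(V, alpha, beta, mu, sigma, p_job, p_mine, p_dur,
                          lambda, alloc, hazard = NULL) {
  C_max <- length(beta)
  mu <- as.matrix(mu); sigma <- as.matrix(sigma)
  p_job <- as.matrix(p_job); p_mine <- as.matrix(p_mine)
  p_dur <- as.matrix(p_dur)
  stopifnot(length(V) == C_max - 1L,
            nrow(mu) == C_max, ncol(mu) == 4L,
            nrow(sigma) == C_max, ncol(sigma) == 4L,
            nrow(p_job) == C_max, ncol(p_job) == 5L,
            nrow(p_mine) == C_max, ncol(p_mine) == 2L,
            nrow(p_dur) == C_max, ncol(p_dur) == 4L,
            length(lambda) == 4L,
            all(alloc >= 1L), all(alloc <= C_max))
  if (is.null(hazard)) hazard <- baseline_hazard(lambda)
  structure(
    list(C_max = C_max, V = V, phi = stick_breaking(V), alpha = alpha,
         beta = beta, mu = mu, sigma = sigma,
         p_job = p_job, p_mine = p_mine, p_dur = p_dur,
         lambda = lambda, alloc = as.integer(alloc), hazard = hazard),
    class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  occ <- tabulate(x$alloc, x$C_max)
  cat(sprintf("mixture_state: C_max = %d, %d exposed subjects, %d non-empty components\n",
              x$C_max, length(x$alloc), sum(occ > 0)))
  cat("  phi:", paste(format(round(x$phi, 3)), collapse = " "), "\n")
  invisible(x)
}

# Internal: precompute cohort quantities used repeatedly by the likelihoods.
# zero_policy "halfmin" replaces zero components of partially exposed rows by
# half the smallest positive observed value of that exposure; "reference"
# routes such rows to the reference cluster instead.
prep_data <- function(cohort, hazard, truncate = TRUE,
                      zero_policy = c("halfmin", "reference")) {
  zero_policy <- match.arg(zero_policy)
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  xm <- cbind(radon = cohort$x_radon, gamma = cohort$x_gamma,
              dust = cohort$x_dust)
  any_pos <- rowSums(xm > 0) > 0
  all_pos <- rowSums(xm > 0) == 3L
  exposed <- if (zero_policy == "reference") all_pos else any_pos
  if (zero_policy == "halfmin" && any(exposed & !all_pos)) {
    for (v in 1:3) {
      z <- exposed & xm[, v] == 0
      if (any(z)) xm[z, v] <- min(xm[xm[, v] > 0, v]) / 2
    }
  }
  eidx <- which(exposed)
  lx <- cbind(log(xm[eidx, , drop = FALSE]),
              age = log(cohort$age_first_exposure[eidx]))
  entry <- cohort$entry_age
  t0 <- if (truncate) entry else numeric(n)
  list(n = n, y = cohort$y, delta = cohort$delta, entry = entry,
       eidx = eidx, n_e = length(eidx),
       lx = lx, lx2 = lx^2,
       job = cohort$job[eidx], mine = cohort$mine[eidx],
       dur = cohort$duration_class[eidx],
       E = person_time(hazard, t0, cohort$y),
       j_y = age_interval(cohort$y, hazard),
       delta_e = cohort$delta[eidx],
       truncate = truncate)
}

# Internal: n_e x C matrix of exposure-profile log-likelihoods, dropping
# per-subject constants that cancel across components when requested.
exposure_ll_matrix <- function(pd, state, full = TRUE) {
  inv2s2 <- 1 / (2 * state$sigma^2)            # C x 4
  # -(lx - mu)^2 / (2 sigma^2) - log sigma, summed over the 4 variables
  W <- -pd$lx2 %*% t(inv2s2) + pd$lx %*% t(2 * state$mu * inv2s2) -
    matrix(rowSums(state$mu^2 * inv2s2 + log(state$sigma)),
           pd$n_e, state$C_max, byrow = TRUE)
  W <- W + t(log(state$p_job))[pd$job, , drop = FALSE] +
    t(log(state$p_mine))[pd$mine, , drop = FALSE] +
    t(log(state$p_dur))[pd$dur, , drop = FALSE]
  if (full)
    W <- W - (rowSums(pd$lx) + 4 * log(2 * pi) / 2)  # lognormal constants
  W
}

# Internal: n_e x C matrix of survival log-likelihoods under each component's
# beta (constants that do not involve beta are included when full = TRUE).
survival_ll_matrix <- function(pd, state, full = TRUE) {
  H0 <- drop(pd$E %*% state$lambda)
  He <- H0[pd$eidx]
  W <- outer(pd$delta_e, log1p(pmax(state$beta, -1))) - outer(He, state$beta)
  W[, state$beta <= -1] <- -Inf  # inadmissible component for every record
  if (full) {
    lam_y <- state$lambda[pd$j_y[pd$eidx]]
    W <- W + (pd$delta_e * log(lam_y) - He)
  }
  W
}

#' Allocation full-conditional probabilities
#'
#' For every exposed subject, the probability of each mixture component:
#' proportional to \eqn{\phi_c} times the exposure-profile likelihood times
#' the survival likelihood under \eqn{\beta_c}, normalized by log-sum-exp.
#'
#' @param state a [mixture_state()].
#' @param cohort a `miner_cohort`.
#' @param truncate left-truncate survival at entry age (default `TRUE`).
#' @return matrix (exposed subjects x components) of probabilities; rows sum
#'   to 1.
#' @export
allocation_probs <- function(state, cohort, truncate = TRUE) {
  pd <- prep_data(cohort, state$hazard, truncate)
  W <- matrix(log(state$phi), pd$n_e, state$C_max, byrow = TRUE) +
    exposure_ll_matrix(pd, state, full = FALSE) +
    survival_ll_matrix(pd, state, full = FALSE)
  mx <- apply(W, 1, max)
  if (any(!is.finite(mx)))
    stop("all components inadmissible for some record")
  P <- exp(W - mx)
  P / rowSums(P)
}

#' Joint log-posterior density of a mixture state
#'
#' Sum of the survival log-likelihood of all subjects (reference subjects at
#' `beta = 0`), the exposure-profile log-likelihood of exposed subjects, the
#' allocation log-probabilities \eqn{\log \phi_{C_i}}, the Beta(1, alpha)
#' log-densities of the stick fractions, and all prior log-densities.
#' Inadmissible states (`beta <= -1`, scales or concentration outside their
#' uniform bounds, zero weight with occupants) return `-Inf` rather than
#' erroring, so the value can be used directly in Metropolis ratios.
#'
#' @param state a [mixture_state()].
#' @param cohort a `miner_cohort`.
#' @param prior a [prior_spec()].
#' @param truncate left-truncate survival at entry age (default `TRUE`).
#' @return scalar log-density (up to a constant), possibly `-Inf`.
#' @export
log_joint <- function(state, cohort, prior, truncate = TRUE) {
  pd <- prep_data(cohort, state$hazard, truncate)
  if (length(state$alloc) != pd$n_e)
    stop("allocation vector does not match the number of exposed subjects")
  sb <- prior$sigma_bounds; ab <- prior$alpha_bounds
  if (any(state$beta <= -1) || any(state$lambda <= 0) ||
      any(state$sigma <= sb[1]) || any(state$sigma >= sb[2]) ||
      state$alpha < ab[1] || state$alpha > ab[2] ||
      any(state$V < 0) || any(state$V > 1))
    return(-Inf)
  occ <- tabulate(state$alloc, state$C_max)
  if (any(occ > 0 & state$phi <= 0)) return(-Inf)

  beta_i <- numeric(pd$n)
  beta_i[pd$eidx] <- state$beta[state$alloc]
  H0 <- drop(pd$E %*% state$lambda)
  lsurv <- sum(pd$delta * (log(state$lambda[pd$j_y]) + log1p(beta_i)) -
                 (1 + beta_i) * H0)

  em <- exposure_ll_matrix(pd, state, full = TRUE)
  lexp <- sum(em[cbind(seq_len(pd$n_e), state$alloc)])

  lalloc <- sum(log(state$phi[state$alloc]))
  lstick <- sum(stats::dbeta(state$V, 1, state$alpha, log = TRUE))

  lprior <- sum(stats::dnorm(state$beta, prior$beta_mean,
                             sqrt(prior$beta_var), log = TRUE)) +
    sum(stats::dnorm(state$mu, matrix(prior$mu_mean, state$C_max, 4,
                                      byrow = TRUE),
                     matrix(sqrt(prior$mu_var), state$C_max, 4,
                            byrow = TRUE), log = TRUE)) -
    length(state$sigma) * log(sb[2] - sb[1]) +
    sum((prior$dirichlet_conc - 1) * log(state$p_job)) +
    sum((prior$dirichlet_conc - 1) * log(state$p_mine)) +
    sum((prior$dirichlet_conc - 1) * log(state$p_dur)) +
    sum(stats::dgamma(state$lambda, prior$lambda_shape,
                      prior$lambda_rate, log = TRUE)) -
    log(ab[2] - ab[1])

  val <- lsurv + lexp + lalloc + lstick + lprior
  if (is.nan(val)) -Inf else val
}
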