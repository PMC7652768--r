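# Shared fixtures, all built in code.

hz4 <- function(rates = c(5e-8, 1.4e-6, 5.5e-6, 9.3e-6)) {
  baseline_hazard(rates)
}

# A tiny hand-built cohort: 3 exposed subjects + 1 reference.
tiny_cohort <- function() {
  structure(data.frame(
    y = c(60, 72, 45, 80) * YEAR_DAYS,
    delta = c(1, 0, 0, 1),
    entry_age = c(25, 30, 28, 22) * YEAR_DAYS,
    x_radon = c(10, 50, 2, 0),
    x_gamma = c(30, 120, 8, 0),
    x_dust = c(1, 4, 0.2, 0),
    age_first_exposure = c(24, 31, 27, NA),
    job = c(1L, 3L, 5L, NA),
    mine = c(1L, 2L, 2L, NA),
    duration_class = c(2L, 4L, 1L, NA),
    true_label = c(1L, 2L, 1L, 0L)),
    class = c("miner_cohort", "data.frame"))
}

# Deterministic valid mixture state for the tiny cohort (3 exposed subjects).
tiny_state <- function(C = 3, alloc = c(1L, 2L, 1L), V = c(0.5, 0.4),
                       beta = c(0.2, 1.0, -0.3), alpha = 2,
                       lambda = c(5e-8, 1.4e-6, 5.5e-6, 9.3e-6)) {
  mixture_state(
    V = V[seq_len(C - 1)], alpha = alpha, beta = beta[seq_len(C)],
    mu = matrix(c(2, 3.5, 0.5, 3.3), C, 4, byrow = TRUE) +
      outer(seq_len(C) - 1, c(1, 1, 1, 0.1)),
    sigma = matrix(0.5, C, 4),
    p_job = matrix(rep(c(0.4, 0.2, 0.2, 0.1, 0.1), each = C), C, 5),
    p_mine = matrix(rep(c(0.3, 0.7), each = C), C, 2),
    p_dur = matrix(rep(c(0.25, 0.25, 0.3, 0.2), each = C), C, 4),
    lambda = lambda, alloc = alloc)
}

# Random valid mixture state over a cohort with n_e exposed subjects.
rand_state <- function(n_e, C, seed) {
  set.seed(seed)
  mixture_state(
    V = runif(C - 1, 0.1, 0.9), alpha = runif(1, 0.5, 8),
    beta = runif(C, -0.8, 3),
    mu = matrix(rnorm(C * 4, c(2, 3.5, 0.5, 3.3), 1), C, 4, byrow = FALSE) +
      matrix(rnorm(C * 4, 0, 0.5), C, 4),
    sigma = matrix(runif(C * 4, 0.2, 2), C, 4),
    p_job = rdirich(C, 5), p_mine = rdirich(C, 2), p_dur = rdirich(C, 4),
    lambda = c(5e-8, 1.4e-6, 5.5e-6, 9.3e-6) * runif(4, 0.5, 2),
    alloc = sample.int(C, n_e, replace = TRUE))
}

rdirich <- function(n, k, conc = 1) {
  g <- matrix(rgamma(n * k, conc), n, k)
  g / rowSums(g)
}

# Hand-built prm_fit skeleton for post-treatment unit tests.
toy_fit <- function(beta_draws, alloc_draws, exposed_idx, n,
                    extra_draws = list()) {
  C <- ncol(beta_draws)
  draws <- c(list(beta = beta_draws), extra_draws)
  structure(list(model = "RPRM", draws = draws, alloc = alloc_draws,
                 n = n, C_max = C, exposed_idx = exposed_idx,
                 seed = 1L, config = sampler_config(preset = "smoke", K = C + 1),
                 accept_rates = c(beta = NA), nonempty = integer(0)),
            class = "prm_fit")
}

# Thin handles on internal sampler kernels under test.
draw_sticks_test <- function(occ, alpha) ehrmix:::draw_sticks(occ, alpha)
lambda_post_params_test <- function(pr, d_j, tE, mult)
  ehrmix:::lambda_post_params(pr, d_j, tE, mult)
sample_rows_test <- function(W) ehrmix:::sample_categorical_rows(W)
adapt_scale_test <- function(ls, rate, target, b)
  ehrmix:::adapt_scale(ls, rate, target, b)

# Swap two components' parameters and relabel allocations on a mixture_state
# (weights untouched) — used to brute-force move ratios via log_joint.
swap_state <- function(st, j, k) {
  sw <- ehrmix:::swap_component_params(st, j, k)
  sw$alloc <- ehrmix:::relabel_alloc(st$alloc, j, k)
  sw
}

# Independent quadrature oracle for the EHR survival log-likelihood.
# Integrated piecewise between the rate discontinuities so the quadrature
# itself is exact to machine precision.
quad_loglik <- function(y, delta, entry, mult, hazard) {
  h <- function(t) hazard$rates[findInterval(t, hazard$cut_days) + 1L] * mult
  brk <- sort(unique(c(entry, hazard$cut_days[hazard$cut_days > entry &
                                                hazard$cut_days < y], y)))
  H <- 0
  for (s in seq_len(length(brk) - 1))
    H <- H + stats::integrate(h, brk[s], brk[s + 1], rel.tol = 1e-13,
                              abs.tol = 0)$value
  delta * log(h(y)) - H
}
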