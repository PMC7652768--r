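# Adaptive Metropolis-within-Gibbs sampler for the profile regression
# mixture, with conjugate Gibbs draws wherever the full conditional is
# tractable (stick fractions, baseline rates, lognormal locations, category
# probabilities) and adapted random-walk Metropolis steps elsewhere (excess
# hazard ratios, lognormal scales, concentration). Three label-switching
# moves run after every sweep to fight the weak identifiability of
# component labels.

#' Sampler configuration
#'
#' The default schedule is the full production one: an adaptive phase of 100
#' batches of 100 iterations (proposal scales tuned towards 40% acceptance
#' for scalar blocks and 20% for vector blocks, then frozen), 10,000 burn-in
#' iterations and 150,000 retained iterations thinned by 20, so each
#' unknown's posterior sample holds 7,500 values. `preset = "smoke"` is a
#' reduced schedule (10 x 50 adaptive, 500 burn-in, 5,000 retained, thin 10)
#' for validation experiments and continuous testing.
#'
#' @param adapt_batches,batch_size adaptive-phase geometry.
#' @param burnin discarded post-adaptation iterations.
#' @param retained further iterations, of which every `thin`-th is stored.
#' @param thin thinning interval (must divide `retained`).
#' @param target_scalar,target_vector acceptance-rate targets for scalar and
#'   vector Metropolis blocks.
#' @param C_max truncation level of the stick-breaking mixture (PRM mode).
#' @param K number of clusters including the reference group (RPRM mode);
#'   the mixture then has `K - 1` exposed components.
#' @param moves run the three label-switching moves each sweep.
#' @param truncate left-truncate survival at entry age.
#' @param zero_policy treatment of subjects with some but not all exposures
#'   zero: `"halfmin"` imputes half the smallest positive observed value,
#'   `"reference"` routes them to the reference cluster.
#' @param seed integer RNG seed.
#' @param preset `NULL` or `"smoke"`.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(adapt_batches = 100, batch_size = 100,
                           burnin = 10000, retained = 150000, thin = 20,
                           target_scalar = 0.40, target_vector = 0.20,
                           C_max = 50, K = NULL, moves = TRUE,
                           truncate = TRUE,
                           zero_policy = c("halfmin", "reference"),
                           seed = 1L, preset = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "smoke")
    adapt_batches <- 10; batch_size <- 50
    burnin <- 500; retained <- 5000; thin <- 10
  }
  stopifnot(adapt_batches >= 0, batch_size >= 1, burnin >= 0,
            retained >= 1, thin >= 1, retained %% thin == 0,
            target_scalar > 0, target_scalar < 1,
            target_vector > 0, target_vector < 1,
            C_max >= 1, is.null(K) || K >= 2)
  structure(
    list(adapt_batches = adapt_batches, batch_size = batch_size,
         burnin = burnin, retained = retained, thin = thin,
         target_scalar = target_scalar, target_vector = target_vector,
         C_max = C_max, K = K, moves = moves, truncate = truncate,
         zero_policy = zero_policy, seed = as.integer(seed)),
    class = "sampler_config")
}

# ---- adaptation ------------------------------------------------------------
# Standard diminishing-adaptation rule: after batch b, move each block's
# log proposal scale by min(0.05, b^-1/2) towards its target (up when the
# empirical batch acceptance exceeds the target, down when below, no-op on a
# tie); scales are frozen once the adaptive phase ends.
adapt_scale <- function(log_scale, acc_rate, target, batch) {
  delta <- min(0.05, 1 / sqrt(batch))
  log_scale + delta * sign(acc_rate - target)
}

# ---- shared label-switching kernels ---------------------------------------
# All three take current occupancy counts and stick state and return the log
# acceptance ratio; swapping of component parameters/allocations is common.

move1_logratio <- function(phi, occ, j, k) {
  e <- occ[k] - occ[j]
  if (e == 0) return(0)
  lr <- e * (log(phi[j]) - log(phi[k]))
  if (is.nan(lr)) -Inf else lr
}

move2_logratio <- function(V, occ, j) {
  occ[j] * log1p(-V[j + 1]) - occ[j + 1] * log1p(-V[j])
}

# Move 3: label swap of (j, j+1) with (V_j, V_{j+1}) redrawn from their exact
# Beta full conditionals under the swapped counts. With full-conditional
# proposals the Metropolis ratio collapses to a ratio of Beta normalizing
# constants and does not depend on the sampled fractions.
move3_logratio <- function(occ, alpha, j) {
  tail_after <- sum(occ[-seq_len(j + 1)])
  (lbeta(1 + occ[j + 1], alpha + occ[j] + tail_after) +
     lbeta(1 + occ[j], alpha + tail_after)) -
    (lbeta(1 + occ[j], alpha + occ[j + 1] + tail_after) +
       lbeta(1 + occ[j + 1], alpha + tail_after))
}

move3_draw_V <- function(occ, alpha, j) {
  tail_after <- sum(occ[-seq_len(j + 1)])
  c(stats::rbeta(1, 1 + occ[j + 1], alpha + occ[j] + tail_after),
    stats::rbeta(1, 1 + occ[j], alpha + tail_after))
}

swap_component_params <- function(th, j, k) {
  th$beta[c(j, k)] <- th$beta[c(k, j)]
  th$mu[c(j, k), ] <- th$mu[c(k, j), ]
  th$sigma[c(j, k), ] <- th$sigma[c(k, j), ]
  th$p_job[c(j, k), ] <- th$p_job[c(k, j), ]
  th$p_mine[c(j, k), ] <- th$p_mine[c(k, j), ]
  th$p_dur[c(j, k), ] <- th$p_dur[c(k, j), ]
  th
}

relabel_alloc <- function(alloc, j, k) {
  at_j <- alloc == j
  alloc[alloc == k] <- j
  alloc[at_j] <- k
  alloc
}

#' Log acceptance ratio of a label-switching move
#'
#' Move 1 swaps the parameters and allocations of two arbitrary components
#' (weights untouched), with ratio \eqn{(\phi_j/\phi_k)^{n_k-n_j}}. Move 2
#' swaps an adjacent pair including its stick fractions, with ratio
#' \eqn{(1-V_{j+1})^{n_j}/(1-V_j)^{n_{j+1}}}. Move 3 swaps an adjacent pair
#' and redraws its stick fractions from their full conditionals under the
#' swapped counts, so the implied weights land near their conditional
#' expectations; its ratio is a closed form in log-Beta functions.
#'
#' @param state a [mixture_state()].
#' @param type move type, 1, 2 or 3.
#' @param j first component (for moves 2-3 the pair is `(j, j+1)` and
#'   `j <= C_max - 2`).
#' @param k second component (move 1 only).
#' @return scalar log acceptance ratio.
#' @export
label_switch_ratio <- function(state, type, j, k = NULL) {
  occ <- tabulate(state$alloc, state$C_max)
  switch(as.character(type),
    "1" = {
      stopifnot(!is.null(k), j != k)
      move1_logratio(state$phi, occ, j, k)
    },
    "2" = {
      if (j < 1 || j > state$C_max - 2) stop("move 2 requires j <= C_max - 2")
      move2_logratio(state$V, occ, j)
    },
    "3" = {
      if (j < 1 || j > state$C_max - 2) stop("move 3 requires j <= C_max - 2")
      move3_logratio(occ, state$alpha, j)
    },
    stop("type must be 1, 2 or 3"))
}

#' Apply a label-switching move to a mixture state
#'
#' Performs the Metropolis accept/reject step for one of the three
#' label-switching moves (see [label_switch_ratio()]); on rejection the state
#' is returned unchanged.
#'
#' @inheritParams label_switch_ratio
#' @return the (possibly updated) `mixture_state`, with attribute
#'   `"accepted"` (logical).
#' @export
label_switch <- function(state, type, j, k = NULL) {
  logr <- label_switch_ratio(state, type, j, k)
  acc <- log(stats::runif(1)) < logr
  if (acc) {
    if (type == 1) {
      state <- swap_component_params(state, j, k)
      state$alloc <- relabel_alloc(state$alloc, j, k)
    } else {
      occ <- tabulate(state$alloc, state$C_max)
      if (type == 2) {
        state$V[c(j, j + 1)] <- state$V[c(j + 1, j)]
      } else {
        newV <- move3_draw_V(occ, state$alpha, j)
        if (any(newV <= 0) || any(newV >= 1)) {  # degenerate draw: auto-reject
          attr(state, "accepted") <- FALSE
          return(state)
        }
        state$V[c(j, j + 1)] <- newV
      }
      state <- swap_component_params(state, j, j + 1)
      state$alloc <- relabel_alloc(state$alloc, j, j + 1)
      state$phi <- stick_breaking(state$V)
    }
  }
  attr(state, "accepted") <- acc
  state
}

# ---- helpers ---------------------------------------------------------------

# Conjugate full-conditional draw of the stick fractions given occupancy
# counts: V_c ~ Beta(1 + n_c, alpha + sum_{l > c} n_l).
draw_sticks <- function(occ, alpha) {
  C <- length(occ)
  if (C < 2) return(numeric(0))
  tail_occ <- (rev(cumsum(rev(occ))))[-1]
  clamp01(stats::rbeta(C - 1, 1 + occ[-C], alpha + tail_occ))
}

# Conjugate gamma full conditional of the baseline rates: shape a_j + d_j
# (events in interval j), rate b_j + sum_i m_i e_ij with hazard multipliers
# m_i and person-time e_ij.
lambda_post_params <- function(prior, d_j, tE, mult) {
  list(shape = prior$lambda_shape + d_j,
       rate = prior$lambda_rate + drop(tE %*% mult))
}

# Exact row-wise categorical sampling from unnormalized log-weights via the
# Gumbel-max trick.
sample_categorical_rows <- function(W) {
  G <- -log(matrix(stats::rexp(length(W)), nrow(W), ncol(W)))
  max.col(W + G, ties.method = "first")
}

rowsum_by <- function(x, f, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, f)
  out[as.integer(rownames(s))] <- s
  out
}

# grouped column sums of a matrix by allocation -> nbins x ncol
groupsum <- function(m, f, nbins) {
  out <- matrix(0, nbins, ncol(m))
  s <- rowsum(m, f)
  out[as.integer(rownames(s)), ] <- s
  out
}

rdirichlet_rows <- function(counts, conc) {
  g <- matrix(stats::rgamma(length(counts), shape = conc + counts),
              nrow(counts), ncol(counts))
  g / rowSums(g)
}

clamp01 <- function(v, eps = 1e-12) pmin(pmax(v, eps), 1 - eps)

# ---- main engine -----------------------------------------------------------

run_engine <- function(cohort, prior, config, C, model) {
  set.seed(config$seed)
  hazard <- baseline_hazard(prior$lambda_shape / prior$lambda_rate)
  pd <- prep_data(cohort, hazard, config$truncate, config$zero_policy)
  if (pd$n_e < 1) stop("cohort has no exposed subjects")
  n_e <- pd$n_e
  conc <- prior$dirichlet_conc
  sb <- prior$sigma_bounds; ab <- prior$alpha_bounds
  m0 <- prior$mu_mean; v0 <- prior$mu_var
  sd_beta0 <- sqrt(prior$beta_var)

  # --- initialization: k-means on standardized log-exposures ---------------
  k_init <- min(C, 5L, n_e)
  if (k_init > 1) {
    km <- stats::kmeans(scale(pd$lx), centers = k_init, nstart = 3,
                        iter.max = 25)
    alloc <- as.integer(km$cluster)
  } else alloc <- rep(1L, n_e)

  mu <- matrix(colMeans(pd$lx), C, 4, byrow = TRUE)
  sigma <- matrix(pmax(apply(pd$lx, 2, stats::sd), 0.2), C, 4, byrow = TRUE)
  for (c in seq_len(k_init)) {
    m <- alloc == c
    if (sum(m) >= 2) {
      mu[c, ] <- colMeans(pd$lx[m, , drop = FALSE])
      sigma[c, ] <- pmax(apply(pd$lx[m, , drop = FALSE], 2, stats::sd), 0.2)
    }
  }
  cnt <- function(fac, L) {
    tab <- matrix(tabulate(alloc + C * (fac - 1L), C * L), C, L)
    (tab + conc) / rowSums(tab + conc)
  }
  p_job <- cnt(pd$job, 5L); p_mine <- cnt(pd$mine, 2L); p_dur <- cnt(pd$dur, 4L)
  beta <- numeric(C)
  lambda <- prior$lambda_shape / prior$lambda_rate
  alpha <- 1
  occ <- tabulate(alloc, C)
  tail_occ <- if (C > 1) (rev(cumsum(rev(occ))))[-1] else numeric(0)
  V <- if (C > 1) clamp01((1 + occ[-C]) / (2 + occ[-C] + alpha + tail_occ))
       else numeric(0)
  phi <- stick_breaking(V)

  # proposal scales (log parametrization adapted, sd used directly)
  ls_beta <- rep(log(0.1), C)
  ls_sigma <- matrix(log(0.1), C, 4)
  ls_alpha <- log(0.5)

  # fixed sufficient statistics
  d_j <- vapply(1:4, function(j) sum(pd$delta[pd$j_y == j]), numeric(1))
  delta_e <- pd$delta_e
  ev_by <- function(a) rowsum_by(delta_e, a, C)   # events per component
  tE <- t(pd$E)

  n_adapt <- config$adapt_batches * config$batch_size
  n_total <- n_adapt + config$burnin + config$retained
  S <- config$retained %/% config$thin

  # storage
  zeros <- function(p) matrix(NA_real_, S, p)
  draws <- list(lambda = zeros(4), alpha = zeros(1), beta = zeros(C),
                phi = zeros(C))
  if (C > 1) draws$V <- zeros(C - 1)
  vn <- c("radon", "gamma", "dust", "age")
  for (v in 1:4) {
    draws[[paste0("mu_", vn[v])]] <- zeros(C)
    draws[[paste0("sigma_", vn[v])]] <- zeros(C)
  }
  for (l in 1:5) draws[[paste0("p_job_", l)]] <- zeros(C)
  for (l in 1:2) draws[[paste0("p_mine_", l)]] <- zeros(C)
  for (l in 1:4) draws[[paste0("p_dur_", l)]] <- zeros(C)
  alloc_draws <- matrix(NA_integer_, S, n_e)
  nonempty <- integer(config$retained)

  # acceptance bookkeeping: per-batch (adaptation) and post-adaptation totals
  acc_beta_b <- numeric(C); acc_sigma_b <- matrix(0, C, 4); acc_alpha_b <- 0
  acc_post <- list(beta = numeric(C), sigma = matrix(0, C, 4), alpha = 0,
                   move1 = 0, move2 = 0, move3 = 0)
  att_post <- 0; att_moves <- c(move1 = 0, move2 = 0, move3 = 0)
  s_idx <- 0L

  for (it in seq_len(n_total)) {
    adapting <- it <= n_adapt

    ## 1. allocations ------------------------------------------------------
    if (C > 1) {
      W <- matrix(log(phi), n_e, C, byrow = TRUE)
      st <- list(C_max = C, beta = beta, mu = mu, sigma = sigma,
                 p_job = p_job, p_mine = p_mine, p_dur = p_dur,
                 lambda = lambda)
      W <- W + exposure_ll_matrix(pd, st, full = FALSE) +
        survival_ll_matrix(pd, st, full = FALSE)
      alloc <- sample_categorical_rows(W)
    }
    occ <- tabulate(alloc, C)

    ## 2. stick fractions (conjugate) --------------------------------------
    if (C > 1) {
      V <- draw_sticks(occ, alpha)
      phi <- stick_breaking(V)
    }

    ## 3. concentration alpha (random-walk MH in [ab1, ab2]) ---------------
    {
      prop <- alpha + exp(ls_alpha) * stats::rnorm(1)
      if (prop >= ab[1] && prop <= ab[2]) {
        sl <- if (C > 1) sum(log1p(-V)) else 0
        logr <- (C - 1) * (log(prop) - log(alpha)) + (prop - alpha) * sl
        if (log(stats::runif(1)) < logr) {
          alpha <- prop
          if (adapting) acc_alpha_b <- acc_alpha_b + 1
          else acc_post$alpha <- acc_post$alpha + 1
        }
      }
    }

    ## 4. baseline rates (conjugate gamma) ---------------------------------
    mult <- rep(1, pd$n)
    mult[pd$eidx] <- 1 + beta[alloc]
    lp <- lambda_post_params(prior, d_j, tE, mult)
    lambda <- stats::rgamma(4, shape = lp$shape, rate = lp$rate)

    ## 5. excess hazard ratios (random-walk MH, beta > -1) ------------------
    {
      H0 <- drop(pd$E %*% lambda)
      He <- H0[pd$eidx]
      D_c <- ev_by(alloc)
      H_c <- rowsum_by(He, alloc, C)
      prop <- beta + exp(ls_beta) * stats::rnorm(C)
      ok <- prop > -1
      logr <- rep(-Inf, C)
      logr[ok] <- D_c[ok] * (log1p(prop[ok]) - log1p(beta[ok])) -
        (prop[ok] - beta[ok]) * H_c[ok] +
        stats::dnorm(prop[ok], prior$beta_mean, sd_beta0, TRUE) -
        stats::dnorm(beta[ok], prior$beta_mean, sd_beta0, TRUE)
      acc <- log(stats::runif(C)) < logr
      beta[acc] <- prop[acc]
      if (adapting) acc_beta_b <- acc_beta_b + acc
      else acc_post$beta <- acc_post$beta + acc
    }

    ## 6. lognormal locations (conjugate normal) ---------------------------
    Sx <- groupsum(pd$lx, alloc, C)
    prec <- sweep(occ / sigma^2, 2, 1 / v0, `+`)
    pmean <- (Sx / sigma^2 + matrix(m0 / v0, C, 4, byrow = TRUE)) / prec
    mu <- matrix(stats::rnorm(C * 4, pmean, 1 / sqrt(prec)), C, 4)

    ## 7. lognormal scales (random-walk MH in sigma bounds) ----------------
    {
      Sxx <- groupsum(pd$lx2, alloc, C)
      SS <- Sxx - 2 * mu * Sx + occ * mu^2
      prop <- sigma + exp(ls_sigma) * matrix(stats::rnorm(C * 4), C, 4)
      inside <- prop > sb[1] & prop < sb[2]
      logr <- matrix(-Inf, C, 4)
      logr[inside] <- (-occ[row(prop)[inside]] * log(prop[inside]) -
                         SS[inside] / (2 * prop[inside]^2)) -
        (-occ[row(prop)[inside]] * log(sigma[inside]) -
           SS[inside] / (2 * sigma[inside]^2))
      acc <- matrix(log(stats::runif(C * 4)), C, 4) < logr
      sigma[acc] <- prop[acc]
      if (adapting) acc_sigma_b <- acc_sigma_b + acc
      else acc_post$sigma <- acc_post$sigma + acc
    }

    ## 8. category probabilities (conjugate Dirichlet) ---------------------
    p_job <- rdirichlet_rows(matrix(tabulate(alloc + C * (pd$job - 1L),
                                             C * 5L), C, 5L), conc)
    p_mine <- rdirichlet_rows(matrix(tabulate(alloc + C * (pd$mine - 1L),
                                              C * 2L), C, 2L), conc)
    p_dur <- rdirichlet_rows(matrix(tabulate(alloc + C * (pd$dur - 1L),
                                             C * 4L), C, 4L), conc)

    ## 9. label-switching moves --------------------------------------------
    if (config$moves && C >= 2) {
      occ <- tabulate(alloc, C)
      jk <- sample.int(C, 2L)
      logr <- move1_logratio(phi, occ, jk[1], jk[2])
      att_moves["move1"] <- att_moves["move1"] + 1
      if (log(stats::runif(1)) < logr) {
        th <- swap_component_params(
          list(beta = beta, mu = mu, sigma = sigma, p_job = p_job,
               p_mine = p_mine, p_dur = p_dur), jk[1], jk[2])
        beta <- th$beta; mu <- th$mu; sigma <- th$sigma
        p_job <- th$p_job; p_mine <- th$p_mine; p_dur <- th$p_dur
        alloc <- relabel_alloc(alloc, jk[1], jk[2])
        occ <- tabulate(alloc, C)
        acc_post$move1 <- acc_post$move1 + 1
      }
      if (C >= 3) {
        for (mv in 2:3) {
          j <- sample.int(C - 2L, 1L)
          logr <- if (mv == 2) move2_logratio(V, occ, j)
                  else move3_logratio(occ, alpha, j)
          att_moves[mv] <- att_moves[mv] + 1
          if (log(stats::runif(1)) < logr) {
            if (mv == 2) {
              V[c(j, j + 1)] <- V[c(j + 1, j)]
            } else {
              newV <- move3_draw_V(occ, alpha, j)
              if (any(newV <= 0) || any(newV >= 1)) next
              V[c(j, j + 1)] <- newV
            }
            th <- swap_component_params(
              list(beta = beta, mu = mu, sigma = sigma, p_job = p_job,
                   p_mine = p_mine, p_dur = p_dur), j, j + 1L)
            beta <- th$beta; mu <- th$mu; sigma <- th$sigma
            p_job <- th$p_job; p_mine <- th$p_mine; p_dur <- th$p_dur
            alloc <- relabel_alloc(alloc, j, j + 1L)
            occ <- tabulate(alloc, C)
            phi <- stick_breaking(V)
            acc_post[[paste0("move", mv)]] <- acc_post[[paste0("move", mv)]] + 1
          }
        }
      }
    }

    ## adaptation ----------------------------------------------------------
    if (adapting) {
      if (it %% config$batch_size == 0) {
        b <- it %/% config$batch_size
        bs <- config$batch_size
        ls_beta <- adapt_scale(ls_beta, acc_beta_b / bs,
                               config$target_scalar, b)
        ls_sigma <- adapt_scale(ls_sigma, acc_sigma_b / bs,
                                config$target_scalar, b)
        ls_alpha <- adapt_scale(ls_alpha, acc_alpha_b / bs,
                                config$target_scalar, b)
        acc_beta_b[] <- 0; acc_sigma_b[] <- 0; acc_alpha_b <- 0
      }
    } else {
      att_post <- att_post + 1
    }

    ## storage -------------------------------------------------------------
    ret_it <- it - n_adapt - config$burnin
    if (ret_it >= 1) {
      nonempty[ret_it] <- sum(tabulate(alloc, C) > 0)
      if (ret_it %% config$thin == 0) {
        s_idx <- s_idx + 1L
        draws$lambda[s_idx, ] <- lambda
        draws$alpha[s_idx, 1] <- alpha
        draws$beta[s_idx, ] <- beta
        draws$phi[s_idx, ] <- phi
        if (C > 1) draws$V[s_idx, ] <- V
        for (v in 1:4) {
          draws[[paste0("mu_", vn[v])]][s_idx, ] <- mu[, v]
          draws[[paste0("sigma_", vn[v])]][s_idx, ] <- sigma[, v]
        }
        for (l in 1:5) draws[[paste0("p_job_", l)]][s_idx, ] <- p_job[, l]
        for (l in 1:2) draws[[paste0("p_mine_", l)]][s_idx, ] <- p_mine[, l]
        for (l in 1:4) draws[[paste0("p_dur_", l)]][s_idx, ] <- p_dur[, l]
        alloc_draws[s_idx, ] <- alloc
      }
    }
  }

  accept_detail <- list(
    beta = acc_post$beta / att_post,
    sigma = acc_post$sigma / att_post,
    alpha = acc_post$alpha / att_post,
    moves = ifelse(att_moves > 0,
                   c(acc_post$move1, acc_post$move2, acc_post$move3) /
                     att_moves, NA))
  structure(
    list(model = model, draws = draws, alloc = alloc_draws,
         n = pd$n, C_max = C, exposed_idx = pd$eidx,
         seed = config$seed, config = config,
         accept_rates = c(beta = mean(accept_detail$beta),
                          sigma = mean(accept_detail$sigma),
                          alpha = accept_detail$alpha),
         accept_detail = accept_detail,
         nonempty = nonempty,
         scales = list(beta = exp(ls_beta), sigma = exp(ls_sigma),
                       alpha = exp(ls_alpha))),
    class = "prm_fit")
}

#' Fit the profile regression mixture (PRM)
#'
#' Runs the full adaptive Metropolis-within-Gibbs schedule on a cohort with
#' the stick-breaking mixture truncated at `config$C_max` components, storing
#' every thinned draw of all parameters and of the allocation vector, and
#' logging per-block acceptance rates plus the per-iteration count of
#' non-empty clusters (the diagnostic used to detect convergence to local
#' modes).
#'
#' @param cohort a `miner_cohort` data.frame (see [read_cohort()]).
#' @param prior a [prior_spec()].
#' @param config a [sampler_config()].
#' @return an object of class `prm_fit`.
#' @export
fit_prm <- function(cohort, prior = prior_spec(), config = sampler_config()) {
  run_engine(cohort, prior, config, C = config$C_max, model = "PRM")
}

#' Fit the restricted profile regression mixture (RPRM)
#'
#' Identical machinery with the number of clusters fixed: `config$K` counts
#' clusters including the reference group, so the mixture holds `K - 1`
#' exposed components. The concentration is still sampled, and component
#' emptiness is reported per iteration rather than forbidden.
#'
#' @inheritParams fit_prm
#' @return an object of class `prm_fit`.
#' @export
fit_rprm <- function(cohort, prior = prior_spec(),
                     config = sampler_config()) {
  if (is.null(config$K) || config$K < 2)
    stop("RPRM requires config$K >= 2 (clusters including the reference)")
  run_engine(cohort, prior, config, C = config$K - 1L, model = "RPRM")
}

#' @export
print.prm_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d (%d exposed), %d mixture components, %d stored draws\n",
              x$model, x$n, length(x$exposed_idx), x$C_max,
              nrow(x$draws[[1]])))
  cat(sprintf("  acceptance: beta %.2f, sigma %.2f, alpha %.2f\n",
              x$accept_rates[["beta"]], x$accept_rates[["sigma"]],
              x$accept_rates[["alpha"]]))
  if (length(x$nonempty))
    cat(sprintf("  non-empty clusters (post burn-in): modal %d, range %d-%d\n",
                as.integer(names(which.max(table(x$nonempty)))),
                min(x$nonempty), max(x$nonempty)))
  invisible(x)
}
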