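# Post-treatment of MCMC output: posterior similarity matrix, least-squares
# best partition among the sampled ones, cluster-conditional posterior
# samples, DIC/WAIC model comparison and cluster characterization reports.

# Internal: draws x n matrix of full labels (reference subjects fixed at 0).
full_label_matrix <- function(fit) {
  if (is.matrix(fit)) return(fit)
  stopifnot(inherits(fit, "prm_fit"))
  if (is.null(fit$alloc)) stop("fit stores no allocation trace")
  L <- matrix(0L, nrow(fit$alloc), fit$n)
  L[, fit$exposed_idx] <- fit$alloc
  L
}

#' Posterior similarity matrix
#'
#' For each retained draw, the binary matrix with entry 1 when subjects i and
#' j share a cluster; their mean over draws is the proportion of draws in
#' which each pair co-clusters. Reference subjects always co-cluster with
#' each other and never with exposed subjects. Computed draw by draw; the
#' individual binary matrices are never all materialized.
#'
#' @param fit a `prm_fit`, or an integer matrix of labels (draws x subjects).
#' @return symmetric n x n matrix with unit diagonal, entries in `[0, 1]`.
#' @export
similarity_matrix <- function(fit) {
  L <- full_label_matrix(fit)
  K <- nrow(L)
  if (K == 0) stop("empty allocation trace")
  n <- ncol(L)
  S <- matrix(0, n, n)
  for (k in seq_len(K)) {
    lab <- L[k, ] + 1L
    Z <- matrix(0, n, max(lab))
    Z[cbind(seq_len(n), lab)] <- 1
    S <- S + tcrossprod(Z)
  }
  S / K
}

#' Best partition by least squares to the similarity matrix
#'
#' Among the sampled partitions only, returns the one minimizing
#' \eqn{\sum_{i<j} (S_k(i,j) - S(i,j))^2}; ties are broken by earliest draw.
#' The distance depends only on co-clustering, so it is invariant to
#' relabeling components within a draw.
#'
#' @param fit a `prm_fit` or a label matrix (draws x subjects).
#' @param S posterior similarity matrix from [similarity_matrix()]; computed
#'   if missing.
#' @return list with `labels` (per-subject labels of the winning draw,
#'   0 = reference), `draw` (its index) and `distance`.
#' @export
best_partition <- function(fit, S = NULL) {
  L <- full_label_matrix(fit)
  if (nrow(L) == 0) stop("empty allocation trace")
  if (is.null(S)) S <- similarity_matrix(L)
  n <- ncol(L)
  dist <- numeric(nrow(L))
  for (k in seq_len(nrow(L))) {
    lab <- L[k, ] + 1L
    Z <- matrix(0, n, max(lab))
    Z[cbind(seq_len(n), lab)] <- 1
    dist[k] <- sum((tcrossprod(Z) - S)^2) / 2  # unordered pairs i < j
  }
  k_best <- which.min(dist)  # which.min takes the earliest on ties
  list(labels = L[k_best, ], draw = k_best, distance = dist[k_best])
}

#' Cluster-conditional posterior samples
#'
#' Conditional on the best partition, the draw-k posterior sample of a
#' cluster-indexed parameter for best-partition cluster c is the average over
#' that cluster's members of the parameter value attached to each member's
#' draw-k component:
#' \eqn{\bar\theta_{c,k} = n_c^{-1} \sum_{i: c_i^{best}=c} \theta_{C_{ik}, k}}.
#' Applies to `beta`, all `mu_*`/`sigma_*` pairs, all `p_*` levels and `phi`.
#'
#' @param fit a `prm_fit`.
#' @param c_best best-partition labels (vector as returned in
#'   `best_partition()$labels`).
#' @param param name of a per-component draws block (e.g. `"beta"`,
#'   `"mu_radon"`, `"p_job_1"`, `"phi"`).
#' @return matrix (draws x best-partition exposed clusters), columns named by
#'   cluster label.
#' @export
conditional_posteriors <- function(fit, c_best, param) {
  stopifnot(inherits(fit, "prm_fit"))
  P <- fit$draws[[param]]
  if (is.null(P) || ncol(P) != fit$C_max)
    stop("'", param, "' is not a cluster-indexed parameter of this fit")
  S <- nrow(P)
  A <- fit$alloc
  cl <- sort(unique(c_best[c_best > 0]))
  out <- matrix(NA_real_, S, length(cl),
                dimnames = list(NULL, as.character(cl)))
  rows <- seq_len(S)
  for (ci in seq_along(cl)) {
    members <- which(c_best == cl[ci])
    pos <- match(members, fit$exposed_idx)
    if (anyNA(pos)) stop("best-partition cluster contains reference subjects")
    idx <- as.vector((A[, pos, drop = FALSE] - 1L) * S + rows)
    out[, ci] <- rowMeans(matrix(P[idx], S, length(pos)))
  }
  out
}

# ---- information criteria --------------------------------------------------

# Internal: draws x n matrix of per-subject log-likelihoods under the
# mixture (exposed: sum_c phi_c f_exposure f_survival; reference: survival
# at beta = 0), plus the same quantity at posterior means of the continuous
# parameters (allocations marginalized by the mixture form).
pointwise_loglik <- function(fit, cohort, at_means = FALSE) {
  cohort <- validate_cohort(cohort)
  config <- fit$config
  hazard <- baseline_hazard(rep(1, 4))  # cutpoints only; rates per draw
  pd <- prep_data(cohort, hazard,
                  isTRUE(config$truncate) || is.null(config$truncate),
                  if (is.null(config$zero_policy)) "halfmin"
                  else config$zero_policy)
  if (fit$model == "EHR")
    return(pointwise_loglik_ehr(fit, cohort, pd, at_means))
  dr <- fit$draws
  C <- fit$C_max
  vn <- c("radon", "gamma", "dust", "age")
  S <- if (at_means) 1L else nrow(dr$beta)
  get <- function(nm, k) if (at_means) colMeans(dr[[nm]]) else dr[[nm]][k, ]
  out <- matrix(NA_real_, S, pd$n)
  ref <- setdiff(seq_len(pd$n), pd$eidx)
  for (k in seq_len(S)) {
    st <- list(C_max = C, beta = get("beta", k),
               mu = sapply(vn, function(v) get(paste0("mu_", v), k)),
               sigma = sapply(vn, function(v) get(paste0("sigma_", v), k)),
               p_job = sapply(1:5, function(l) get(paste0("p_job_", l), k)),
               p_mine = sapply(1:2, function(l) get(paste0("p_mine_", l), k)),
               p_dur = sapply(1:4, function(l) get(paste0("p_dur_", l), k)),
               lambda = get("lambda", k))
    if (C == 1) {
      st$mu <- matrix(st$mu, 1); st$sigma <- matrix(st$sigma, 1)
      st$p_job <- matrix(st$p_job, 1); st$p_mine <- matrix(st$p_mine, 1)
      st$p_dur <- matrix(st$p_dur, 1)
    }
    phi <- get("phi", k)
    W <- matrix(log(phi), pd$n_e, C, byrow = TRUE) +
      exposure_ll_matrix(pd, st, full = TRUE) +
      survival_ll_matrix(pd, st, full = TRUE)
    mx <- apply(W, 1, max)
    out[k, pd$eidx] <- mx + log(rowSums(exp(W - mx)))
    H0 <- drop(pd$E %*% st$lambda)
    out[k, ref] <- pd$delta[ref] * log(st$lambda[pd$j_y[ref]]) - H0[ref]
  }
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)
    stop("non-finite pointwise likelihood for subject ", bad[1, 2])
  }
  out
}

pointwise_loglik_ehr <- function(fit, cohort, pd, at_means = FALSE) {
  X <- as.matrix(cohort[paste0("x_", fit$exposures)])
  X <- sweep(X, 2, fit$scaling, `*`)
  S <- if (at_means) 1L else nrow(fit$draws$coef)
  out <- matrix(NA_real_, S, pd$n)
  for (k in seq_len(S)) {
    coef <- if (at_means) colMeans(fit$draws$coef) else fit$draws$coef[k, ]
    lam <- if (at_means) colMeans(fit$draws$lambda) else fit$draws$lambda[k, ]
    m <- 1 + drop(X %*% coef)
    H0 <- drop(pd$E %*% lam)
    out[k, ] <- pd$delta * (log(lam[pd$j_y]) + log(m)) - m * H0
  }
  out
}

#' DIC from a pointwise log-likelihood table
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\hat\theta)}, where
#' \eqn{\bar D} is the posterior mean deviance and \eqn{D(\hat\theta)} the
#' deviance at a plug-in point estimate.
#'
#' @param logp draws x subjects matrix of log-likelihoods.
#' @param logp_hat length-n vector of log-likelihoods at the point estimate.
#' @return list with `dic`, `p_d`, `d_bar`, `d_hat`.
#' @export
dic_from_loglik <- function(logp, logp_hat) {
  d_bar <- mean(-2 * rowSums(logp))
  d_hat <- -2 * sum(logp_hat)
  p_d <- d_bar - d_hat
  list(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar, d_hat = d_hat)
}

#' WAIC from a pointwise log-likelihood table
#'
#' \eqn{WAIC = -2(lppd - p_{waic})} with
#' \eqn{lppd = \sum_i \log \frac1K \sum_k p_{ik}} and
#' \eqn{p_{waic} = \sum_i \mathrm{var}_k(\log p_{ik})}.
#'
#' @param logp draws x subjects matrix of log-likelihoods.
#' @return list with `waic`, `p_waic`, `lppd`.
#' @export
waic_from_loglik <- function(logp) {
  K <- nrow(logp)
  mx <- apply(logp, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(logp, 2, mx)))))
  p_waic <- if (K > 1) sum(apply(logp, 2, stats::var)) else 0
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Deviance information criterion of a fitted model
#'
#' Per-subject likelihoods use the mixture form (allocations marginalized
#' over components weighted by phi); the plug-in deviance is evaluated at the
#' posterior means of the continuous parameters.
#'
#' @param fit a `prm_fit`.
#' @param cohort the cohort the model was fitted to.
#' @return list with `dic`, `p_d`, `d_bar`, `d_hat`.
#' @export
compute_dic <- function(fit, cohort) {
  logp <- pointwise_loglik(fit, cohort)
  logp_hat <- drop(pointwise_loglik(fit, cohort, at_means = TRUE))
  dic_from_loglik(logp, logp_hat)
}

#' Watanabe-Akaike information criterion of a fitted model
#'
#' @inheritParams compute_dic
#' @return list with `waic`, `p_waic`, `lppd`.
#' @export
compute_waic <- function(fit, cohort) {
  waic_from_loglik(pointwise_loglik(fit, cohort))
}

# ---- cluster characterization ---------------------------------------------

interval_flag <- function(lo, hi, ref = 0) {
  ifelse(lo > ref, "above", ifelse(hi < ref, "below", "overlap"))
}

#' Cluster characterization report
#'
#' Summarizes each best-partition cluster: size, lung-cancer events, excess
#' hazard ratio quartiles and 95% credible interval with a risk flag
#' (interval above 0 = "significant high risk", below 0 = "significant low
#' risk", otherwise neutral), plus, for every exposure-profile covariate, the
#' position of the cluster-conditional 95% interval relative to the
#' all-subject median (below / above / overlapping). Clusters are ordered by
#' posterior median excess hazard ratio.
#'
#' @param fit a `prm_fit` (PRM or RPRM).
#' @param cohort the fitted cohort.
#' @param c_best best-partition labels; computed via [best_partition()] when
#'   missing.
#' @return list with `clusters` (one row per cluster) and `covariates` (one
#'   row per cluster x covariate), plus the labels used, class
#'   `cluster_report`.
#' @export
cluster_report <- function(fit, cohort, c_best = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(c_best)) c_best <- best_partition(fit)$labels
  cl <- sort(unique(c_best[c_best > 0]))
  qs <- function(m) t(apply(m, 2, stats::quantile,
                            probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                            names = FALSE))
  bq <- qs(conditional_posteriors(fit, c_best, "beta"))
  clusters <- data.frame(
    cluster = cl,
    n = vapply(cl, function(c) sum(c_best == c), numeric(1)),
    events = vapply(cl, function(c) sum(cohort$delta[c_best == c]),
                    numeric(1)),
    beta_lo = bq[, 1], beta_q1 = bq[, 2], beta_median = bq[, 3],
    beta_q3 = bq[, 4], beta_hi = bq[, 5])
  fl <- interval_flag(clusters$beta_lo, clusters$beta_hi)
  clusters$risk_flag <- c(above = "significant high risk",
                          below = "significant low risk",
                          overlap = "neutral")[fl]

  cont <- c(mu_radon = "x_radon", mu_gamma = "x_gamma", mu_dust = "x_dust",
            mu_age = "age_first_exposure")
  cov_rows <- list()
  for (p in names(cont)) {
    med <- exp(qs(conditional_posteriors(fit, c_best, p))[, c(1, 3, 5),
                                                          drop = FALSE])
    ref <- stats::median(cohort[[cont[p]]], na.rm = TRUE)
    cov_rows[[p]] <- data.frame(
      cluster = cl, covariate = cont[[p]],
      lo = med[, 1], median = med[, 2], hi = med[, 3], global = ref,
      position = interval_flag(med[, 1], med[, 3], ref))
  }
  cats <- list(p_job = list("job", 5), p_mine = list("mine", 2),
               p_dur = list("duration_class", 4))
  for (p in names(cats)) {
    v <- cats[[p]][[1]]; L <- cats[[p]][[2]]
    for (l in seq_len(L)) {
      q <- qs(conditional_posteriors(fit, c_best,
                                     paste0(p, "_", l)))[, c(1, 3, 5),
                                                         drop = FALSE]
      ref <- mean(cohort[[v]] == l, na.rm = TRUE)
      cov_rows[[paste0(p, l)]] <- data.frame(
        cluster = cl, covariate = paste0(v, "=", l),
        lo = q[, 1], median = q[, 2], hi = q[, 3], global = ref,
        position = interval_flag(q[, 1], q[, 3], ref))
    }
  }
  covariates <- do.call(rbind, cov_rows)
  rownames(covariates) <- NULL
  ord <- order(clusters$beta_median)
  structure(list(clusters = clusters[ord, ],
                 covariates = covariates, c_best = c_best),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster characterization (ordered by posterior median excess hazard ratio)\n")
  print(x$clusters, row.names = FALSE, digits = 3)
  invisible(x)
}
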