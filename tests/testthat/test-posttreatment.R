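# Brute-force oracles for the similarity matrix and best partition.
brute_similarity <- function(L) {
  n <- ncol(L)
  S <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    S[i, j] <- mean(L[, i] == L[, j])
  S
}
brute_best <- function(L, S = brute_similarity(L)) {
  d <- apply(L, 1, function(lab) {
    s <- 0
    n <- length(lab)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + ((lab[i] == lab[j]) - S[i, j])^2
    s
  })
  list(k = which.min(d), d = d)
}

test_that("similarity matrix equals the mean of co-clustering indicators", {
  # degenerate chain: the block 0/1 matrix of the single sampled partition
  L <- matrix(rep(c(1L, 1L, 2L, 0L), each = 3), 3, 4)
  S <- similarity_matrix(L)
  expect_equal(S, brute_similarity(L))
  expect_true(all(S %in% c(0, 1)))
  # a pair together in exactly one of two draws scores 0.5
  L2 <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  expect_equal(similarity_matrix(L2)[1, 2], 0.5)
  expect_equal(similarity_matrix(L2)[2, 3], 0.5)
  expect_equal(similarity_matrix(L2)[1, 3], 0)
  # 5 subjects, 4 hand-written draws
  L3 <- rbind(c(1L, 1L, 2L, 2L, 0L),
              c(1L, 2L, 2L, 2L, 0L),
              c(3L, 3L, 3L, 1L, 0L),
              c(1L, 1L, 1L, 1L, 0L))
  S3 <- similarity_matrix(L3)
  expect_equal(S3, brute_similarity(L3))
  expect_true(isSymmetric(S3))
  expect_equal(diag(S3), rep(1, 5))
})

test_that("best partition minimizes squared distance among sampled partitions", {
  L2 <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  bp <- best_partition(L2)
  orc <- brute_best(L2)
  expect_equal(bp$draw, orc$k)
  expect_equal(bp$distance, orc$d[orc$k])
  expect_equal(bp$labels, L2[orc$k, ])
  # argmin contract against every sampled partition
  expect_true(all(bp$distance <= orc$d))
  # single sampled partition: that partition wins
  L1 <- matrix(c(1L, 2L, 2L, 0L), 1, 4)
  expect_equal(best_partition(L1)$labels, L1[1, ])
})

test_that("similarity and best partition match exhaustive enumeration on random traces", {
  set.seed(55)
  for (rep in 1:5) {
    L <- matrix(sample(0:2, 8 * 10, replace = TRUE), 10, 8)
    expect_equal(similarity_matrix(L), brute_similarity(L))
    bp <- best_partition(L)
    orc <- brute_best(L)
    expect_equal(bp$distance, orc$d[orc$k], tolerance = 1e-12)
    expect_equal(bp$draw, orc$k)
  }
})

test_that("best partition is invariant to relabeling components within draws", {
  set.seed(56)
  L <- matrix(sample(1:3, 6 * 8, replace = TRUE), 8, 6)
  perm <- rbind(1:3, c(2, 3, 1), c(3, 1, 2), c(1, 3, 2),
                c(2, 1, 3), c(3, 2, 1), 1:3, c(2, 3, 1))
  Lp <- L
  for (k in 1:8) Lp[k, ] <- perm[k, ][L[k, ]]
  b1 <- best_partition(L); b2 <- best_partition(Lp)
  expect_equal(b1$draw, b2$draw)
  expect_equal(b1$distance, b2$distance, tolerance = 1e-12)
  expect_error(best_partition(matrix(integer(0), 0, 3)), "empty")
})

test_that("cluster-conditional posteriors implement the membership average", {
  # chain that never reallocates: conditional trace equals the raw trace
  beta <- cbind(rnorm(6, 0), rnorm(6, 2))
  alloc <- matrix(rep(c(1L, 1L, 2L), each = 6), 6, 3)
  fit <- toy_fit(beta, alloc, exposed_idx = 1:3, n = 3)
  cb <- c(1L, 1L, 2L)
  cp <- conditional_posteriors(fit, cb, "beta")
  expect_equal(cp[, "1"], beta[, 1])
  expect_equal(cp[, "2"], beta[, 2])
  # two members split between components a and b at one draw: the two-term mean
  alloc2 <- rbind(c(1L, 1L), c(1L, 2L))
  beta2 <- rbind(c(0.5, 3), c(1, 4))
  fit2 <- toy_fit(beta2, alloc2, exposed_idx = 1:2, n = 2)
  cp2 <- conditional_posteriors(fit2, c(1L, 1L), "beta")
  expect_equal(cp2[, 1], c(0.5, (1 + 4) / 2))
  # hand-worked toy: 4 subjects, 3 draws, clusters of sizes 3 and 1
  alloc3 <- rbind(c(1L, 1L, 2L, 2L), c(2L, 1L, 1L, 2L), c(1L, 2L, 1L, 2L))
  beta3 <- rbind(c(10, 20), c(30, 40), c(50, 60))
  fit3 <- toy_fit(beta3, alloc3, exposed_idx = 1:4, n = 4)
  cb3 <- c(1L, 1L, 1L, 2L)
  cp3 <- conditional_posteriors(fit3, cb3, "beta")
  expect_equal(cp3[, "1"], c((10 + 10 + 20) / 3, (40 + 30 + 30) / 3,
                             (50 + 60 + 50) / 3))
  expect_equal(cp3[, "2"], c(20, 40, 60))
  expect_error(conditional_posteriors(fit3, cb3, "lambda"), "cluster-indexed")
})

test_that("DIC and WAIC match hand-computed values on a toy table", {
  # 3 subjects x 4 draws, literal numbers
  logp <- rbind(c(-1.0, -2.0, -0.5),
                c(-1.2, -1.8, -0.7),
                c(-0.9, -2.2, -0.6),
                c(-1.1, -2.0, -0.4))
  logp_hat <- c(-1.0, -1.9, -0.5)
  d <- dic_from_loglik(logp, logp_hat)
  dbar <- mean(-2 * rowSums(logp))
  expect_equal(d$d_bar, dbar)
  expect_equal(d$p_d, dbar - (-2 * sum(logp_hat)))
  expect_equal(d$dic, 2 * dbar - (-2 * sum(logp_hat)))
  w <- waic_from_loglik(logp)
  lppd <- sum(log(colMeans(exp(logp))))
  p_waic <- sum(apply(logp, 2, var))
  expect_equal(w$lppd, lppd)
  expect_equal(w$waic, -2 * (lppd - p_waic))
  # deviance constant across draws: p_D = 0 and DIC = mean deviance
  lp_const <- matrix(rep(c(-1, -2, -3), each = 4), 4, 3)
  d0 <- dic_from_loglik(lp_const, c(-1, -2, -3))
  expect_equal(d0$p_d, 0)
  expect_equal(d0$dic, d0$d_bar)
  # single draw: p_waic = 0 and WAIC = -2 sum log p
  w1 <- waic_from_loglik(matrix(c(-1, -2), 1, 2))
  expect_equal(w1$p_waic, 0)
  expect_equal(w1$waic, -2 * (-3))
})

test_that("information criteria favor the correctly specified cluster number", {
  coh <- simulate_cohort(sim_truth_separated(250, seed = 23))
  cfg <- function(K, s) sampler_config(adapt_batches = 4, batch_size = 25,
                                       burnin = 200, retained = 1000,
                                       thin = 10, K = K, seed = s)
  fit_true <- fit_rprm(coh, config = cfg(4, 1))
  fit_miss <- fit_rprm(coh, config = cfg(2, 1))
  expect_lt(compute_dic(fit_true, coh)$dic, compute_dic(fit_miss, coh)$dic)
  expect_lt(compute_waic(fit_true, coh)$waic,
            compute_waic(fit_miss, coh)$waic)
})

test_that("cluster report flags risk and covariate positions from the intervals", {
  set.seed(60)
  n <- 40
  coh <- simulate_cohort(sim_truth_separated(n, seed = 60))
  ne <- sum(coh$true_label > 0)
  S <- 50
  # cluster 1 interval strictly above 0, cluster 2 straddling 0
  beta <- cbind(runif(S, 0.1, 0.9), runif(S, -0.5, 0.5))
  alloc <- matrix(rep(ifelse(coh$true_label[coh$true_label > 0] > 1, 2L, 1L),
                      each = S), S, ne)
  extra <- list()
  vn <- c("radon", "gamma", "dust", "age")
  for (v in vn) {
    extra[[paste0("mu_", v)]] <- cbind(rnorm(S, 8, 0.05), rnorm(S, -6, 0.05))
    extra[[paste0("sigma_", v)]] <- matrix(0.5, S, 2)
  }
  for (l in 1:5) extra[[paste0("p_job_", l)]] <- matrix(0.2, S, 2)
  for (l in 1:2) extra[[paste0("p_mine_", l)]] <- matrix(0.5, S, 2)
  for (l in 1:4) extra[[paste0("p_dur_", l)]] <- matrix(0.25, S, 2)
  extra$phi <- matrix(0.5, S, 2)
  fit <- toy_fit(beta, alloc, exposed_idx = which(coh$true_label > 0), n = n,
                 extra_draws = extra)
  cb <- ifelse(coh$true_label > 1, 2L, ifelse(coh$true_label == 1, 1L, 0L))
  rep <- cluster_report(fit, coh, cb)
  cl <- rep$clusters
  expect_equal(cl$risk_flag[cl$cluster == 1], "significant high risk")
  expect_equal(cl$risk_flag[cl$cluster == 2], "neutral")
  # mu ~ 8 (medians e^8 ~ 3000) sits above every observed covariate median,
  # mu ~ -6 below
  cov1 <- subset(rep$covariates, cluster == 1 & covariate == "x_radon")
  cov2 <- subset(rep$covariates, cluster == 2 & covariate == "x_radon")
  expect_equal(cov1$position, "above")
  expect_equal(cov2$position, "below")
  # clusters ordered by posterior median excess risk
  expect_equal(cl$cluster, c(2, 1))
})
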