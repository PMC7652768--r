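# Prior specification for the three sub-models. Defaults are the study's
# informative/weakly-informative choices: diffuse normals for the excess
# hazard ratios and the age-at-first-exposure log-mean, external-cohort
# normals for the exposure log-means, informative gammas (national lung
# cancer mortality) for the baseline rates, U[0,100] for lognormal scales,
# Dirichlet(1/2) for category probabilities and U[0.3, 10] for the
# concentration of the stick-breaking process.

#' Prior specification for the profile regression mixture
#'
#' Builds the prior set used by every fitting routine. Normal priors are
#' parametrized by `(mean, variance)` by default (`normal_dialect = "var"`);
#' gamma priors by `(shape, rate)` with time in days (`gamma_dialect =
#' "rate"`): e.g. the default pre-40 prior G(23.7, 4.9e8) has mean
#' `23.7/4.9e8 ~ 4.8e-8` events/day, a plausible young-adult lung-cancer
#' mortality, whereas a scale reading would be absurd. Both dialects can be
#' overridden.
#'
#' @param beta_mean,beta_var normal prior on each cluster excess hazard ratio
#'   (support restricted to `beta > -1` by the likelihood).
#' @param mu_mean,mu_var length-4 named vectors: normal priors on the
#'   lognormal location of radon, gamma, dust and age at first exposure.
#' @param sigma_bounds uniform bounds for all lognormal scale parameters.
#' @param dirichlet_conc symmetric Dirichlet concentration for the job, mine
#'   and duration-class probability vectors.
#' @param lambda_shape,lambda_rate length-4 gamma priors on the baseline
#'   rates (events/day).
#' @param alpha_bounds uniform bounds for the stick-breaking concentration.
#' @param normal_dialect `"var"` or `"sd"`: how `*_var` arguments are read.
#' @param gamma_dialect `"rate"` or `"scale"`: how `lambda_rate` is read.
#' @return An object of class `prior_spec` (normal parameters stored as
#'   variances, gammas as rates).
#' @examples
#' pr <- prior_spec()
#' pr$lambda_shape / pr$lambda_rate  # prior mean baseline rates, events/day
#' @export
prior_spec <- function(beta_mean = 0, beta_var = 1e6,
                       mu_mean = c(radon = -2.3, gamma = 0.10,
                                   dust = 1.01, age = 0),
                       mu_var = c(radon = 8.08, gamma = 2.25,
                                  dust = 11.79, age = 1e6),
                       sigma_bounds = c(0, 100),
                       dirichlet_conc = 0.5,
                       lambda_shape = c(23.7, 35.5, 88.1, 29.7),
                       lambda_rate = c(4.9e8, 2.6e7, 1.6e7, 3.2e6),
                       alpha_bounds = c(0.3, 10),
                       normal_dialect = c("var", "sd"),
                       gamma_dialect = c("rate", "scale")) {
  normal_dialect <- match.arg(normal_dialect)
  gamma_dialect <- match.arg(gamma_dialect)
  if (normal_dialect == "sd") {
    beta_var <- beta_var^2
    mu_var <- mu_var^2
  }
  if (gamma_dialect == "scale") lambda_rate <- 1 / lambda_rate
  stopifnot(beta_var > 0, all(mu_var > 0),
            all(lambda_shape > 0), all(lambda_rate > 0),
            length(lambda_shape) == 4L, length(lambda_rate) == 4L,
            length(mu_mean) == 4L, length(mu_var) == 4L,
            dirichlet_conc > 0,
            length(sigma_bounds) == 2L, sigma_bounds[1] < sigma_bounds[2],
            sigma_bounds[1] >= 0,
            length(alpha_bounds) == 2L, alpha_bounds[1] < alpha_bounds[2],
            alpha_bounds[1] > 0)
  structure(
    list(beta_mean = beta_mean, beta_var = beta_var,
         mu_mean = mu_mean, mu_var = mu_var,
         sigma_bounds = sigma_bounds,
         dirichlet_conc = dirichlet_conc,
         lambda_shape = lambda_shape, lambda_rate = lambda_rate,
         alpha_bounds = alpha_bounds),
    class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Profile-regression prior specification\n")
  cat(sprintf("  beta   ~ N(%g, %g)\n", x$beta_mean, x$beta_var))
  for (v in names(x$mu_mean))
    cat(sprintf("  mu_%-5s ~ N(%g, %g)\n", v, x$mu_mean[[v]], x$mu_var[[v]]))
  cat(sprintf("  sigma  ~ U[%g, %g];  p ~ Dirichlet(%g)\n",
              x$sigma_bounds[1], x$sigma_bounds[2], x$dirichlet_conc))
  cat(sprintf("  lambda ~ G(shape = %s; rate = %s)\n",
              paste(x$lambda_shape, collapse = ", "),
              paste(format(x$lambda_rate), collapse = ", ")))
  cat(sprintf("  alpha  ~ U[%g, %g]\n", x$alpha_bounds[1], x$alpha_bounds[2]))
  invisible(x)
}
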