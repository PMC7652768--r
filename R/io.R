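# Cohort file round-tripping and validation. The on-disk format is plain
# CSV, one row per subject:
#   y                  event/censoring age in days
#   delta              1 = lung-cancer death, 0 = censored / competing death
#   entry_age          entry (hire) age in days
#   x_radon            cumulative radon exposure, WLM
#   x_gamma            cumulative gamma exposure, mSv
#   x_dust             cumulative uranium-dust exposure, kBq m^-3 h
#   age_first_exposure age at first exposure, years (NA for reference rows)
#   job                job type, 1..5
#   mine               mine group, 1 = Herault, 2 = other
#   duration_class     exposure-duration class, 1..4
#   true_label         optional simulator label (0 = reference)

COHORT_COLUMNS <- c("y", "delta", "entry_age", "x_radon", "x_gamma",
                    "x_dust", "age_first_exposure", "job", "mine",
                    "duration_class")

#' Validate a miner cohort table
#'
#' Checks column presence, types, ranges and internal consistency
#' (`y > entry_age >= 0`, `delta` in 0/1, nonnegative exposures, categorical
#' codes within their level sets, exposure-profile covariates present on
#' exposed rows). Errors cite offending row numbers.
#'
#' @param cohort a data.frame with the documented cohort columns.
#' @return the cohort, classed `miner_cohort`, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  miss <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  bad_rows <- function(cond, what) {
    w <- which(cond)
    if (length(w))
      stop(sprintf("invalid cohort rows (%s): %s", what,
                   paste(utils::head(w, 5L), collapse = ", ")))
  }
  num <- c("y", "entry_age", "x_radon", "x_gamma", "x_dust")
  for (v in num) {
    if (!is.numeric(cohort[[v]])) stop("column ", v, " must be numeric")
    bad_rows(!is.finite(cohort[[v]]), paste("non-finite", v))
  }
  bad_rows(!cohort$delta %in% c(0, 1), "delta not in {0,1}")
  bad_rows(cohort$entry_age < 0, "negative entry_age")
  bad_rows(cohort$y <= cohort$entry_age, "y <= entry_age")
  bad_rows(cohort$x_radon < 0 | cohort$x_gamma < 0 | cohort$x_dust < 0,
           "negative exposure")
  exposed <- cohort_exposed(cohort)
  bad_rows(exposed & (!is.finite(cohort$age_first_exposure) |
                        cohort$age_first_exposure <= 0),
           "exposed row without positive age_first_exposure")
  bad_rows(exposed & !cohort$job %in% 1:5, "job outside 1..5")
  bad_rows(exposed & !cohort$mine %in% 1:2, "mine outside 1..2")
  bad_rows(exposed & !cohort$duration_class %in% 1:4,
           "duration_class outside 1..4")
  if (!inherits(cohort, "miner_cohort"))
    class(cohort) <- c("miner_cohort", "data.frame")
  cohort
}

# Reference subjects carry no radiation exposure at all.
cohort_exposed <- function(cohort) {
  cohort$x_radon > 0 | cohort$x_gamma > 0 | cohort$x_dust > 0
}

#' Read a cohort CSV
#'
#' Reads, validates and summarizes a cohort file in the documented format.
#'
#' @param path CSV file path.
#' @param quiet suppress the one-line summary log.
#' @return a validated `miner_cohort` data.frame.
#' @export
read_cohort <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path)
  df <- validate_cohort(df)
  if (!quiet) {
    exp_frac <- mean(cohort_exposed(df))
    message(sprintf(
      "cohort %s: n = %d, events = %d (%.1f%%), exposed = %.1f%%",
      basename(path), nrow(df), sum(df$delta), 100 * mean(df$delta),
      100 * exp_frac))
  }
  df
}

#' Write a cohort CSV
#'
#' @param cohort a `miner_cohort` (or conforming data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write a fitted model's trace to a directory
#'
#' Parameter draws go to one CSV per parameter block, the allocation trace to
#' a compact integer CSV, and run metadata (configuration echo, seed,
#' acceptance rates, non-empty-cluster trace) to a JSON sidecar.
#'
#' @param fit a `prm_fit` from [fit_prm()], [fit_rprm()] or [fit_ehr()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "prm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fit$draws)) {
    utils::write.csv(as.data.frame(fit$draws[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  if (!is.null(fit$alloc))
    utils::write.csv(as.data.frame(fit$alloc),
                     file.path(dir, "alloc.csv"), row.names = FALSE)
  meta <- list(model = fit$model, n = fit$n, C_max = fit$C_max,
               exposed_idx = fit$exposed_idx, seed = fit$seed,
               config = unclass(fit$config),
               accept_rates = as.list(fit$accept_rates),
               nonempty = fit$nonempty)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a fitted model written by [write_fit()]
#'
#' @param dir directory written by [write_fit()].
#' @return a `prm_fit` object.
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  files <- list.files(dir, pattern = "\\.csv$")
  draws <- list()
  alloc <- NULL
  for (f in files) {
    nm <- sub("\\.csv$", "", f)
    m <- as.matrix(utils::read.csv(file.path(dir, f)))
    if (nm == "alloc") alloc <- m else draws[[nm]] <- m
  }
  structure(
    list(model = meta$model, draws = draws, alloc = alloc,
         n = meta$n, C_max = meta$C_max, exposed_idx = meta$exposed_idx,
         seed = meta$seed, config = meta$config,
         accept_rates = unlist(meta$accept_rates),
         nonempty = meta$nonempty),
    class = "prm_fit")
}
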