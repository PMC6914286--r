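#' Configure the subject-resampling bootstrap
#'
#' @param n_boot number of bootstrap replicates (>= 2).  The default 200
#'   keeps small analyses fast; for production inference >= 1999
#'   replicates is recommended so percentile endpoints rest on more than
#'   a handful of order statistics.
#' @param level CI coverage in (0, 1), default 0.95.
#' @param seed integer seed making the resampling fully reproducible.
#' @param stratified resample within arm so every replicate preserves the
#'   per-arm subject counts (default); `FALSE` pools arms.
#' @param max_retries_per_replicate redraws allowed when a replicate's
#'   refit fails to converge before the replicate is counted as failed.
#' @return an object of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(n_boot = 200, level = 0.95, seed = 1L,
                             stratified = TRUE,
                             max_retries_per_replicate = 5) {
  stopifnot(is.numeric(n_boot), length(n_boot) == 1L, n_boot >= 2,
            is.numeric(level), length(level) == 1L, level > 0, level < 1,
            is.numeric(seed), length(seed) == 1L,
            is.logical(stratified), length(stratified) == 1L,
            is.numeric(max_retries_per_replicate),
            max_retries_per_replicate >= 0)
  structure(list(n_boot = as.integer(n_boot), level = level,
                 seed = as.integer(seed), stratified = stratified,
                 max_retries_per_replicate =
                   as.integer(max_retries_per_replicate)),
            class = "bootstrap_config")
}

#' Bootstrap the indirect effect by resampling subjects
#'
#' Cluster bootstrap respecting the repeated-measures dependence: each
#' replicate draws subjects with replacement — every drawn subject
#' carries all of its records, and a subject drawn twice enters as two
#' distinct clusters — stratified by arm so the per-arm counts of the
#' design are preserved.  The c model (outcome ~ group x time) and c'
#' model (additionally adjusting for the mediator) are refit on each
#' replicate and the indirect effect c - c' recorded.  Replicates whose
#' refit fails to converge are redrawn up to
#' `max_retries_per_replicate` times, then counted as failed; more than
#' 10% failures raises a warning.  Given the same data and seed the
#' sample vector is identical.
#'
#' @inheritParams estimate_paths
#' @param config a [bootstrap_config()].
#' @param point_estimate optional full-data indirect effect; computed
#'   from the full data when omitted.
#' @return an object of class `"bootstrap_distribution"`: `samples`
#'   (successful replicates' indirect effects), `n_failed`,
#'   `point_estimate`.
#' @export
bootstrap_indirect <- function(dataset, mediator, outcome,
                               config = bootstrap_config(),
                               point_estimate = NULL,
                               covariance_mode = "compound_symmetry",
                               method = "REML") {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(config, "bootstrap_config"))
  wide <- pivot_measurements(dataset, c(outcome, mediator))
  wide <- wide[!is.na(wide[[outcome]]), , drop = FALSE]
  spec_c <- model_spec(outcome, covariance_mode = covariance_mode,
                       method = method)
  spec_cp <- model_spec(outcome, mediator = mediator,
                        covariance_mode = covariance_mode, method = method)

  if (is.null(point_estimate)) {
    full_c <- fit_lmm_frame(wide, spec_c)
    full_cp <- fit_lmm_frame(wide[!is.na(wide[[mediator]]), , drop = FALSE],
                             spec_cp)
    if (!full_c$converged || !full_cp$converged) {
      stop("full-data c/c' model did not converge", call. = FALSE)
    }
    point_estimate <- indirect_effect(difference_of_change(full_c, "c"),
                                      difference_of_change(full_cp,
                                                           "c_prime"))
  }

  subj <- unique(wide$subject_id)
  arm_of <- wide$arm[match(subj, wide$subject_id)]
  rows_of <- split(seq_len(nrow(wide)), factor(wide$subject_id,
                                               levels = subj))
  pool_control <- which(arm_of == 0L)
  pool_exercise <- which(arm_of == 1L)

  one_replicate <- function() {
    if (config$stratified) {
      picks <- c(pool_control[sample.int(length(pool_control),
                                         length(pool_control),
                                         replace = TRUE)],
                 pool_exercise[sample.int(length(pool_exercise),
                                          length(pool_exercise),
                                          replace = TRUE)])
    } else {
      picks <- sample.int(length(subj), length(subj), replace = TRUE)
    }
    rows <- rows_of[picks]
    nd <- wide[unlist(rows, use.names = FALSE), , drop = FALSE]
    # subjects drawn twice must be distinct clusters in the refit
    nd$subject_id <- rep(sprintf("b%04d", seq_along(picks)),
                         lengths(rows))
    fit_c <- fit_lmm_frame(nd, spec_c)
    if (!fit_c$converged) return(NULL)
    nd_m <- nd[!is.na(nd[[mediator]]), , drop = FALSE]
    fit_cp <- fit_lmm_frame(nd_m, spec_cp)
    if (!fit_cp$converged) return(NULL)
    co_c <- fit_c$coefficients
    co_cp <- fit_cp$coefficients
    co_c$estimate[co_c$term == "group_x_time"] -
      co_cp$estimate[co_cp$term == "group_x_time"]
  }

  set.seed(config$seed)
  samples <- numeric(0)
  n_failed <- 0L
  for (i in seq_len(config$n_boot)) {
    value <- NULL
    for (attempt in seq_len(1L + config$max_retries_per_replicate)) {
      value <- one_replicate()
      if (!is.null(value)) break
    }
    if (is.null(value)) n_failed <- n_failed + 1L else
      samples <- c(samples, value)
  }
  if (n_failed > 0.1 * config$n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, config$n_boot), call. = FALSE)
  }
  structure(list(samples = samples, n_failed = n_failed,
                 point_estimate = point_estimate, config = config),
            class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf(
    "Bootstrap distribution of the indirect effect: %d replicates%s\n",
    length(x$samples),
    if (x$n_failed > 0) sprintf(" (%d failed)", x$n_failed) else ""))
  cat(sprintf("  point estimate %.3f; sample mean %.3f, SD %.3f\n",
              x$point_estimate, mean(x$samples), stats::sd(x$samples)))
  invisible(x)
}

#' Percentile confidence interval from bootstrap samples
#'
#' Empirical `(1-level)/2` and `(1+level)/2` quantiles with linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param samples numeric vector of bootstrap statistics (>= 2 values).
#' @param level coverage in (0, 1).
#' @return length-2 numeric `c(lower, upper)`.
#' @export
percentile_ci <- function(samples, level = 0.95) {
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("percentile_ci requires at least 2 samples", call. = FALSE)
  }
  stopifnot(level > 0, level < 1)
  stats::quantile(samples, probs = c((1 - level) / 2, (1 + level) / 2),
                  type = 7, names = FALSE)
}

#' Declare mediation significant when the CI excludes zero
#'
#' Zero must lie strictly outside the interval; an endpoint exactly at
#' zero does not count as exclusion.
#'
#' @param ci length-2 interval `c(lower, upper)`.
#' @return logical scalar.
#' @export
decide_significance <- function(ci) {
  stopifnot(is.numeric(ci), length(ci) == 2L, ci[1] <= ci[2])
  ci[1] > 0 || ci[2] < 0
}

# Deterministic per-pair seed substream: adding or removing one
# mediator-outcome pair never perturbs another pair's resampling.
substream_seed <- function(master_seed, mediator, outcome) {
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(paste(mediator, outcome, sep = "\r"))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
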