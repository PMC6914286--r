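#' Construct a path estimate
#'
#' One Baron-Kenny path coefficient with Wald-normal inference: `a`
#' (group effect on the mediator's change), `b` (mediator-outcome
#' association), `c` (total group effect on the outcome's change) or
#' `c_prime` (direct group effect adjusting for the mediator).  Paths a,
#' c and c' are read from the group-by-time term of their model; path b
#' from the mediator term of the multivariable model.
#'
#' @param path label: `"a"`, `"b"`, `"c"`, `"c_prime"`, or a free label.
#' @param beta point estimate.
#' @param se standard error (> 0).
#' @param p_value two-sided P value in `[0, 1]`.
#' @param ci95 length-2 interval bracketing `beta`.
#' @param term name of the model coefficient it was read from.
#' @return an object of class `"path_estimate"`.
#' @export
path_estimate <- function(path, beta, se, p_value, ci95,
                          term = "group_x_time") {
  stopifnot(is.numeric(beta), length(beta) == 1L,
            is.numeric(se), length(se) == 1L,
            is.numeric(p_value), length(p_value) == 1L,
            is.numeric(ci95), length(ci95) == 2L)
  if (!is.na(se) && se <= 0) stop("se must be positive", call. = FALSE)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  if (!any(is.na(ci95)) && !is.na(beta) &&
      (ci95[1] > beta || ci95[2] < beta)) {
    stop("ci95 must bracket the estimate", call. = FALSE)
  }
  structure(list(path = path, beta = beta, se = se, p_value = p_value,
                 ci95 = ci95, term = term),
            class = "path_estimate")
}

#' @export
print.path_estimate <- function(x, ...) {
  cat(sprintf("path %s: beta=%.2f (SE %.2f), 95%% CI %.2f to %.2f, P=%s\n",
              x$path, x$beta, x$se, x$ci95[1], x$ci95[2],
              format_p(x$p_value)))
  invisible(x)
}

#' Estimate the four mediation paths for one mediator-outcome pair
#'
#' Fits three repeated-measures mixed models and reads off the
#' Baron-Kenny paths:
#' * path a — group-by-time coefficient of the mediator model;
#' * path c — group-by-time coefficient of the outcome model;
#' * path c' — group-by-time coefficient of the outcome model that
#'   additionally adjusts for the mediator's concurrent (time-varying)
#'   value;
#' * path b — by default the mediator coefficient of that same
#'   multivariable model (adjusted for group and time); with
#'   `b_adjusted = FALSE`, the mediator coefficient of an outcome model
#'   containing only time and the mediator.
#'
#' The machinery is direction-agnostic: swapping the `mediator` and
#' `outcome` arguments runs the reverse (exploratory) mediation with no
#' other change.
#'
#' @param dataset a `"trial_dataset"` with transforms applied.
#' @param mediator,outcome variable names, both measured at both
#'   timepoints.
#' @param b_adjusted read path b from the group-adjusted multivariable
#'   model (default) or from an unadjusted mediator-outcome model.
#' @param covariance_mode,method passed to [model_spec()].
#' @return an object of class `"mediation_paths"`: list with elements
#'   `a`, `b`, `c`, `c_prime` (each a [path_estimate()]) plus the three
#'   underlying `"lmm_fit"` objects in `fits`.
#' @export
estimate_paths <- function(dataset, mediator, outcome, b_adjusted = TRUE,
                           covariance_mode = "compound_symmetry",
                           method = "REML") {
  stopifnot(inherits(dataset, "trial_dataset"))
  fit_m <- fit_lmm(dataset, model_spec(mediator,
                                       covariance_mode = covariance_mode,
                                       method = method))
  fit_y <- fit_lmm(dataset, model_spec(outcome,
                                       covariance_mode = covariance_mode,
                                       method = method))
  fit_ym <- fit_lmm(dataset, model_spec(outcome, mediator = mediator,
                                        covariance_mode = covariance_mode,
                                        method = method))
  check_conv <- function(fit, which) {
    if (!isTRUE(fit$converged)) {
      stop("model for path ", which, " did not converge (outcome '",
           fit$spec$outcome, "')", call. = FALSE)
    }
  }
  check_conv(fit_m, "a")
  check_conv(fit_y, "c")
  check_conv(fit_ym, "c'/b")

  a <- extract_term(fit_m, "group_x_time", path = "a")
  c_est <- extract_term(fit_y, "group_x_time", path = "c")
  c_prime <- extract_term(fit_ym, "group_x_time", path = "c_prime")
  if (b_adjusted) {
    b <- extract_term(fit_ym, "mediator", path = "b")
  } else {
    wide <- pivot_measurements(dataset, c(outcome, mediator))
    wide <- wide[!is.na(wide[[outcome]]) & !is.na(wide[[mediator]]), ,
                 drop = FALSE]
    fml <- stats::as.formula(paste0("`", outcome, "` ~ timepoint + `",
                                    mediator, "` + (1 | subject_id)"))
    res <- fit_lmer(fml, wide, reml = method == "REML")
    if (!res$converged) {
      stop("model for path b (unadjusted) did not converge", call. = FALSE)
    }
    i <- match(mediator, names(res$est))
    z <- res$est[[i]] / res$se[[i]]
    b <- path_estimate("b", res$est[[i]], res$se[[i]],
                       2 * stats::pnorm(-abs(z)),
                       res$est[[i]] + c(-1, 1) * stats::qnorm(0.975) *
                         res$se[[i]],
                       term = "mediator")
  }
  structure(list(a = a, b = b, c = c_est, c_prime = c_prime,
                 mediator = mediator, outcome = outcome,
                 b_adjusted = b_adjusted,
                 fits = list(mediator = fit_m, outcome = fit_y,
                             outcome_mediator = fit_ym)),
            class = "mediation_paths")
}

#' @export
print.mediation_paths <- function(x, ...) {
  cat(sprintf("Mediation paths: %s -> %s\n", x$mediator, x$outcome))
  for (p in list(x$a, x$b, x$c, x$c_prime)) {
    cat("  "); print(p)
  }
  invisible(x)
}

#' Screen a mediator with the causal-steps significance gate
#'
#' A mediation test proceeds only when paths a, b and c are all
#' significant at the gate level, by strict inequality (`P < alpha`;
#' P exactly equal to alpha fails).  The default alpha of 0.10 is the
#' liberal screen appropriate to small pilot trials.
#'
#' @param paths a `"mediation_paths"` object (or list with elements
#'   `a`, `b`, `c` carrying `p_value`s).
#' @param alpha gate significance level in (0, 1).
#' @return an object of class `"gate_decision"`: `passed_a`, `passed_b`,
#'   `passed_c`, `alpha`, `proceed` (the conjunction).
#' @export
gate <- function(paths, alpha = 0.10) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  p_of <- function(x) {
    if (inherits(x, "path_estimate")) x$p_value else as.numeric(x)
  }
  passed_a <- p_of(paths$a) < alpha
  passed_b <- p_of(paths$b) < alpha
  passed_c <- p_of(paths$c) < alpha
  structure(list(passed_a = passed_a, passed_b = passed_b,
                 passed_c = passed_c, alpha = alpha,
                 proceed = passed_a && passed_b && passed_c),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  mark <- function(p) if (p) "pass" else "fail"
  cat(sprintf("Gate at P<%.2g: a %s, b %s, c %s -> %s\n", x$alpha,
              mark(x$passed_a), mark(x$passed_b), mark(x$passed_c),
              if (x$proceed) "test mediation" else "do not test"))
  invisible(x)
}

#' Indirect effect by the difference-of-coefficients method
#'
#' The mediated portion of the total effect: the drop from the total
#' group effect (path c) to the direct effect adjusting for the mediator
#' (path c').  In the linear Gaussian model without exposure-mediator
#' interaction this equals the product-of-coefficients a*b.
#'
#' @param c_est,cprime_est [path_estimate()]s for c and c' from the same
#'   dataset.
#' @return numeric scalar, `c - c'`.
#' @export
indirect_effect <- function(c_est, cprime_est) {
  b_of <- function(x) if (inherits(x, "path_estimate")) x$beta else
    as.numeric(x)
  b_of(c_est) - b_of(cprime_est)
}

#' Full mediation analysis for one mediator-outcome pair
#'
#' Estimates paths a, b, c, c'; applies the significance gate; and, when
#' the gate passes, bootstraps the indirect effect c - c' by resampling
#' subjects (see [bootstrap_indirect()]) and forms the percentile CI.
#' Gate-failed pairs report their paths but no CI, mirroring the practice
#' of not testing mediation when the preconditions fail.
#'
#' @inheritParams estimate_paths
#' @param alpha gate level (default 0.10).
#' @param boot a [bootstrap_config()]; its `seed` governs the resampling.
#' @return an object of class `"mediation_result"`: the pair's names,
#'   `paths`, `gate`, `indirect` (c - c'), and — when gated in —
#'   `boot_ci95`, `n_boot`, `n_failed`, `seed` and `significant`
#'   (CI strictly excludes zero).
#' @export
mediate <- function(dataset, mediator, outcome, alpha = 0.10,
                    boot = bootstrap_config(), b_adjusted = TRUE,
                    covariance_mode = "compound_symmetry",
                    method = "REML") {
  paths <- estimate_paths(dataset, mediator, outcome,
                          b_adjusted = b_adjusted,
                          covariance_mode = covariance_mode,
                          method = method)
  g <- gate(paths, alpha = alpha)
  ind <- indirect_effect(paths$c, paths$c_prime)
  res <- list(mediator = mediator, outcome = outcome, paths = paths,
              gate = g, indirect = ind, boot_ci95 = NULL,
              n_boot = NA_integer_, n_failed = NA_integer_,
              seed = boot$seed, level = boot$level, significant = NA)
  if (g$proceed) {
    dist <- bootstrap_indirect(dataset, mediator, outcome, config = boot,
                               point_estimate = ind,
                               covariance_mode = covariance_mode,
                               method = method)
    ci <- percentile_ci(dist$samples, level = boot$level)
    res$boot_ci95 <- ci
    res$n_boot <- length(dist$samples)
    res$n_failed <- dist$n_failed
    res$significant <- decide_significance(ci)
  }
  structure(res, class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s\n", x$mediator, x$outcome))
  print(x$gate)
  cat(sprintf("  indirect effect (c - c'): %.2f\n", x$indirect))
  if (!is.null(x$boot_ci95)) {
    cat(sprintf("  bootstrap %d%% CI: %.2f to %.2f (%d replicates%s) -> %s\n",
                round(100 * x$level),
                x$boot_ci95[1], x$boot_ci95[2], x$n_boot,
                if (x$n_failed > 0)
                  sprintf(", %d failed", x$n_failed) else "",
                if (x$significant) "mediation" else "no mediation"))
  } else {
    cat("  gate not passed: mediation not tested\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
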