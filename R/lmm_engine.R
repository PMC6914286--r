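#' Specify a repeated-measures mixed model
#'
#' The path models all share one structure: fixed effects for group, time
#' and group-by-time (plus, for the multivariable path b / c' model, the
#' time-varying mediator), with a subject-level random intercept.  The
#' group-by-time coefficient is the difference-of-change contrast: the
#' between-arm difference in baseline-to-week-12 change.
#'
#' `covariance_mode` chooses the residual structure.  With only two
#' timepoints an "unstructured" marginal covariance on top of a random
#' intercept is not identifiable, so the default is compound symmetry
#' (random intercept + iid residual); `"heteroscedastic_time"` relaxes
#' this to timepoint-specific residual variances.
#'
#' @param outcome name of the modelled variable.
#' @param mediator optional name of a time-varying mediator covariate
#'   (present for the path b / c' model only).
#' @param covariance_mode `"compound_symmetry"` (default) or
#'   `"heteroscedastic_time"`.
#' @param method `"REML"` (default) or `"ML"`.  AIC comparisons are only
#'   exposed for ML fits.
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(outcome, mediator = NULL,
                       covariance_mode = c("compound_symmetry",
                                           "heteroscedastic_time"),
                       method = c("REML", "ML")) {
  covariance_mode <- match.arg(covariance_mode)
  method <- match.arg(method)
  stopifnot(is.character(outcome), length(outcome) == 1L)
  if (!is.null(mediator)) stopifnot(is.character(mediator),
                                    length(mediator) == 1L)
  fixed_terms <- c("intercept", "group", "time", "group_x_time",
                   if (!is.null(mediator)) "mediator")
  structure(list(outcome = outcome, mediator = mediator,
                 fixed_terms = fixed_terms,
                 covariance_mode = covariance_mode, method = method),
            class = "model_spec")
}

#' Fit a subject-level random-intercept mixed model
#'
#' Fits the model declared by `spec` to the (transformed) dataset by
#' restricted maximum likelihood (or full ML), using `lme4::lmer` for the
#' compound-symmetry mode and `nlme::lme` with timepoint-stratified
#' residual variances for the heteroscedastic mode.  Rows with a missing
#' outcome (or missing mediator, when one is in the model) are dropped —
#' available-case analysis, unbiased under missingness at random.
#' Inference on fixed effects is Wald-normal: z statistics, two-sided P
#' values and 95% CIs from the estimated standard errors.
#'
#' Non-convergence is flagged (`converged = FALSE`), never silently
#' worked around; estimates from a non-converged optimizer are retained
#' for inspection but downstream contrast extraction refuses them.
#' Singular fits (a random-intercept variance estimated at zero) are
#' legitimate boundary estimates and count as converged.
#'
#' @param dataset a `"trial_dataset"` with transforms already applied
#'   (or none declared).
#' @param spec a [model_spec()].
#' @return an object of class `"lmm_fit"`: list with `coefficients` (data
#'   frame: term, estimate, se, z, p_value, ci_lower, ci_upper),
#'   `variance_components` (`tau2`, `sigma2` — the latter length 2 under
#'   heteroscedastic_time), `n_subjects`, `n_observations`, `converged`,
#'   `loglik`, `aic` (ML only, else `NA`), and the originating `spec`.
#' @export
fit_lmm <- function(dataset, spec) {
  stopifnot(inherits(dataset, "trial_dataset"), inherits(spec, "model_spec"))
  if (!dataset$transformed &&
      any(dataset$transforms == "log")) {
    stop("apply_transforms() must be called before model fitting",
         call. = FALSE)
  }
  vars <- c(spec$outcome, spec$mediator)
  wide <- pivot_measurements(dataset, vars)
  wide <- wide[!is.na(wide[[spec$outcome]]), , drop = FALSE]
  if (!is.null(spec$mediator)) {
    wide <- wide[!is.na(wide[[spec$mediator]]), , drop = FALSE]
  }
  if (nrow(wide) == 0L) {
    stop("no non-missing observations of '", spec$outcome, "'",
         call. = FALSE)
  }
  n_per_arm <- table(factor(wide$arm[wide$timepoint == 0L], levels = 0:1))
  if (any(n_per_arm < 2L)) {
    stop("need at least 2 subjects per arm with baseline data",
         call. = FALSE)
  }
  fit_lmm_frame(wide, spec)
}

# Core fitter on a prebuilt wide frame; also the bootstrap's inner loop.
fit_lmm_frame <- function(wide, spec) {
  med <- spec$mediator
  rhs <- "arm * timepoint"
  if (!is.null(med)) rhs <- paste0(rhs, " + `", med, "`")
  res <- tryCatch({
    if (spec$covariance_mode == "compound_symmetry") {
      fml <- stats::as.formula(paste0("`", spec$outcome, "` ~ ", rhs,
                                      " + (1 | subject_id)"))
      fit_lmer(fml, wide, reml = spec$method == "REML")
    } else {
      fml <- stats::as.formula(paste0("`", spec$outcome, "` ~ ", rhs))
      fit_lme_het(fml, wide, method = spec$method)
    }
  }, error = function(e) NULL)
  term_map <- c("(Intercept)" = "intercept", "arm" = "group",
                "timepoint" = "time", "arm:timepoint" = "group_x_time")
  if (!is.null(med)) term_map[[med]] <- "mediator"
  if (is.null(res)) {
    # optimizer raised an error: flagged fit, estimates unavailable
    est <- stats::setNames(rep(NA_real_, length(term_map)), names(term_map))
    res <- list(est = est, se = est, tau2 = NA_real_, sigma2 = NA_real_,
                loglik = NA_real_, aic = NA_real_, converged = FALSE)
  }
  terms <- unname(term_map[names(res$est)])
  z <- res$est / res$se
  coefficients <- data.frame(
    term = terms, estimate = unname(res$est), se = unname(res$se),
    z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
    ci_lower = unname(res$est - stats::qnorm(0.975) * res$se),
    ci_upper = unname(res$est + stats::qnorm(0.975) * res$se),
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefficients,
         variance_components = list(tau2 = res$tau2, sigma2 = res$sigma2),
         n_subjects = length(unique(wide$subject_id)),
         n_observations = nrow(wide),
         converged = res$converged,
         loglik = res$loglik,
         aic = if (spec$method == "ML") res$aic else NA_real_,
         spec = spec),
    class = "lmm_fit"
  )
}

# Relative likelihood tolerance 1e-8, at most 200 evaluations; optimizer
# failures are surfaced through `converged`, never retried on altered data.
lmer_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    optCtrl = list(ftol_rel = 1e-8, maxeval = 200))
}

fit_lmer <- function(fml, wide, reml) {
  conv_warning <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = wide, REML = reml, control = lmer_ctrl()),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        conv_warning <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  converged <- !conv_warning && isTRUE(fit@optinfo$conv$opt == 0L)
  # a residual variance at numerical zero (perfect within-subject fit) is
  # a boundary solution: the profiled objective decreases without a finite
  # optimum, the optimizer stops on its evaluation budget, and the fixed
  # effects are exact.  Treated as converged-at-boundary, like a zero
  # random-intercept variance.
  if (!converged) {
    y <- lme4::getME(fit, "y")
    if (stats::sigma(fit)^2 <= 1e-8 * max(stats::var(y), 1e-8)) {
      converged <- TRUE
    }
  }
  vc <- lme4::VarCorr(fit)
  list(est = lme4::fixef(fit),
       se = sqrt(diag(as.matrix(stats::vcov(fit)))),
       tau2 = as.numeric(vc$subject_id[1L, 1L]),
       sigma2 = stats::sigma(fit)^2,
       loglik = as.numeric(stats::logLik(fit)),
       aic = stats::AIC(fit),
       converged = converged)
}

fit_lme_het <- function(fml, wide, method) {
  wide$.tp <- factor(wide$timepoint, levels = 0:1)
  fit <- nlme::lme(fml, random = ~ 1 | subject_id, data = wide,
                   weights = nlme::varIdent(form = ~ 1 | .tp),
                   method = method,
                   control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                              returnObject = FALSE))
  est <- nlme::fixef(fit)
  vc <- nlme::VarCorr(fit)
  sigma2_base <- fit$sigma^2
  ratios <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                        allCoef = TRUE)
  sigma2 <- sigma2_base * unname(ratios[order(names(ratios))])^2
  names(sigma2) <- c("baseline", "week12")
  list(est = est,
       se = sqrt(diag(as.matrix(stats::vcov(fit)))),
       tau2 = as.numeric(vc["(Intercept)", "Variance"]),
       sigma2 = sigma2,
       loglik = as.numeric(stats::logLik(fit)),
       aic = stats::AIC(fit),
       converged = TRUE)
}

#' Extract the difference-of-change contrast from a fitted model
#'
#' Returns the group-by-time coefficient — the between-arm difference in
#' baseline-to-week-12 change — as a path estimate with Wald-normal SE,
#' two-sided P value and 95% CI.
#'
#' @param fit an [fit_lmm()] result; must have converged.
#' @param path label to attach (`"a"`, `"c"`, `"c_prime"`, or a free
#'   label such as the default `"did"`).
#' @return an object of class `"path_estimate"`.
#' @export
difference_of_change <- function(fit, path = "did") {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) {
    stop("model did not converge; refusing to extract contrast",
         call. = FALSE)
  }
  extract_term(fit, "group_x_time", path = path)
}

extract_term <- function(fit, term, path) {
  co <- fit$coefficients
  row <- co[co$term == term, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("term '", term, "' not present in fit", call. = FALSE)
  }
  path_estimate(path = path, beta = row$estimate, se = row$se,
                p_value = row$p_value,
                ci95 = c(row$ci_lower, row$ci_upper), term = term)
}

#' Compare two ML fits by AIC
#'
#' Model-selection by Akaike Information Criterion; only meaningful for
#' full-ML fits (REML likelihoods of models with different fixed effects
#' are not comparable), so REML fits are refused.
#'
#' @param fit1,fit2 [fit_lmm()] results with `method = "ML"`.
#' @return named numeric: each fit's AIC and their difference
#'   (`fit1 - fit2`; negative favours `fit1`).
#' @export
compare_aic <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "lmm_fit"), inherits(fit2, "lmm_fit"))
  if (is.na(fit1$aic) || is.na(fit2$aic)) {
    stop("AIC comparison requires ML fits (method = \"ML\")", call. = FALSE)
  }
  c(aic1 = fit1$aic, aic2 = fit2$aic, delta = fit1$aic - fit2$aic)
}

#' Serialize a model summary
#'
#' @param fit an [fit_lmm()] result.
#' @param format `"text"` (2-decimal human-readable lines) or `"json"`.
#' @return a character scalar.
#' @export
format_lmm <- function(fit, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    return(jsonlite::toJSON(list(
      outcome = fit$spec$outcome,
      method = fit$spec$method,
      covariance_mode = fit$spec$covariance_mode,
      coefficients = fit$coefficients,
      variance_components = fit$variance_components,
      n_subjects = fit$n_subjects, n_observations = fit$n_observations,
      converged = fit$converged, loglik = fit$loglik
    ), auto_unbox = TRUE, digits = NA))
  }
  co <- fit$coefficients
  lines <- c(
    sprintf("Mixed model for '%s' (%s, %s): %d subjects, %d observations%s",
            fit$spec$outcome, fit$spec$method, fit$spec$covariance_mode,
            fit$n_subjects, fit$n_observations,
            if (fit$converged) "" else " [NOT CONVERGED]"),
    sprintf("  %-14s %8s %7s %16s %7s", "term", "beta", "SE", "95% CI", "P"),
    sprintf("  %-14s %8.2f %7.2f (%6.2f, %6.2f) %7s",
            co$term, co$estimate, co$se, co$ci_lower, co$ci_upper,
            format_p(co$p_value))
  )
  paste(lines, collapse = "\n")
}

format_p <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(format_lmm(x, "text"), "\n")
  invisible(x)
}
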