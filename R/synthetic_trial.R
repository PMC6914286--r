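#' Specify a synthetic two-arm, two-timepoint trial
#'
#' Generative parameters for a trial with the structure of a small
#' 12-week exercise RCT: 43 exercise / 44 control subjects, measurements
#' at baseline and week 12, a subject-level random intercept, and one
#' dropout per arm missing at random.  The structural model for subject
#' i in arm g (0/1) at timepoint t (0/1) is
#'
#' \deqn{M_{it} = \mu_M + \gamma_M t + a\, g t + u_i + \epsilon_{it}}
#' \deqn{Y_{it} = \mu_Y + \gamma_Y t + d\, g t + b\, M_{it} + v_i + \eta_{it}}
#'
#' with `u ~ N(0, tau2_m)`, `eps ~ N(0, sigma2_m)` and analogously for
#' the outcome.  The implied total group effect on the outcome's change
#' is `c = direct_effect + a_effect * b_effect`, and with no
#' exposure-mediator interaction and Gaussian errors the
#' difference-of-coefficients indirect effect c - c' coincides with the
#' product a*b — the regime in which the pipeline's product-vs-difference
#' consistency checks are valid.
#'
#' Default scale parameters echo the published summaries of the
#' emulated trial (mediator T-score mean 55.2, outcome mean 45.4, total
#' SD about 8, split 58/6 between subject and residual variance so the
#' difference-of-change SE lands near the published 0.7); they make
#' synthetic output comparable in scale, nothing more.  Because the
#' outcome equation adds `b * M`, the realized outcome baseline mean is
#' `outcome_baseline_mean + b_effect * mediator_baseline_mean`.
#'
#' @param n_exercise,n_control subjects per arm (defaults 43, 44).
#' @param a_effect arm effect on the mediator's change (default -1.5,
#'   e.g. an anxiety T-score reduction).
#' @param b_effect mediator-outcome slope (default 0.4).
#' @param direct_effect arm effect on the outcome's change net of the
#'   mediator (default 0).
#' @param mediator_baseline_mean,outcome_baseline_mean baseline means
#'   (T-score scale; defaults 55.2 and 45.4).
#' @param tau2_m,tau2_y subject random-intercept variances (default 58).
#' @param sigma2_m,sigma2_y residual variances (default 6).  Together with
#'   the default `tau2` values these give a total SD of 8 and a
#'   difference-of-change SE near 0.73 at the default sample size,
#'   matching the scale of the published per-arm SDs and path-a SEs of
#'   the emulated trial.
#' @param time_trend_m,time_trend_y secular baseline-to-week-12 change in
#'   the control arm (default 0).
#' @param biomarker_mode emit strictly positive log-normal values: the
#'   linear model above holds on the natural-log scale and values are
#'   exponentiated (so declare `transforms = "log"` downstream).
#' @param heavy_tailed replace Gaussian errors by scaled t (4 df) —
#'   robustness exercises only.
#' @param dropout_per_arm subjects per arm losing all week-12 records
#'   (default 1, i.e. 98% retention at the default sample size).
#' @param mediator_name,outcome_name variable names in the emitted
#'   dataset.
#' @param extra_null_vars optional named list of additional variables
#'   unrelated to arm, mediator and outcome; each element a list with
#'   fields `mean`, `tau2`, `sigma2` and optional `biomarker = TRUE`.
#'   Useful for composing multi-mediator screens with known nulls.
#' @param seed integer seed.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_exercise = 43, n_control = 44,
                           a_effect = -1.5, b_effect = 0.4,
                           direct_effect = 0,
                           mediator_baseline_mean = 55.2,
                           outcome_baseline_mean = 45.4,
                           tau2_m = 58, tau2_y = 58,
                           sigma2_m = 6, sigma2_y = 6,
                           time_trend_m = 0, time_trend_y = 0,
                           biomarker_mode = FALSE, heavy_tailed = FALSE,
                           dropout_per_arm = 1,
                           mediator_name = "mediator",
                           outcome_name = "outcome",
                           extra_null_vars = list(), seed = 1L) {
  stopifnot(n_exercise >= 2, n_control >= 2,
            tau2_m >= 0, tau2_y >= 0, sigma2_m >= 0, sigma2_y >= 0,
            dropout_per_arm >= 0,
            dropout_per_arm < min(n_exercise, n_control))
  if (mediator_name == outcome_name) {
    stop("mediator and outcome need distinct names", call. = FALSE)
  }
  structure(list(n_exercise = as.integer(n_exercise),
                 n_control = as.integer(n_control),
                 a_effect = a_effect, b_effect = b_effect,
                 direct_effect = direct_effect,
                 mediator_baseline_mean = mediator_baseline_mean,
                 outcome_baseline_mean = outcome_baseline_mean,
                 tau2_m = tau2_m, tau2_y = tau2_y,
                 sigma2_m = sigma2_m, sigma2_y = sigma2_y,
                 time_trend_m = time_trend_m, time_trend_y = time_trend_y,
                 biomarker_mode = isTRUE(biomarker_mode),
                 heavy_tailed = isTRUE(heavy_tailed),
                 dropout_per_arm = as.integer(dropout_per_arm),
                 mediator_name = mediator_name,
                 outcome_name = outcome_name,
                 extra_null_vars = extra_null_vars,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# t(4) scaled to unit variance, or standard normal
rerror <- function(n, heavy) {
  if (heavy) stats::rt(n, df = 4) / sqrt(2) else stats::rnorm(n)
}

#' Generate a synthetic trial dataset
#'
#' Draws one trial from the generative model of [synthetic_spec()] and
#' returns it as a long-format [trial_dataset()] with roles and (in
#' biomarker mode) log transforms declared.  Dropout is applied last via
#' [apply_dropout()], removing all week-12 records of the chosen
#' subjects.  Identical spec (including seed) gives an identical
#' dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return a `"trial_dataset"`.
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_control + spec$n_exercise
  subj <- sprintf("S%03d", seq_len(n))
  arm <- c(rep(0L, spec$n_control), rep(1L, spec$n_exercise))

  u <- sqrt(spec$tau2_m) * stats::rnorm(n)
  v <- sqrt(spec$tau2_y) * stats::rnorm(n)
  rows <- vector("list", 0L)
  m_mat <- matrix(NA_real_, n, 2)
  y_mat <- matrix(NA_real_, n, 2)
  for (t in 0:1) {
    eps <- sqrt(spec$sigma2_m) * rerror(n, spec$heavy_tailed)
    eta <- sqrt(spec$sigma2_y) * rerror(n, spec$heavy_tailed)
    m <- spec$mediator_baseline_mean + spec$time_trend_m * t +
      spec$a_effect * arm * t + u + eps
    y <- spec$outcome_baseline_mean + spec$time_trend_y * t +
      spec$direct_effect * arm * t + spec$b_effect * m + v + eta
    m_mat[, t + 1L] <- m
    y_mat[, t + 1L] <- y
  }
  emit <- function(values, name, t) {
    data.frame(subject_id = subj, arm = arm, timepoint = t,
               variable = name, value = values, stringsAsFactors = FALSE)
  }
  tf_m <- if (spec$biomarker_mode) exp else identity
  for (t in 0:1) {
    rows[[length(rows) + 1L]] <- emit(tf_m(m_mat[, t + 1L]),
                                      spec$mediator_name, t)
    rows[[length(rows) + 1L]] <- emit(y_mat[, t + 1L],
                                      spec$outcome_name, t)
  }

  roles <- stats::setNames(c("mediator", "outcome"),
                           c(spec$mediator_name, spec$outcome_name))
  transforms <- character(0)
  if (spec$biomarker_mode) {
    transforms <- stats::setNames("log", spec$mediator_name)
  }
  for (nm in names(spec$extra_null_vars)) {
    ev <- spec$extra_null_vars[[nm]]
    w <- sqrt(ev$tau2) * stats::rnorm(n)
    tf <- if (isTRUE(ev$biomarker)) exp else identity
    for (t in 0:1) {
      vals <- ev$mean + w + sqrt(ev$sigma2) * stats::rnorm(n)
      rows[[length(rows) + 1L]] <- emit(tf(vals), nm, t)
    }
    roles[nm] <- "mediator"
    if (isTRUE(ev$biomarker)) transforms[nm] <- "log"
  }

  ds <- trial_dataset(do.call(rbind, rows), roles = roles,
                      transforms = transforms)
  if (spec$dropout_per_arm > 0L) {
    ds <- apply_dropout(ds, per_arm = spec$dropout_per_arm,
                        seed = spec$seed + 1L)
  }
  ds
}

#' Remove week-12 records of randomly chosen subjects
#'
#' Emulates loss to follow-up: `per_arm` subjects per arm, chosen
#' uniformly and independently of any measured value (missing completely
#' at random by construction), lose all their week-12 records across all
#' variables.  Baseline records are always retained, so the subjects
#' remain in the intent-to-treat analysis set.
#'
#' @param dataset a `"trial_dataset"`.
#' @param per_arm dropouts per arm; must be smaller than either arm.
#' @param seed integer seed for the uniform selection.
#' @return the thinned `"trial_dataset"`.
#' @export
apply_dropout <- function(dataset, per_arm, seed = 1L) {
  stopifnot(inherits(dataset, "trial_dataset"), per_arm >= 0)
  if (per_arm == 0L) return(dataset)
  d <- dataset$data
  subj <- unique(d$subject_id)
  arm_of <- d$arm[match(subj, d$subject_id)]
  if (per_arm >= min(sum(arm_of == 0L), sum(arm_of == 1L))) {
    stop("per_arm must be smaller than the smaller arm", call. = FALSE)
  }
  set.seed(seed)
  drop_ids <- c(sample(subj[arm_of == 0L], per_arm),
                sample(subj[arm_of == 1L], per_arm))
  keep <- !(d$subject_id %in% drop_ids & d$timepoint == 1L)
  dataset$data <- d[keep, , drop = FALSE]
  rownames(dataset$data) <- NULL
  validate_trial_dataset(dataset)
  dataset
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic trial spec: %d exercise / %d control, a=%.2f b=%.2f direct=%.2f\n",
    x$n_exercise, x$n_control, x$a_effect, x$b_effect, x$direct_effect))
  cat(sprintf("  implied total effect c = %.2f; dropout %d/arm; seed %d%s\n",
              x$direct_effect + x$a_effect * x$b_effect,
              x$dropout_per_arm, x$seed,
              if (x$biomarker_mode) "; biomarker (log-normal) mode" else ""))
  invisible(x)
}
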