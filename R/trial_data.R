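#' Construct a trial dataset of long-format repeated measures
#'
#' The single input container for the whole pipeline: one row per
#' subject x timepoint x variable, together with the analytic role of each
#' variable (outcome, mediator or covariate) and the scalar transform to
#' apply before modelling (`"none"` or natural-log `"log"`).
#'
#' Coding conventions are fixed package-wide: `arm` 0 = control,
#' 1 = exercise; `timepoint` 0 = baseline, 1 = week 12.  All downstream
#' coefficient signs are interpreted against this coding, so e.g. a
#' negative group-by-time effect on an anxiety T-score means a greater
#' reduction in the exercise arm.
#'
#' @param data data frame with columns `subject_id`, `arm`, `timepoint`,
#'   `variable`, `value`.  `arm` and `timepoint` may be 0/1 numerics or the
#'   labels `"control"`/`"exercise"` and `"baseline"`/`"week12"`.
#' @param roles named character vector mapping variable names to one of
#'   `"outcome"`, `"mediator"`, `"covariate"`.
#' @param transforms named character vector mapping variable names to
#'   `"none"` or `"log"`.  Variables not named default to `"none"`.
#' @return An object of class `"trial_dataset"`: a list with elements
#'   `data` (the validated long data frame), `roles`, `transforms`,
#'   `n_subjects_per_arm` (named count vector) and `transformed`
#'   (logical; have the declared transforms been applied yet).
#' @seealso [read_long_csv()], [apply_transforms()], [generate_trial()]
#' @export
trial_dataset <- function(data, roles = character(0),
                          transforms = character(0)) {
  stopifnot(is.data.frame(data))
  required <- c("subject_id", "arm", "timepoint", "variable", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    subject_id = as.character(data$subject_id),
    arm        = decode_binary(data$arm, c("control", "exercise"), "arm"),
    timepoint  = decode_binary(data$timepoint,
                               c("baseline", "week12"), "timepoint"),
    variable   = as.character(data$variable),
    value      = as.numeric(data$value),
    stringsAsFactors = FALSE
  )
  d <- d[order(d$subject_id, d$timepoint, d$variable), , drop = FALSE]
  rownames(d) <- NULL

  roles <- validate_roles(roles)
  transforms <- validate_transforms(transforms)

  per_arm <- subjects_per_arm(d)
  obj <- structure(
    list(data = d, roles = roles, transforms = transforms,
         n_subjects_per_arm = per_arm, transformed = FALSE),
    class = "trial_dataset"
  )
  validate_trial_dataset(obj)
  obj
}

decode_binary <- function(x, labels, what) {
  if (is.numeric(x) || is.logical(x)) {
    v <- as.integer(x)
  } else {
    s <- tolower(trimws(as.character(x)))
    v <- rep(NA_integer_, length(s))
    v[s %in% c("0", labels[1])] <- 0L
    v[s %in% c("1", labels[2], "week 12", "12 weeks", "week_12")] <- 1L
  }
  if (any(is.na(v)) || !all(v %in% c(0L, 1L))) {
    stop(what, " values must decode to 0/1 (", labels[1], "/", labels[2], ")",
         call. = FALSE)
  }
  v
}

validate_roles <- function(roles) {
  if (length(roles) == 0L) return(character(0))
  roles <- vapply(roles, as.character, character(1))
  bad <- setdiff(unique(roles), c("outcome", "mediator", "covariate"))
  if (length(bad) > 0L) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(roles)) || any(names(roles) == "")) {
    stop("roles must be a named vector (variable -> role)", call. = FALSE)
  }
  roles
}

validate_transforms <- function(transforms) {
  if (length(transforms) == 0L) return(character(0))
  bad <- setdiff(unique(transforms), c("none", "log"))
  if (length(bad) > 0L) {
    stop("unknown transform(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(transforms)) || any(names(transforms) == "")) {
    stop("transforms must be a named vector (variable -> transform)",
         call. = FALSE)
  }
  transforms
}

subjects_per_arm <- function(d) {
  arm_of <- tapply(d$arm, d$subject_id, function(a) unique(a))
  if (any(lengths(arm_of) != 1L)) {
    stop("arm must be constant within subject; offending subject(s): ",
         paste(names(arm_of)[lengths(arm_of) != 1L], collapse = ", "),
         call. = FALSE)
  }
  arm_of <- unlist(arm_of)
  c(control = sum(arm_of == 0L), exercise = sum(arm_of == 1L))
}

#' Validate a trial dataset's structural invariants
#'
#' Checks (and errors on violation of): uniqueness of
#' (subject, timepoint, variable) records; constancy of arm within subject;
#' presence in the measurements of every variable that `roles` references;
#' presence of baseline records for every subject (week-12 records may be
#' absent, i.e. dropout); strict positivity of values still awaiting a log
#' transform.
#'
#' @param x a `"trial_dataset"`.
#' @return `x`, invisibly, if valid.
#' @export
validate_trial_dataset <- function(x) {
  stopifnot(inherits(x, "trial_dataset"))
  d <- x$data
  key <- paste(d$subject_id, d$timepoint, d$variable, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate record for (", dup$subject_id, ", timepoint ",
         dup$timepoint, ", ", dup$variable, ")", call. = FALSE)
  }
  subjects_per_arm(d)  # errors if arm varies within subject
  missing_vars <- setdiff(names(x$roles), unique(d$variable))
  if (length(missing_vars) > 0L) {
    stop("role declared for unmeasured variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  has_baseline <- tapply(d$timepoint == 0L, d$subject_id, any)
  if (!all(has_baseline)) {
    stop("subject(s) without baseline records: ",
         paste(names(has_baseline)[!has_baseline], collapse = ", "),
         call. = FALSE)
  }
  if (!x$transformed) {
    logvars <- names(x$transforms)[x$transforms == "log"]
    for (v in logvars) {
      vals <- d$value[d$variable == v]
      if (any(vals <= 0, na.rm = TRUE)) {
        stop("variable '", v, "' is flagged for log transform but has ",
             "non-positive value(s)", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Read a long-format trial CSV
#'
#' Expects columns `subject_id`, `arm`, `timepoint`, `variable`, `value`.
#' Duplicate (subject, timepoint, variable) rows are rejected, as are
#' non-positive values for variables declared log-transformed.
#'
#' @inheritParams trial_dataset
#' @param path path to a CSV file.
#' @return a [trial_dataset()].
#' @export
read_long_csv <- function(path, roles = character(0),
                          transforms = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  trial_dataset(raw, roles = roles, transforms = transforms)
}

#' Write a trial dataset as long-format CSV
#'
#' Emits the same five-column layout [read_long_csv()] consumes, so a
#' write/read round trip reproduces the measurements exactly.
#'
#' @param dataset a `"trial_dataset"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide-format trial CSV
#'
#' Adapter for the one-row-per-subject-x-timepoint layout: columns
#' `subject_id`, `arm`, `timepoint` plus one column per variable.  The
#' table is melted to long format and validated as in [read_long_csv()].
#'
#' @inheritParams read_long_csv
#' @return a [trial_dataset()].
#' @export
read_wide_csv <- function(path, roles = character(0),
                          transforms = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  id_cols <- c("subject_id", "arm", "timepoint")
  missing_cols <- setdiff(id_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  vars <- setdiff(names(raw), id_cols)
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(subject_id = raw$subject_id, arm = raw$arm,
               timepoint = raw$timepoint, variable = v,
               value = as.numeric(raw[[v]]), stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  trial_dataset(long, roles = roles, transforms = transforms)
}

#' Natural-log transform of positive measurements
#'
#' Biomarkers (BDNF, CRP, HOMA2-IR and similar right-skewed positive
#' concentrations) are analysed on the natural-log scale; this is the
#' elementwise transform applied before modelling.
#'
#' @param values numeric vector, all strictly positive.
#' @return `log(values)`.
#' @export
log_transform <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (any(values <= 0, na.rm = TRUE)) {
    stop("log transform requires strictly positive values", call. = FALSE)
  }
  log(values)
}

#' Apply declared transforms to a trial dataset
#'
#' Applies each variable's declared transform (currently natural log) to
#' its values and marks the dataset as transformed.  Model-fitting
#' functions require transforms to have been applied; applying twice is an
#' error.
#'
#' @param dataset a `"trial_dataset"`.
#' @return the transformed `"trial_dataset"`.
#' @export
apply_transforms <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (dataset$transformed) {
    stop("transforms have already been applied to this dataset",
         call. = FALSE)
  }
  d <- dataset$data
  logvars <- names(dataset$transforms)[dataset$transforms == "log"]
  for (v in logvars) {
    sel <- d$variable == v
    d$value[sel] <- log_transform(d$value[sel])
  }
  dataset$data <- d
  dataset$transformed <- TRUE
  dataset
}

#' Convert a raw score to the PROMIS-style T-score metric
#'
#' T-scores are standardized to mean 50 and SD 10 in a reference
#' population: `50 + 10 * (raw - ref_mean) / ref_sd`.
#'
#' @param raw raw score(s).
#' @param ref_mean reference-population mean.
#' @param ref_sd reference-population SD (> 0).
#' @return T-score(s).
#' @export
to_t_score <- function(raw, ref_mean, ref_sd) {
  if (!is.numeric(ref_sd) || any(ref_sd <= 0)) {
    stop("ref_sd must be positive", call. = FALSE)
  }
  50 + 10 * (raw - ref_mean) / ref_sd
}

#' Classify a T-score change as clinically meaningful
#'
#' A change is meaningful when its absolute value reaches the threshold
#' (default 3 T-score points, inclusive).  Direction is ignored: a
#' 3.5-point worsening is as meaningful as a 3.5-point improvement.
#'
#' @param delta change in T-score points.
#' @param threshold positive threshold in T-score points.
#' @return logical vector, `TRUE` where `abs(delta) >= threshold`.
#' @export
classify_meaningful_change <- function(delta, threshold = 3) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  abs(delta) >= threshold
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Two-arm, two-timepoint trial dataset\n")
  cat(sprintf("  subjects: %d control / %d exercise\n",
              x$n_subjects_per_arm[["control"]],
              x$n_subjects_per_arm[["exercise"]]))
  cat(sprintf("  measurements: %d rows, %d variable(s)\n",
              nrow(x$data), length(unique(x$data$variable))))
  if (length(x$roles) > 0L) {
    cat("  roles:", paste(sprintf("%s=%s", names(x$roles), x$roles),
                          collapse = ", "), "\n")
  }
  logvars <- names(x$transforms)[x$transforms == "log"]
  if (length(logvars) > 0L) {
    cat(sprintf("  log-transformed: %s (%s)\n",
                paste(logvars, collapse = ", "),
                if (x$transformed) "applied" else "pending"))
  }
  invisible(x)
}

# Wide per-(subject, timepoint) model frame for the named variables.
# Rows ordered by subject then timepoint so downstream fits are invariant
# to the input row order.
pivot_measurements <- function(dataset, vars) {
  d <- dataset$data
  missing_vars <- setdiff(vars, unique(d$variable))
  if (length(missing_vars) > 0L) {
    stop("variable(s) not in dataset: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  d <- d[d$variable %in% vars, , drop = FALSE]
  key <- paste(d$subject_id, d$timepoint, sep = "\r")
  first <- !duplicated(key)
  out <- d[first, c("subject_id", "arm", "timepoint"), drop = FALSE]
  ukey <- key[first]
  for (v in vars) {
    sel <- d$variable == v
    col <- rep(NA_real_, nrow(out))
    col[match(key[sel], ukey)] <- d$value[sel]
    out[[v]] <- col
  }
  out <- out[order(out$subject_id, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
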