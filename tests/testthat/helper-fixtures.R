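# Shared fixtures, all built in code.

# Balanced complete two-timepoint toy with hand-specified cell means.
# Subjects deviate +/-1 from their cell mean at both timepoints, so the
# data are consistent with a subject random intercept and the four cell
# means are exact.  Difference-in-differences of the cell means:
# (mean_e1 - mean_e0) - (mean_c1 - mean_c0).
did_toy <- function(mean_c0 = 10, mean_c1 = 12,
                    mean_e0 = 10, mean_e1 = 15,
                    n_per_arm = 2) {
  # subject offsets sum to zero within each arm, and the extra
  # time-varying deviations sum to zero within every arm x time cell, so
  # the four cell means are exactly as specified while both variance
  # components stay positive
  offs <- seq(-1, 1, length.out = n_per_arm)
  dev <- 0.5 * rev(offs)
  rows <- list()
  k <- 0L
  for (g in 0:1) {
    for (i in seq_len(n_per_arm)) {
      k <- k + 1L
      id <- sprintf("S%02d", k)
      base <- if (g == 0) mean_c0 else mean_e0
      wk12 <- if (g == 0) mean_c1 else mean_e1
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, arm = g, timepoint = c(0L, 1L), variable = "y",
        value = c(base + offs[i] + dev[i], wk12 + offs[i] - dev[i]))
    }
  }
  trial_dataset(do.call(rbind, rows), roles = c(y = "outcome"))
}

# Long-format CSV written to a temp file.
write_fixture_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal 1-subject, 2-timepoint, 2-variable long table.
minimal_long <- function() {
  data.frame(
    subject_id = "S1", arm = 0,
    timepoint = rep(c(0, 1), each = 2),
    variable = rep(c("anxiety", "crp"), 2),
    value = c(55, 1.2, 52, 0.9))
}

# Monte-Carlo SE of a mean
mc_se <- function(x) stats::sd(x) / sqrt(length(x))
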