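make_study_ds <- function(seed = 1, n_e = 30, n_c = 30) {
  generate_trial(synthetic_spec(n_exercise = n_e, n_control = n_c,
                                dropout_per_arm = 1, seed = seed))
}

test_that("baseline table compares arms with Welch t and chi-square", {
  # identical continuous values in both arms -> t = 0, P = 1
  rows <- expand.grid(subject_id = sprintf("S%02d", 1:20),
                      timepoint = 0:1, stringsAsFactors = FALSE)
  rows$arm <- as.integer(sub("S", "", rows$subject_id)) %% 2L
  rows$variable <- "age"
  rows$value <- rep(c(50, 55, 60, 65, 70), 8)
  ds <- trial_dataset(rows)
  bt <- baseline_table(ds, continuous = "age")
  expect_equal(bt$p_value[1], 1)
  expect_equal(bt$control[1], bt$exercise[1])

  # balanced 2x2 counts -> chi-square 0, P = 1
  cat_rows <- data.frame(
    subject_id = sprintf("C%02d", 1:40),
    arm = rep(0:1, each = 20), timepoint = 0L, variable = "stage",
    value = rep(c(1, 1, 2, 2), 10))
  ds2 <- trial_dataset(cat_rows)
  bt2 <- baseline_table(ds2, categorical = "stage")
  expect_equal(bt2$p_value[1], 1)
  expect_equal(nrow(bt2), 2L)  # one row per level
  expect_true(is.na(bt2$p_value[2]))

  # single-level categorical: comparison skipped with a note
  cat_rows$value <- 1
  bt3 <- baseline_table(trial_dataset(cat_rows), categorical = "stage")
  expect_match(bt3$note[1], "skipped")
  expect_true(is.na(bt3$p_value[1]))
})

test_that("pooling per-arm summaries reproduces published whole-sample values", {
  # anxiety 54.8 (8.51) n=43 / 55.6 (6.95) n=44 -> 55.2 (7.72)
  anx <- pool_mean_sd(c(55.6, 54.8), c(6.95, 8.51), c(44, 43))
  expect_equal(round(unname(anx["mean"]), 1), 55.2)
  # per-arm inputs are themselves rounded to 2 decimals, so the pooled SD
  # is recovered to within one unit of that precision
  expect_lt(abs(unname(anx["sd"]) - 7.72), 0.01)
  # depression 50.0 (8.16) / 50.7 (7.88) -> 50.4 (7.98)
  dep <- pool_mean_sd(c(50.7, 50.0), c(7.88, 8.16), c(44, 43))
  expect_equal(round(unname(dep["mean"]), 1), 50.4)
  expect_equal(round(unname(dep["sd"]), 2), 7.98)
})

test_that("pipeline produces one row per configured pair", {
  sp <- synthetic_spec(
    n_exercise = 20, n_control = 20, dropout_per_arm = 1, seed = 3,
    mediator_name = "anxiety", outcome_name = "cognitive_abilities",
    extra_null_vars = list(
      fatigue = list(mean = 52, tau2 = 40, sigma2 = 20),
      crp = list(mean = 1.1, tau2 = 0.4, sigma2 = 0.2, biomarker = TRUE)))
  ds <- generate_trial(sp)
  # a second outcome, unrelated: reuse fatigue under outcome role
  cfg <- analysis_config(
    input = ds, mediators = c("anxiety", "crp"),
    outcomes = c("cognitive_abilities", "fatigue"),
    reverse_pairs = list(c("cognitive_abilities", "anxiety")),
    bootstrap = bootstrap_config(n_boot = 30, seed = 9))
  rep <- run_pipeline(cfg)
  expect_equal(nrow(rep$mediation), 5L)  # 2x2 grid + 1 reverse
  expect_equal(rep$n_pairs_tested, 5L)
  expect_equal(sum(rep$mediation$direction == "reverse"), 1L)
  # gate-failed pairs show paths but no CI
  failed <- rep$mediation[!rep$mediation$proceed, ]
  if (nrow(failed) > 0) {
    expect_true(all(is.na(failed$ci_lower)))
    expect_false(any(is.na(failed$a_beta)))
  }
  expect_error(analysis_config(input = ds, mediators = "x",
                               outcomes = "x"), "disjoint")
})

test_that("pipeline results are invariant to input row order", {
  ds <- make_study_ds(seed = 12)
  shuffled <- ds
  set.seed(1)
  shuffled$data <- shuffled$data[sample.int(nrow(shuffled$data)), ]
  cfg <- function(d) analysis_config(
    input = d, mediators = "mediator", outcomes = "outcome",
    bootstrap = bootstrap_config(n_boot = 25, seed = 4))
  r1 <- run_pipeline(cfg(ds))
  r2 <- run_pipeline(cfg(shuffled))
  expect_equal(r1$mediation, r2$mediation)
})

test_that("same config and seed render byte-identical reports", {
  ds <- make_study_ds(seed = 20)
  cfg <- analysis_config(
    input = ds, mediators = "mediator", outcomes = "outcome",
    baseline_continuous = c("mediator", "outcome"),
    bootstrap = bootstrap_config(n_boot = 40, seed = 2))
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  for (fmt in c("text", "tsv", "json")) {
    expect_identical(render_report(r1, fmt), render_report(r2, fmt))
  }
})

test_that("removing one pair leaves the other pairs' numbers unchanged", {
  sp <- synthetic_spec(n_exercise = 25, n_control = 25,
                       dropout_per_arm = 1, seed = 31,
                       mediator_name = "anxiety",
                       outcome_name = "cognition",
                       extra_null_vars = list(
                         fatigue = list(mean = 52, tau2 = 40, sigma2 = 20)))
  ds <- generate_trial(sp)
  boot <- bootstrap_config(n_boot = 30, seed = 17)
  both <- run_pipeline(analysis_config(
    input = ds, mediators = c("anxiety", "fatigue"),
    outcomes = "cognition", bootstrap = boot))
  only <- run_pipeline(analysis_config(
    input = ds, mediators = "anxiety", outcomes = "cognition",
    bootstrap = boot))
  b <- both$mediation[both$mediation$mediator == "anxiety", ]
  o <- only$mediation
  rownames(b) <- rownames(o) <- NULL
  expect_equal(b, o)
})

test_that("reports render deterministically in all formats", {
  ds <- make_study_ds(seed = 40)
  rep <- run_pipeline(analysis_config(
    input = ds, mediators = "mediator", outcomes = "outcome",
    bootstrap = bootstrap_config(n_boot = 25, seed = 8)))
  txt <- render_report(rep, "text")
  expect_match(txt, "mediator -> outcome")
  expect_match(txt, "solid|dashed")
  tsv <- render_report(rep, "tsv")
  parsed <- utils::read.delim(text = tsv)
  js <- jsonlite::fromJSON(render_report(rep, "json"))
  # TSV and JSON agree at the rendered precision
  expect_equal(parsed$a_beta, js$mediation$a_beta)
  expect_equal(parsed$indirect, js$mediation$indirect)
  expect_error(render_report(rep, "xml"))

  out_dir <- withr::local_tempdir()
  cfgd <- analysis_config(
    input = ds, mediators = "mediator", outcomes = "outcome",
    bootstrap = bootstrap_config(n_boot = 25, seed = 8),
    out_dir = out_dir)
  run_pipeline(cfgd)
  expect_setequal(list.files(out_dir),
                  c("report.tsv", "results.json", "report.txt", "run.log"))
})

test_that("configs round-trip through YAML and JSON files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "synthetic:",
    "  n_exercise: 10",
    "  n_control: 10",
    "  seed: 4",
    "mediators: [mediator]",
    "outcomes: [outcome]",
    "alpha_gate: 0.2",
    "bootstrap:",
    "  n_boot: 25",
    "  seed: 3"), path)
  cfg <- read_analysis_config(path)
  expect_s3_class(cfg$input, "synthetic_spec")
  expect_equal(cfg$alpha_gate, 0.2)
  expect_equal(cfg$bootstrap$n_boot, 25L)
  rep <- run_pipeline(cfg)
  expect_equal(nrow(rep$mediation), 1L)
})
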