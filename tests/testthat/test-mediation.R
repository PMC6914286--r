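test_that("paths recover generative parameters on large synthetic data", {
  ds <- generate_trial(synthetic_spec(n_exercise = 1500, n_control = 1500,
                                      a_effect = 2, b_effect = 0.5,
                                      direct_effect = 0,
                                      dropout_per_arm = 1, seed = 21))
  paths <- estimate_paths(ds, "mediator", "outcome")
  expect_lt(abs(paths$a$beta - 2), 3 * paths$a$se)
  expect_lt(abs(paths$b$beta - 0.5), 3 * paths$b$se)
  expect_lt(abs(paths$c$beta - 1.0), 3 * paths$c$se)   # c = d + a*b
  expect_lt(abs(paths$c_prime$beta - 0), 3 * paths$c_prime$se)
})

test_that("null structure gives near-zero b and c", {
  ds <- generate_trial(synthetic_spec(n_exercise = 800, n_control = 800,
                                      a_effect = 0, b_effect = 0,
                                      direct_effect = 0,
                                      dropout_per_arm = 0, seed = 33))
  paths <- estimate_paths(ds, "mediator", "outcome")
  expect_lt(abs(paths$b$beta), 3 * paths$b$se)
  expect_lt(abs(paths$c$beta), 3 * paths$c$se)
})

test_that("reverse mediation runs by swapping the roles", {
  ds <- generate_trial(synthetic_spec(n_exercise = 40, n_control = 40,
                                      seed = 8))
  fwd <- estimate_paths(ds, "mediator", "outcome")
  rev <- estimate_paths(ds, "outcome", "mediator")
  expect_equal(rev$mediator, "outcome")
  expect_equal(rev$outcome, "mediator")
  # path a of the reverse direction is the forward path c by definition
  expect_equal(rev$a$beta, fwd$c$beta, tolerance = 1e-8)
})

test_that("swapping arm labels negates a, c, c' and leaves b invariant", {
  ds <- generate_trial(synthetic_spec(n_exercise = 50, n_control = 50,
                                      dropout_per_arm = 1, seed = 14))
  swapped <- ds
  swapped$data$arm <- 1L - swapped$data$arm
  swapped$n_subjects_per_arm <- rev(swapped$n_subjects_per_arm)
  p1 <- estimate_paths(ds, "mediator", "outcome")
  p2 <- estimate_paths(swapped, "mediator", "outcome")
  expect_equal(p2$a$beta, -p1$a$beta, tolerance = 1e-6)
  expect_equal(p2$c$beta, -p1$c$beta, tolerance = 1e-6)
  expect_equal(p2$c_prime$beta, -p1$c_prime$beta, tolerance = 1e-6)
  expect_equal(p2$b$beta, p1$b$beta, tolerance = 1e-6)
  expect_equal(indirect_effect(p2$c, p2$c_prime),
               -indirect_effect(p1$c, p1$c_prime), tolerance = 1e-6)
})

test_that("the unadjusted path-b variant differs but tracks the association", {
  ds <- generate_trial(synthetic_spec(n_exercise = 300, n_control = 300,
                                      b_effect = 0.5, dropout_per_arm = 0,
                                      seed = 19))
  adj <- estimate_paths(ds, "mediator", "outcome", b_adjusted = TRUE)
  unadj <- estimate_paths(ds, "mediator", "outcome", b_adjusted = FALSE)
  expect_false(isTRUE(all.equal(adj$b$beta, unadj$b$beta)))
  expect_lt(abs(unadj$b$beta - 0.5), 4 * unadj$b$se)
})

test_that("gate reproduces published screening decisions from printed P values", {
  pe <- function(path, p) path_estimate(path, beta = 1, se = 1,
                                        p_value = p, ci95 = c(-1, 3))
  # anxiety: a P=.04, b and c also below .10 -> proceed
  g <- gate(list(a = pe("a", .04), b = pe("b", .05), c = pe("c", .09)))
  expect_true(g$proceed)
  # physical functioning passes path a at P=.049
  g2 <- gate(list(a = pe("a", .049), b = pe("b", .02), c = pe("c", .05)))
  expect_true(g2$passed_a && g2$proceed)
  # BDNF (P=.59) and HOMA2-IR (P=.55) fail path a: no mediation test
  for (p_a in c(.59, .55)) {
    g3 <- gate(list(a = pe("a", p_a), b = pe("b", .01), c = pe("c", .01)))
    expect_false(g3$passed_a)
    expect_false(g3$proceed)
  }
  # CRP passes a at P=.09 but fails b: never bootstrapped
  g4 <- gate(list(a = pe("a", .09), b = pe("b", .45), c = pe("c", .05)))
  expect_true(g4$passed_a)
  expect_false(g4$passed_b)
  expect_false(g4$proceed)
})

test_that("gate uses strict inequality and is monotone in alpha", {
  pe <- function(p) path_estimate("a", 1, 1, p, c(-1, 3))
  paths <- list(a = pe(.10), b = pe(.01), c = pe(.01))
  expect_false(gate(paths, alpha = 0.10)$proceed)  # P = alpha fails
  expect_true(gate(paths, alpha = 0.101)$proceed)
  # raising alpha never flips proceed from TRUE to FALSE
  set.seed(4)
  for (i in 1:20) {
    ps <- list(a = pe(runif(1)), b = pe(runif(1)), c = pe(runif(1)))
    alphas <- sort(runif(3, 0.01, 0.5))
    dec <- vapply(alphas, function(a) gate(ps, a)$proceed, logical(1))
    expect_true(all(diff(dec) >= 0))
  }
})

test_that("indirect effect is the c - c' difference", {
  pe <- function(path, b) path_estimate(path, b, 1, .5, c(b - 2, b + 2))
  expect_equal(indirect_effect(pe("c", 2.0), pe("c_prime", 1.2)), 0.8)
  expect_equal(indirect_effect(pe("c", 1.4), pe("c_prime", 1.4)), 0)
})

test_that("difference- and product-of-coefficients estimators agree", {
  # identical in expectation for the linear Gaussian model with no
  # exposure-mediator interaction; compare both on the same replicates
  seeds <- 3000 + 7 * seq_len(30)
  est <- t(vapply(seeds, function(seed) {
    ds <- generate_trial(synthetic_spec(n_exercise = 500, n_control = 500,
                                        a_effect = 2, b_effect = 0.5,
                                        direct_effect = 0,
                                        dropout_per_arm = 1, seed = seed))
    p <- estimate_paths(ds, "mediator", "outcome")
    c(cc = indirect_effect(p$c, p$c_prime), ab = p$a$beta * p$b$beta)
  }, numeric(2)))
  # per replicate the two estimators agree relative to the Monte-Carlo
  # spread of the indirect-effect estimate itself
  mc_sd <- sd(est[, "cc"])
  expect_true(all(abs(est[, "cc"] - est[, "ab"]) < 2 * mc_sd))
  # and both are unbiased for a*b = 1
  expect_lt(abs(mean(est[, "cc"]) - 1), 2 * mc_se(est[, "cc"]))
})

test_that("indirect effect shrinks to zero as n grows when b = 0", {
  ind_at <- function(n, seed) {
    ds <- generate_trial(synthetic_spec(n_exercise = n, n_control = n,
                                        a_effect = 2, b_effect = 0,
                                        dropout_per_arm = 0, seed = seed))
    p <- estimate_paths(ds, "mediator", "outcome")
    abs(indirect_effect(p$c, p$c_prime))
  }
  small <- mean(vapply(1:8, function(s) ind_at(30, 100 + s), numeric(1)))
  large <- mean(vapply(1:8, function(s) ind_at(1000, 200 + s), numeric(1)))
  expect_lt(large, small)
  expect_lt(large, 0.05)
})

test_that("path estimates validate their own invariants", {
  expect_error(path_estimate("a", 1, -1, .5, c(0, 2)), "positive")
  expect_error(path_estimate("a", 1, 1, 1.5, c(0, 2)), "0, 1")
  expect_error(path_estimate("a", 5, 1, .5, c(0, 2)), "bracket")
})
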