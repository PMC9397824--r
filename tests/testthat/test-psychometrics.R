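test_that("phase scores average per-stimulus proportions", {
  rec <- data.frame(f_co = rep(c(100, 116), each = 5),
                    correct = c(1, 1, 1, 0, 0, 1, 1, 1, 1, 1))
  ps <- phase_score(rec)
  expect_equal(ps$per_stimulus$p, c(0.6, 1.0))
  expect_equal(ps$score, 0.8)
  all_right <- data.frame(f_co = rep(comparison_frequencies(default_stimulus_set()), 5),
                          correct = 1)
  expect_equal(phase_score(all_right)$score, 1)
  expect_error(phase_score(rec, default_stimulus_set()), "132")
})

test_that("chance-level responding scores one third", {
  blk <- constant_stimuli_block(default_stimulus_set(), 1250, seed = 21)
  sim <- simulate_block(blk, observer_model(beta = 0), seed = 22)
  sc <- phase_score(sim, default_stimulus_set())$score
  expect_lt(abs(sc - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / nrow(sim)))
})

test_that("psychometric fits recover known parameters", {
  set.seed(31)
  obs <- observer_model(alpha = -2, beta = 10)   # true PSE = 0.2
  rec <- sim_side_records(obs, c(16, 32, 48, 64) / 164, 1000)
  fit <- fit_psychometric(rec)
  expect_true(fit$converged)
  expect_lt(abs(fit$pse - 0.2), 0.01)
  expect_lt(abs(fit$beta - 10), 1)
})

test_that("degenerate response patterns are flagged, not errors", {
  x <- rep(c(16, 32, 48, 64) / 164, each = 10)
  all_right <- data.frame(diff_ratio = x, correct = 1)
  expect_false(fit_psychometric(all_right)$converged)   # separation / no info
  desc <- data.frame(diff_ratio = x, correct = as.integer(x < 0.2))
  fit_desc <- fit_psychometric(desc)                    # negative slope
  expect_false(fit_desc$converged)
  one_x <- data.frame(diff_ratio = 0.2, correct = rep(c(0, 1), 10))
  expect_false(fit_psychometric(one_x)$converged)
})

test_that("convergence requires the PSE inside the baseline ratio range", {
  expect_true(check_convergence(0.2))
  expect_false(check_convergence(0.5))
  expect_true(check_convergence(0.098))   # inclusive bounds
  expect_true(check_convergence(16 / 164))
  expect_true(check_convergence(64 / 164))
  expect_false(check_convergence(0.09))
  expect_false(check_convergence(NA))
})

test_that("phase PSE combines sides and applies the ceiling edge rule", {
  set.seed(41)
  mk <- function(pse, beta, side) {
    obs <- observer_model(alpha = -beta * pse, beta = beta)
    sim_side_records(obs, c(16, 32, 48, 64) / 164, 500, side)
  }
  rec <- rbind(mk(0.15, 12, "more_coarse"), mk(0.25, 12, "less_coarse"))
  po <- pse_outcome(rec)
  expect_lt(abs(po$pse_more_coarse - 0.15), 0.02)
  expect_lt(abs(po$pse_less_coarse - 0.25), 0.02)
  expect_equal(po$pse, mean(c(po$pse_more_coarse, po$pse_less_coarse)))

  # ceiling rule: all trials of the phase correct -> minimum ratio
  all_right <- data.frame(diff_ratio = rep(c(16, 64) / 164, 20),
                          side = rep(c("more_coarse", "less_coarse"), 20),
                          correct = 1)
  expect_equal(pse_outcome(all_right)$pse, 16 / 164)
  expect_equal(round(pse_outcome(all_right)$pse, 3), 0.098)

  # one side degenerate -> phase PSE missing under the paired-exclusion rule
  mixed <- rbind(mk(0.2, 12, "more_coarse"),
                 data.frame(diff_ratio = rep(c(16, 32, 48, 64) / 164, 5),
                            side = "less_coarse", correct = 1))
  expect_true(is.na(pse_outcome(mixed)$pse))
  expect_false(is.na(pse_outcome(mixed, require_both_sides = FALSE)$pse))
  # per-side variant of the ceiling rule
  po_side <- pse_outcome(mixed, all_correct_rule = "side")
  expect_equal(po_side$pse_less_coarse, 16 / 164)
})

test_that("PSE-adapted training sets center on the PSE with baseline spacing", {
  s <- default_stimulus_set()
  center <- mean(difference_ratio(s$more_coarse, s$standard))  # 40/164
  adapted <- adapt_training_set(center, center, s, TRUE, TRUE)
  expect_equal(adapted$more_coarse, s$more_coarse, tolerance = 1e-10)
  expect_equal(adapted$less_coarse, s$less_coarse, tolerance = 1e-10)

  # non-converged sides keep the baseline stimuli
  same <- adapt_training_set(NA, NA, s, FALSE, FALSE)
  expect_equal(same$more_coarse, s$more_coarse)
  expect_equal(same$less_coarse, s$less_coarse)
  half <- adapt_training_set(0.15, NA, s, TRUE, FALSE)
  expect_false(isTRUE(all.equal(half$more_coarse, s$more_coarse)))
  expect_equal(half$less_coarse, s$less_coarse)

  # clipped construction stays positive, distinct, and inside the range
  for (pse in seq(16 / 164, 64 / 164, length.out = 9)) {
    a <- adapt_training_set(pse, pse, s, TRUE, TRUE)
    r_mc <- difference_ratio(a$more_coarse, s$standard)
    r_lc <- difference_ratio(a$less_coarse, s$standard)
    expect_true(all(c(r_mc, r_lc) > 0))
    expect_true(all(c(r_mc, r_lc) <= 64 / 164 + 1e-12))
    expect_true(all(diff(a$more_coarse) > 0) && all(diff(a$less_coarse) > 0))
  }
})
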