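test_that("Bayesian risk is the posterior expected absolute loss", {
  # point mass with cycle-1 mean exactly on target: zero risk
  fit <- fake_tox_fit(beta0 = 0.28 - 0.2 - 0.05, beta1 = 0.1, beta2 = 0.05)
  expect_equal(unname(bayes_risk(fit, 2, target = 0.28)), 0)
  # two equally weighted draws with cycle-1 means 0.2 and 0.4
  fit2 <- fake_tox_fit(beta0 = c(0.2, 0.4), beta1 = c(1e-9, 1e-9),
                       beta2 = c(0, 0))
  expect_equal(unname(bayes_risk(fit2, 1, target = 0.28)),
               (0.08 + 0.12) / 2, tolerance = 1e-6)
  # the point-estimate reading collapses the same two draws differently
  expect_equal(unname(bayes_risk(fit2, 1, 0.28, method = "point_estimate")),
               abs(0.3 - 0.28), tolerance = 1e-6)
})

test_that("3+3 start-up follows the canonical rule table", {
  cfg <- design_config()
  mk <- function(n, ndlt, dose = 1)
    data.frame(uniqueID = paste0("p", seq_len(n)), dose = dose, cycle = 1,
               nTTP = 0.1, DLT = rep(c(1, 0), c(ndlt, n - ndlt)))
  expect_identical(startup_rule(mk(3, 0), cfg), 2L)        # escalate
  expect_identical(startup_rule(mk(3, 1), cfg), 1L)        # expand
  expect_identical(startup_rule(mk(3, 2), cfg), NA_integer_) # stop at lowest
  expect_identical(startup_rule(mk(6, 1), cfg), 2L)        # 1/6 escalates
  expect_identical(startup_rule(mk(6, 2), cfg), NA_integer_)
  expect_identical(startup_rule(mk(3, 2, dose = 2), cfg), 1L) # de-escalate
  expect_identical(startup_rule(mk(2, 0), cfg), 1L)        # cohort incomplete
  # at the top dose a clean cohort stays (nowhere to escalate)
  expect_identical(startup_rule(mk(3, 0, dose = 6), cfg), 6L)
  expect_error(startup_rule(example_trial_data(), cfg), "single dose")
})

test_that("dose recommendation follows risk minimization with no skipping", {
  cfg <- design_config()
  # no data: the starting dose
  rec0 <- recommend_dose_tox(data.frame(), cfg)
  expect_identical(rec0$next_dose, 1L)
  expect_identical(rec0$stage, "startup")
  # the worked nine-record example recommends dose 2
  rec <- recommend_dose_tox(example_trial_data(), cfg, seed = 104)
  expect_identical(rec$next_dose, 2L)
  expect_identical(rec$stage, "model_tox")
  expect_identical(unname(which.min(rec$risks)), 2L)
  # steeply sub-target data on doses 1-2: unconstrained argmin is high,
  # the cap keeps the recommendation at highest-tried + 1
  low <- data.frame(uniqueID = rep(paste0("p", 1:6), each = 1),
                    dose = rep(c(1, 2), each = 3), cycle = 1,
                    nTTP = rep(c(0.001, 0.01), each = 3), DLT = 0)
  rec2 <- recommend_dose_tox(low, cfg, seed = 105)
  expect_gt(unname(which.min(rec2$risks)), 3)
  expect_identical(rec2$next_dose, 3L)
})

test_that("allowable-dose screening applies both posterior conditions", {
  # point mass with cycle-1 means 0.1, 0.2, 0.3, 0.4 at doses 1-4
  fit <- fake_joint_fit(alpha0 = 0.5, alpha1 = 0, alpha2 = 0,
                        beta0 = 0, beta1 = 0.1, beta2 = 0)
  expect_identical(allowable_doses(fit, 1:4, c1 = 0.28, p1 = 0.2,
                                   c2 = 0.28, p2 = 0.2), c(1L, 2L))
  # degenerate cutoffs admit every dose for a diffuse posterior
  real <- fit_tox_lmm(example_trial_data(), iter = 800, burnin = 200,
                      seed = 106)
  expect_identical(allowable_doses(real, 1:6, c1 = 0.28, p1 = 0),
                   1:6)
  # an impossible safety bound empties the set (point-mass posterior)
  pm <- fake_joint_fit(alpha0 = 0.5, alpha1 = 0, alpha2 = 0,
                       beta0 = 0.05, beta1 = 0.1, beta2 = 0)
  expect_length(allowable_doses(pm, 1:4, c1 = 0.05, p1 = 0.1), 0)
  # late-cycle condition can exclude on its own (large cycle effect)
  fit2 <- fake_joint_fit(alpha0 = 0.5, alpha1 = 0, alpha2 = 0,
                         beta0 = 0, beta1 = 0.05, beta2 = 0.5)
  expect_identical(allowable_doses(fit2, 1:4, c1 = 0.28, p1 = 0.2),
                   1:4)
  expect_length(allowable_doses(fit2, 1:4, c1 = 0.28, p1 = 0.2,
                                c2 = 0.28, p2 = 0.2), 0)
})

test_that("adaptive randomization is a softmax over predicted efficacy", {
  p <- stage2_probs(c(`1` = 0.4, `2` = 0.4, `3` = 0.4))
  expect_equal(unname(p), rep(1 / 3, 3))
  p2 <- stage2_probs(c(`1` = 0.2, `2` = 1.2))
  expect_equal(unname(p2), c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))),
               tolerance = 1e-12)
  # translation invariance and conservation
  pe <- c(`1` = 0.1, `2` = 0.35, `4` = 0.6)
  expect_equal(stage2_probs(pe), stage2_probs(pe + 100))
  expect_equal(sum(stage2_probs(pe)), 1)
  # empirical allocation matches the probabilities within 3 SEs
  set.seed(107)
  draws <- replicate(20000, as.integer(randomize_stage2(pe)))
  pr <- stage2_probs(pe)
  for (i in seq_along(pr)) {
    se <- sqrt(pr[i] * (1 - pr[i]) / 20000)
    expect_lt(abs(mean(draws == as.integer(names(pr)[i])) - pr[i]), 3 * se)
  }
  expect_error(stage2_probs(numeric(0)), "no allowable doses")
})

test_that("final selection picks the lowest near-optimal allowable dose", {
  sel <- select_efficacious(c(`1` = 0.2, `2` = 0.5, `3` = 0.51),
                            delta = 0.02)
  expect_identical(sel$efficacious, c(2L, 3L))
  expect_identical(sel$recommended, 2L)
  # delta = 0 with a unique maximizer
  sel0 <- select_efficacious(c(`1` = 0.2, `2` = 0.5, `3` = 0.51), 0)
  expect_identical(sel0$efficacious, 3L)
  expect_identical(sel0$recommended, 3L)
  # flat efficacy: everything is efficacious, lowest dose wins
  self <- select_efficacious(c(`2` = 0.4, `4` = 0.4, `5` = 0.4), 0.05)
  expect_identical(self$efficacious, c(2L, 4L, 5L))
  expect_identical(self$recommended, 2L)
  # delta large enough always recovers H = A and min(A)
  selb <- select_efficacious(c(`1` = 0.1, `3` = 0.9), delta = 2)
  expect_identical(selb$efficacious, c(1L, 3L))
  expect_identical(selb$recommended, 1L)
})

test_that("three-stage decisions switch at the sample-size boundaries", {
  cfg <- dual_design_config(trial_size = 12, cohort_size = 3,
                            max_cycle = 3, tox_target = 0.28,
                            p1 = 0.1, p2 = 0.1, ps1 = 0.1, delta = 0.1)
  expect_identical(run_trial_dual(data.frame(), NULL, cfg)$stage, "stage1")
  # benign synthetic trial state on doses 1-2 (5 patients < N/2 = 6)
  mk_tox <- function(n, doses) data.frame(
    uniqueID = paste0("p", seq_len(n)), dose = rep(doses, length.out = n),
    cycle = 1, nTTP = 0.05 * rep(doses, length.out = n), DLT = 0)
  r1 <- run_trial_dual(mk_tox(5, 1:2), NULL, cfg, iter = 600,
                       burnin = 150, seed = 108)
  expect_identical(r1$stage, "stage1")
  expect_false(r1$terminated)
  expect_lte(r1$next_dose, 3L)   # no skipping above highest tried + 1
  # 6 patients reach stage 2 and need efficacy data
  tox6 <- mk_tox(6, 1:2)
  expect_error(run_trial_dual(tox6, NULL, cfg, iter = 200, burnin = 50),
               "efficacy data")
  eff6 <- data.frame(subID = paste0("p", 1:6),
                     dose = rep(1:2, length.out = 6),
                     Efficacy = c(0.4, 0.5, 0.45, 0.5, 0.55, 0.6))
  r2 <- run_trial_dual(tox6, eff6, cfg, iter = 600, burnin = 150,
                       seed = 109)
  expect_identical(r2$stage, "stage2")
  expect_lte(r2$next_dose, 3L)
  # 12 patients (= N) trigger the stage-3 final selection
  tox12 <- mk_tox(12, 1:3)
  eff12 <- data.frame(subID = paste0("p", 1:12),
                      dose = rep(1:3, length.out = 12),
                      Efficacy = rep(0.5, 12))
  r3 <- run_trial_dual(tox12, eff12, cfg, iter = 600, burnin = 150,
                       seed = 110)
  expect_identical(r3$stage, "stage3")
  if (!r3$terminated) {
    expect_true(r3$next_dose %in% r3$allowable)
    # flat efficacy concentrates the recommendation at min(H)
    expect_identical(r3$next_dose, min(r3$efficacious))
  }
})

test_that("uniformly toxic data terminates the dual design early", {
  toxic <- data.frame(uniqueID = paste0("p", 1:8),
                      dose = rep(1:2, each = 4), cycle = 1,
                      nTTP = 0.6 + 0.02 * (1:8 %% 3), DLT = 1)
  cfg <- dual_design_config(trial_size = 36, cohort_size = 3,
                            max_cycle = 3, c1 = 0.28, c2 = 0.28,
                            p1 = 0.2, p2 = 0.2, ps1 = 0.2, delta = 0.1)
  r <- run_trial_dual(toxic, NULL, cfg, iter = 800, burnin = 200,
                      seed = 111)
  expect_true(r$terminated)
  expect_identical(r$next_dose, NA_integer_)
  expect_length(r$allowable, 0)
})
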