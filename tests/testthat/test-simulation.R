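# Small, fast trial configurations keep the simulated-trial tests within
# a few seconds each; chain lengths are reduced accordingly.

small_cfg <- design_config(doses = 1:4, trial_size = 9, cohort_size = 3,
                           max_cycle = 2, tox_target = 0.28)
probs4 <- gen_tox_prob(spec_tox, 4, 2)

test_that("a benign scenario yields a clean, complete, deterministic trial", {
  deg <- array(0, dim = c(4, 2, 3, 5)); deg[, , , 1] <- 1   # all grade 0
  tr <- simulate_trial_tox(deg, wm3, small_cfg, iter = 400, burnin = 100,
                           seed = 201)
  expect_identical(tr$n_enrolled, 9L)
  expect_identical(length(tr$assignments), 3L)        # N / m cohorts
  expect_true(all(tr$data$nTTP == 0))
  expect_true(all(tr$data$DLT == 0))
  expect_false(tr$early_stop)
  # fixed seed: bit-identical repeat
  tr2 <- simulate_trial_tox(deg, wm3, small_cfg, iter = 400, burnin = 100,
                            seed = 201)
  expect_identical(tr$data, tr2$data)
  expect_identical(tr$recommendation, tr2$recommendation)
})

test_that("trial conduct honours cohort accounting and the no-skip rule", {
  tr <- simulate_trial_tox(probs4, wm3, small_cfg, iter = 400,
                           burnin = 100, seed = 202)
  expect_lte(tr$n_enrolled, small_cfg$trial_size)
  # doses constant within patient; cycles contiguous from 1
  for (id in unique(tr$data$uniqueID)) {
    rows <- tr$data[tr$data$uniqueID == id, ]
    expect_length(unique(rows$dose), 1)
    expect_identical(sort(rows$cycle), seq_along(rows$cycle))
  }
  # a DLT ends the patient's follow-up at that cycle
  for (id in unique(tr$data$uniqueID)) {
    rows <- tr$data[tr$data$uniqueID == id, ]
    if (any(rows$DLT == 1))
      expect_identical(max(rows$cycle), rows$cycle[rows$DLT == 1])
  }
  # no skipping: each cohort at most one level above everything before it
  for (i in seq_along(tr$assignments)[-1])
    expect_lte(tr$assignments[i], max(tr$assignments[1:(i - 1)]) + 1L)
})

test_that("operating characteristics are conserved and match scenario truth", {
  oc <- sim_rmd(probs4, wm3, small_cfg, iter = 300, burnin = 100,
                n_trials = 3, seed = 203)
  expect_equal(sum(oc$allocation_pct), 1, tolerance = 1e-9)
  expect_equal(sum(oc$recommendation_pct) + oc$early_stop_pct, 1,
               tolerance = 1e-9)
  # the $sc block equals the analytic scenario truth exactly
  expect_equal(oc$sc[paste0("mnTTP.", 1:2), 1],
               setNames(sapply(1:2, function(t)
                 scenario_mnttp(probs4, wm3, 1, t)),
                 paste0("mnTTP.", 1:2)))
  expect_equal(unname(oc$sc["pDLT", ]),
               sapply(1:4, function(d) scenario_pdlt(probs4, wm3, d)))
  # a single trial gives an indicator recommendation vector
  oc1 <- sim_rmd(probs4, wm3, small_cfg, iter = 300, burnin = 100,
                 n_trials = 1, seed = 204)
  expect_true(sum(oc1$recommendation_pct) + oc1$early_stop_pct == 1)
  expect_true(all(oc1$recommendation_pct %in% c(0, 1)))
})

test_that("dual-endpoint trials run all three stages and stay reproducible", {
  dual_cfg <- dual_design_config(doses = 1:4, trial_size = 12,
                                 cohort_size = 3, max_cycle = 2,
                                 tox_target = 0.28, c1 = 0.28, c2 = 0.28,
                                 p1 = 0.1, p2 = 0.1, ps1 = 0.1,
                                 delta = 0.1)
  es <- eff_scenario(rep(0.5, 4), 0.2)
  tr <- simulate_trial_dual(probs4, es, wm3, dual_cfg, iter = 400,
                            burnin = 100, seed = 205)
  tr2 <- simulate_trial_dual(probs4, es, wm3, dual_cfg, iter = 400,
                             burnin = 100, seed = 205)
  expect_identical(tr$data, tr2$data)
  expect_identical(tr$recommendation, tr2$recommendation)
  if (!tr$early_stop) {
    expect_identical(tr$n_enrolled, 12L)
    # one efficacy outcome per enrolled patient
    expect_identical(nrow(tr$eff), 12L)
    expect_true(all(tr$eff$Efficacy > 0 & tr$eff$Efficacy < 1))
  }
  for (i in seq_along(tr$assignments)[-1])
    expect_lte(tr$assignments[i], max(tr$assignments[1:(i - 1)]) + 1L)
})

test_that("an over-toxic scenario mostly terminates the dual design early", {
  hot <- po_model_spec(c(-0.5, 0.5, 1.2, 2.0), c(-0.3, -0.3, -0.3), 0)
  probs_hot <- gen_tox_prob(hot, 4, 2)
  expect_gt(scenario_pdlt(probs_hot, wm3, 1), 0.5)
  dual_cfg <- dual_design_config(doses = 1:4, trial_size = 12,
                                 cohort_size = 3, max_cycle = 2,
                                 tox_target = 0.23, c1 = 0.23, c2 = 0.23,
                                 p1 = 0.1, p2 = 0.1, ps1 = 0.1,
                                 delta = 0.1)
  es <- eff_scenario(rep(0.5, 4), 0.2)
  stops <- sapply(1:8, function(s)
    simulate_trial_dual(probs_hot, es, wm3, dual_cfg, iter = 300,
                        burnin = 100, seed = 300 + s)$early_stop)
  expect_gt(mean(stops), 0.5)
})

test_that("dual operating characteristics include the efficacy truth row", {
  dual_cfg <- dual_design_config(doses = 1:4, trial_size = 9,
                                 cohort_size = 3, max_cycle = 2,
                                 tox_target = 0.28, p1 = 0.1, p2 = 0.1,
                                 ps1 = 0.1, delta = 0.1)
  es <- eff_scenario(rep(0.5, 4), 0.2)
  oc <- sim_rmd_eff(probs4, es, wm3, dual_cfg, iter = 300, burnin = 100,
                    n_trials = 2, seed = 207)
  expect_equal(unname(oc$sc["mEFF", ]), rep(0.5, 4))
  expect_equal(sum(oc$recommendation_pct) + oc$early_stop_pct, 1,
               tolerance = 1e-9)
  expect_equal(sum(oc$allocation_pct), 1, tolerance = 1e-9)
})
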