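test_that("posterior on the nine-record example tracks the least-squares fit", {
  pat <- example_trial_data()
  # independent oracle: OLS on the same design (vague priors, small
  # random-effect variance make the posterior mean land nearby)
  ols <- lm(nTTP ~ dose + cycle, data = pat)
  expect_equal(unname(coef(ols)), c(-1/6, 1/6, 1/15), tolerance = 1e-10)
  fit <- fit_tox_lmm(pat, iter = 2000, burnin = 500, seed = 101)
  post <- colMeans(fit$draws)
  expect_lt(abs(post["beta1"] - 1/6), 0.03)
  expect_lt(abs(post["beta2"] - 1/15), 0.03)
  # agreement at the doses carrying data (extrapolated doses magnify the
  # residual slope difference between the truncated posterior and OLS)
  for (d in 1:2) {
    ols_mean <- sum(coef(ols) * c(1, d, 1))
    expect_lt(abs(mean(cycle1_means(fit, d)) - ols_mean), 0.03)
  }
})

test_that("dose-effect positivity and variance positivity hold in every draw", {
  fit <- fit_tox_lmm(example_trial_data(), iter = 1500, burnin = 300,
                     seed = 5)
  expect_true(all(fit$draws[, "beta1"] > 0))
  expect_true(all(fit$draws[, "sigma_eps"] > 0))
  expect_true(all(fit$draws[, "sigma_gamma"] > 0))
})

test_that("a single observation still yields a valid posterior sample", {
  one <- data.frame(uniqueID = "p1", dose = 2, cycle = 1, nTTP = 0.3,
                    DLT = 0)
  fit <- fit_tox_lmm(one, iter = 2000, burnin = 500, seed = 6)
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(fit$draws[, "beta1"] > 0))
  # with an informative error-variance prior the one-point likelihood
  # pins the fitted value at the observed design point
  pri <- default_priors()
  pri$s2.epsilon <- parm("invgamma", shape = 3, scale = 0.02)
  fit2 <- fit_tox_lmm(one, priors = pri, iter = 2000, burnin = 500,
                      seed = 7)
  expect_lt(abs(median(cycle1_means(fit2, 2)) - 0.3), 0.15)
})

test_that("posterior surface summarizes draws exactly", {
  fit <- fake_tox_fit(beta0 = 0, beta1 = 0.1, beta2 = 0.05)
  s <- posterior_tox_surface(fit, doses = 1:3, cycles = 1:2)
  expect_equal(s["cycle1", "mean", "Dose 2"], 0.25)     # 0 + 0.2 + 0.05
  expect_equal(s["cycle2", "mean", "Dose 2"], 0.30)
  expect_equal(s["cycle1", "sd", "Dose 2"], 0)
  # quantiles weakly increasing, median equals 50% quantile
  fit2 <- fit_tox_lmm(example_trial_data(), iter = 1000, burnin = 200,
                      seed = 7)
  s2 <- posterior_tox_surface(fit2, 1:6, 1:3)
  qn <- c("2.5%", "25%", "50%", "75%", "97.5%")
  for (cy in dimnames(s2)[[1]])
    for (d in dimnames(s2)[[3]]) {
      expect_false(is.unsorted(s2[cy, qn, d]))
      expect_equal(s2[cy, "median", d], s2[cy, "50%", d])
    }
})

test_that("Gibbs agrees with a frequentist mixed-model fit under vague priors", {
  d <- simulate_lmm_data(n_patients = 60, n_cycles = 3,
                         beta = c(0.05, 0.05, 0.01), seed = 11)
  fit <- fit_tox_lmm(d, iter = 2000, burnin = 500, seed = 12)
  lmer_fit <- lme4::lmer(nTTP ~ dose + cycle + (1 | uniqueID), data = d,
                         REML = FALSE)
  fe <- lme4::fixef(lmer_fit)
  se <- sqrt(diag(as.matrix(vcov(lmer_fit))))
  post <- colMeans(fit$draws)
  expect_lt(abs(post["beta0"] - fe[1]), 3 * se[1] + 0.01)
  expect_lt(abs(post["beta1"] - fe[2]), 3 * se[2] + 0.01)
  expect_lt(abs(post["beta2"] - fe[3]), 3 * se[3] + 0.01)
})

test_that("chains with different seeds agree on the toxicity surface", {
  pat <- example_trial_data()
  f1 <- fit_tox_lmm(pat, iter = 2000, burnin = 500, seed = 21)
  f2 <- fit_tox_lmm(pat, iter = 2000, burnin = 500, seed = 22)
  for (d in 1:6) {
    v1 <- cycle1_means(f1, d); v2 <- cycle1_means(f2, d)
    mcse <- sqrt(var(v1) / length(v1) + var(v2) / length(v2))
    # block updates make draws near-independent; allow a small floor
    expect_lt(abs(mean(v1) - mean(v2)), 6 * mcse + 0.005)
  }
})

test_that("joint model with the loading pinned at zero decouples", {
  sim <- simulate_joint_data(n_patients = 40, n_cycles = 2, seed = 31)
  pri <- default_priors()
  pri$nu <- parm("normal", mean = 0, var = 1e-10)   # degenerate at 0
  jf <- fit_joint_model(sim$tox, sim$eff, priors = pri, iter = 1500,
                        burnin = 300, seed = 32)
  tf <- fit_tox_lmm(sim$tox, iter = 1500, burnin = 300, seed = 33,
                    cycle_coding = "binary")
  expect_lt(max(abs(jf$draws[, "nu"])), 1e-3)
  for (d in c(1, 4, 6))
    expect_lt(abs(mean(cycle1_means(jf, d)) - mean(cycle1_means(tf, d))),
              0.03)
})

test_that("joint model recovers known parameters on synthetic data", {
  sim <- simulate_joint_data(n_patients = 120, n_cycles = 3,
                             alpha = c(0.1, 0.15, -0.015), nu = 0.5,
                             seed = 41)
  jf <- fit_joint_model(sim$tox, sim$eff, iter = 2000, burnin = 500,
                        seed = 42)
  truth <- c(beta0 = 0.05, beta1 = 0.05, beta2 = 0.01, alpha0 = 0.1,
             alpha1 = 0.15, alpha2 = -0.015)
  for (p in names(truth)) {
    est <- mean(jf$draws[, p]); psd <- sd(jf$draws[, p])
    expect_lt(abs(est - truth[[p]]), 3 * psd)
  }
  # posterior mean efficacy curve is a quadratic in dose
  pe <- predicted_efficacy(jf, 1:6)
  a <- colMeans(jf$draws[, c("alpha0", "alpha1", "alpha2")])
  expect_equal(unname(pe), a[1] + a[2] * (1:6) + a[3] * (1:6)^2,
               tolerance = 1e-10)
})

test_that("predicted efficacy equals the draw-wise average", {
  fit <- fake_joint_fit(alpha0 = 0.1, alpha1 = 0.2, alpha2 = -0.02)
  expect_equal(unname(predicted_efficacy(fit, 3)), 0.52)
  # increasing when the quadratic term is zero and the slope positive
  fit2 <- fake_joint_fit(alpha0 = 0.1, alpha1 = 0.2, alpha2 = 0)
  expect_false(is.unsorted(predicted_efficacy(fit2, 1:6), strictly = TRUE))
  # brute-force loop over stored draws
  sim <- simulate_joint_data(n_patients = 30, n_cycles = 2, seed = 51)
  jf <- fit_joint_model(sim$tox, sim$eff, iter = 600, burnin = 100,
                        seed = 52)
  manual <- 0
  for (i in seq_len(nrow(jf$draws)))
    manual <- manual + jf$draws[i, "alpha0"] + jf$draws[i, "alpha1"] * 4 +
      jf$draws[i, "alpha2"] * 16
  expect_equal(unname(predicted_efficacy(jf, 4)),
               unname(manual) / nrow(jf$draws), tolerance = 1e-9)
})

test_that("orphan efficacy records and empty inputs are rejected", {
  sim <- simulate_joint_data(n_patients = 10, n_cycles = 2, seed = 61)
  bad_eff <- rbind(sim$eff,
                   data.frame(subID = "ghost", dose = 1, Efficacy = 0.4))
  expect_error(fit_joint_model(sim$tox, bad_eff, iter = 100, burnin = 10),
               "ghost")
  expect_error(fit_tox_lmm(sim$tox[0, ], iter = 100, burnin = 10),
               "no toxicity observations")
  expect_error(fit_tox_lmm(sim$tox, iter = 100, burnin = 200),
               "invalid MCMC sizes")
})
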