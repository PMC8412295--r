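# Shared fixtures: the default weight matrix, the two proportional-odds
# scenario parameter sets used throughout the examples, and small design
# configurations for fast simulated trials.

wm3 <- default_weight_matrix()

spec_tox <- po_model_spec(c(2, 3, 4.2, 5.7), c(-0.2, -0.4, -0.7), 0,
                          type_names = c("Renal", "Neuro", "Heme"))
spec_dual <- po_model_spec(c(1.9, 2.3, 2.6, 3.1), c(-0.3, -0.2, -0.25), 0)

flat_eff <- eff_scenario(rep(0.5, 6), 0.2)

dual_cfg_flat <- dual_design_config(
  trial_size = 36, cohort_size = 3, max_cycle = 6, tox_target = 0.23,
  c1 = 0.23, c2 = 0.23, p1 = 0.1, p2 = 0.1, ps1 = 0.1, delta = 0.1)

# Fabricate a fit object carrying exactly the given draws (point-mass or
# enumerated posteriors for deterministic decision-rule checks).
fake_tox_fit <- function(beta0, beta1, beta2, cycle_coding = "index") {
  draws <- cbind(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 sigma_eps = 0.1, sigma_gamma = 0.1)
  if (nrow(draws) == 1L) draws <- draws[c(1L, 1L), , drop = FALSE]
  structure(list(draws = draws, cycle_coding = cycle_coding),
            class = "rmd_tox_fit")
}

fake_joint_fit <- function(alpha0, alpha1, alpha2,
                           beta0 = 0, beta1 = 0.01, beta2 = 0,
                           cycle_coding = "binary") {
  draws <- cbind(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 nu = 0, sigma_eps = 0.1, sigma_gamma = 0.1,
                 sigma_e = 0.1)
  if (nrow(draws) == 1L) draws <- draws[c(1L, 1L), , drop = FALSE]
  structure(list(draws = draws, cycle_coding = cycle_coding),
            class = c("rmd_joint_fit", "rmd_tox_fit"))
}

# Cycle-1 population mean nTTP draws at a dose (re-derived here so the
# tests do not lean on the package's own internal helper).
cycle1_means <- function(fit, dose) {
  tc <- if (fit$cycle_coding == "index") 1 else 0
  fit$draws[, "beta0"] + fit$draws[, "beta1"] * dose +
    fit$draws[, "beta2"] * tc
}
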