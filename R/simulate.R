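# Whole-trial simulators and operating-characteristic summaries for the
# toxicity-only and dual-endpoint repeated-measures designs.

check_scenario_dims <- function(probs, wm, cfg) {
  probs <- validate_tox_prob(probs)
  if (dim(probs)[1L] < max(cfg$doses))
    stop("scenario has fewer dose levels than the design", call. = FALSE)
  if (dim(probs)[2L] < cfg$max_cycle)
    stop("scenario has fewer cycles than the design's max_cycle",
         call. = FALSE)
  if (dim(probs)[3L] != n_tox_types(wm))
    stop("scenario and weight matrix disagree on the number of toxicity ",
         "types", call. = FALSE)
  probs
}

# Simulate the full multi-cycle toxicity trajectory of one patient at a
# fixed dose: per-cycle grade draws, with dropout after the first
# DLT cycle (the DLT cycle itself is observed).
sim_patient_course <- function(probs, dose, wm, max_cycle) {
  nttp <- numeric(0); dlt <- integer(0)
  for (cyc in seq_len(max_cycle)) {
    out <- sample_patient_cycle(probs, dose, cyc, wm)
    nttp <- c(nttp, out$nttp); dlt <- c(dlt, as.integer(out$dlt))
    if (out$dlt) break
  }
  data.frame(cycle = seq_along(nttp), nTTP = nttp, DLT = dlt)
}

n_enrolled_sim <- function(trial)
  if (is.null(trial)) 0L else length(unique(trial$uniqueID))

# Rows of the accumulated trial table visible when cohort `current` is
# about to be enrolled: cohort b has completed min(current - b, J,
# dropout) cycles (cohorts are enrolled one cycle apart).
revealed_rows <- function(trial, current) {
  trial[trial$cycle <= (current - trial$cohort), , drop = FALSE]
}

#' Simulate one trial of the toxicity-only repeated-measures design
#'
#' Enrolls cohorts of \code{cohort_size} patients one treatment cycle
#' apart.  The first cohort receives the starting dose; every later
#' cohort receives the dose recommended by [recommend_dose_tox()] applied
#' to the toxicity data observable at that moment (each earlier cohort
#' contributes the cycles it has completed, truncated at DLT dropout).
#' After the last cohort completes treatment, the final MTD is the
#' Bayesian-risk-minimizing dose among the doses actually tried, based on
#' the complete data.
#'
#' @param probs toxicity probability array covering the design's doses
#'   and cycles.
#' @param wm a [weight_matrix()].
#' @param cfg a [design_config()].
#' @param priors,iter,burnin,thin MCMC settings for the per-decision
#'   model fits.
#' @param seed optional integer seed; a fixed seed reproduces the trial
#'   exactly.
#' @return A list of class \code{"rmd_trial"}: the patient-cycle table
#'   (\code{data}), per-cohort assigned doses, the final
#'   \code{recommendation} (\code{NA} if the trial stopped early),
#'   \code{early_stop}, and \code{n_enrolled}.
#' @export
simulate_trial_tox <- function(probs, wm, cfg, priors = default_priors(),
                               iter = 1000, burnin = 400, thin = 1,
                               seed = NULL) {
  stopifnot(inherits(cfg, "design_config"))
  probs <- check_scenario_dims(probs, wm, cfg)
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$trial_size; m <- cfg$cohort_size
  trial <- NULL
  assignments <- integer(0)
  early_stop <- FALSE
  cohort <- 0L
  while (is.null(trial) || n_enrolled_sim(trial) < N) {
    cohort <- cohort + 1L
    if (cohort == 1L) dose <- cfg$start_dose
    else {
      rec <- recommend_dose_tox(revealed_rows(trial, cohort), cfg,
                                priors = priors, iter = iter,
                                burnin = burnin, thin = thin)
      if (rec$terminated) { early_stop <- TRUE; break }
      dose <- rec$next_dose
    }
    assignments <- c(assignments, dose)
    n_new <- min(m, N - n_enrolled_sim(trial))
    for (s in seq_len(n_new)) {
      course <- sim_patient_course(probs, dose, wm, cfg$max_cycle)
      course <- cbind(
        data.frame(uniqueID = sprintf("cohort%dsubj%d", cohort, s),
                   cohort = cohort, subj = s, dose = dose),
        course)
      trial <- rbind(trial, course)
    }
  }
  recommendation <- NA_integer_
  if (!early_stop) {
    tried <- sort(unique(as.integer(trial$dose)))
    if (length(tried) < 2L) recommendation <- tried
    else {
      fit <- fit_tox_lmm(trial, priors = priors, iter = iter,
                         burnin = burnin, thin = thin,
                         cycle_coding = "index")
      risks <- bayes_risk(fit, tried, cfg$tox_target)
      recommendation <- tried[which.min(risks)]
    }
  }
  structure(list(data = trial, assignments = assignments,
                 recommendation = recommendation,
                 early_stop = early_stop,
                 n_enrolled = n_enrolled_sim(trial)),
            class = "rmd_trial")
}

new_oc <- function(alloc, recs, stops, n_trials, sc, cfg) {
  K <- length(cfg$doses)
  alloc_pct <- alloc / sum(alloc)
  rec_pct <- tabulate(recs[!is.na(recs)], K) / n_trials
  op <- rbind("Allocation %" = round(alloc_pct, 3),
              "Recommendation %" = round(rec_pct, 3))
  colnames(op) <- paste0("Dose ", cfg$doses)
  structure(list(op.table = op, sc = sc,
                 allocation_pct = alloc_pct,
                 recommendation_pct = rec_pct,
                 early_stop_pct = mean(stops),
                 recommendations = recs, n_trials = n_trials, cfg = cfg),
            class = "rmd_oc")
}

#' Operating characteristics of the toxicity-only design
#'
#' Runs independent simulated trials under a toxicity scenario and
#' summarizes the per-dose patient allocation and final-recommendation
#' percentages alongside the analytic scenario truth (mean nTTP by cycle
#' and dose, cycle-1 DLT probability by dose).
#'
#' Each trial gets its own seed derived from the master seed, so trials
#' are mutually independent and any single trial can be reproduced in
#' isolation.
#'
#' @inheritParams simulate_trial_tox
#' @param n_trials number of simulated trials.
#' @param seed master integer seed.
#' @return An object of class \code{"rmd_oc"} with components
#'   \code{op.table}, \code{sc}, \code{allocation_pct},
#'   \code{recommendation_pct}, \code{early_stop_pct} and the per-trial
#'   \code{recommendations}.
#' @export
sim_rmd <- function(probs, wm, cfg, priors = default_priors(),
                    iter = 1000, burnin = 400, thin = 1, n_trials = 100,
                    seed = NULL) {
  stopifnot(n_trials >= 1)
  probs <- check_scenario_dims(probs, wm, cfg)
  if (!is.null(seed)) set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  K <- length(cfg$doses)
  alloc <- numeric(K); recs <- rep(NA_integer_, n_trials)
  stops <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_trial_tox(probs, wm, cfg, priors = priors, iter = iter,
                             burnin = burnin, thin = thin,
                             seed = trial_seeds[i])
    pat <- unique(tr$data[c("uniqueID", "dose")])
    alloc <- alloc + tabulate(as.integer(pat$dose), K)
    recs[i] <- tr$recommendation
    stops[i] <- tr$early_stop
  }
  sc <- scenario_truth(probs[, seq_len(cfg$max_cycle), , , drop = FALSE], wm)
  new_oc(alloc, recs, stops, n_trials, sc, cfg)
}

#' Simulate one trial of the three-stage dual-endpoint design
#'
#' Like [simulate_trial_tox()] but driven by [run_trial_dual()]: stage-1
#' toxicity-only escalation for the first half of the sample, stage-2
#' adaptive randomization among allowable doses towards higher predicted
#' efficacy, and a stage-3 final selection on the complete data.  Each
#' patient contributes one beta-distributed efficacy outcome, observed
#' once the patient has completed cycle 1.  The trial terminates early
#' whenever the allowable set becomes empty.
#'
#' @inheritParams simulate_trial_tox
#' @param eff_scen an [eff_scenario()].
#' @param cfg a [dual_design_config()].
#' @return A list of class \code{"rmd_trial"} with the toxicity table
#'   (\code{data}), efficacy table (\code{eff}), per-cohort assignments,
#'   final \code{recommendation}, \code{early_stop} and
#'   \code{n_enrolled}.
#' @export
simulate_trial_dual <- function(probs, eff_scen, wm, cfg,
                                priors = default_priors(), iter = 1000,
                                burnin = 400, thin = 1, seed = NULL) {
  stopifnot(inherits(cfg, "dual_design_config"),
            inherits(eff_scen, "eff_scenario"))
  probs <- check_scenario_dims(probs, wm, cfg)
  if (length(eff_scen$mean_eff) < max(cfg$doses))
    stop("efficacy scenario has fewer dose levels than the design",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  N <- cfg$trial_size; m <- cfg$cohort_size
  trial <- NULL; effs <- NULL
  assignments <- integer(0)
  early_stop <- FALSE
  cohort <- 0L
  while (is.null(trial) || n_enrolled_sim(trial) < N) {
    cohort <- cohort + 1L
    if (cohort == 1L) dose <- cfg$start_dose
    else {
      seen <- revealed_rows(trial, cohort)
      seen_eff <- effs[effs$subID %in% seen$uniqueID, , drop = FALSE]
      rec <- run_trial_dual(seen, seen_eff, cfg, priors = priors,
                            iter = iter, burnin = burnin, thin = thin)
      if (rec$terminated) { early_stop <- TRUE; break }
      dose <- rec$next_dose
    }
    assignments <- c(assignments, dose)
    n_new <- min(m, N - n_enrolled_sim(trial))
    for (s in seq_len(n_new)) {
      id <- sprintf("cohort%dsubj%d", cohort, s)
      course <- sim_patient_course(probs, dose, wm, cfg$max_cycle)
      trial <- rbind(trial, cbind(
        data.frame(uniqueID = id, cohort = cohort, subj = s, dose = dose),
        course))
      effs <- rbind(effs, data.frame(
        subID = id, dose = dose,
        Efficacy = sample_efficacy(eff_scen, dose)))
    }
  }
  recommendation <- NA_integer_
  if (!early_stop) {
    final <- run_trial_dual(trial, effs, cfg, priors = priors, iter = iter,
                            burnin = burnin, thin = thin)
    if (!final$terminated) recommendation <- final$next_dose
    else early_stop <- TRUE
  }
  structure(list(data = trial, eff = effs, assignments = assignments,
                 recommendation = recommendation, early_stop = early_stop,
                 n_enrolled = n_enrolled_sim(trial)),
            class = "rmd_trial")
}

#' Operating characteristics of the dual-endpoint design
#'
#' Aggregates independent simulated three-stage trials and reports dose
#' allocation and recommendation percentages together with the scenario
#' truth (mean nTTP per cycle, mean efficacy, and cycle-1 DLT probability
#' per dose).
#'
#' @inheritParams simulate_trial_dual
#' @param n_trials number of simulated trials.
#' @param seed master integer seed.
#' @return An object of class \code{"rmd_oc"}.
#' @export
sim_rmd_eff <- function(probs, eff_scen, wm, cfg,
                        priors = default_priors(), iter = 1000,
                        burnin = 400, thin = 1, n_trials = 100,
                        seed = NULL) {
  stopifnot(n_trials >= 1)
  probs <- check_scenario_dims(probs, wm, cfg)
  if (!is.null(seed)) set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)
  K <- length(cfg$doses)
  alloc <- numeric(K); recs <- rep(NA_integer_, n_trials)
  stops <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_trial_dual(probs, eff_scen, wm, cfg, priors = priors,
                              iter = iter, burnin = burnin, thin = thin,
                              seed = trial_seeds[i])
    if (!is.null(tr$data)) {
      pat <- unique(tr$data[c("uniqueID", "dose")])
      alloc <- alloc + tabulate(as.integer(pat$dose), K)
    }
    recs[i] <- tr$recommendation
    stops[i] <- tr$early_stop
  }
  sc <- scenario_truth(probs[, seq_len(cfg$max_cycle), , , drop = FALSE],
                       wm, eff_scenario = eff_scen)
  new_oc(alloc, recs, stops, n_trials, sc, cfg)
}

#' @export
print.rmd_oc <- function(x, digits = 4, ...) {
  cat("Operating characteristics based on", x$n_trials, "simulations\n")
  cat("Sample size", x$cfg$trial_size, "\n\n$op.table\n")
  print(x$op.table, ...)
  if (x$early_stop_pct > 0)
    cat(sprintf("Early termination in %.1f%% of trials\n",
                100 * x$early_stop_pct))
  cat("\n$sc\n")
  print(round(x$sc, digits), ...)
  invisible(x)
}
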