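# Decision logic: Bayesian-risk dose recommendation for the toxicity-only
# design and the three-stage logic of the dual-endpoint design.

#' Bayesian risk of a dose against the cycle-1 toxicity target
#'
#' Posterior expectation of the absolute loss
#' \eqn{|\pi_Y(x, \theta, t_1) - \pi_1|}, where \eqn{\pi_Y(x, \theta,
#' t_1)} is the population mean nTTP at dose \eqn{x} in the first
#' treatment cycle and \eqn{\pi_1} the elicited target.  The dose
#' minimizing this risk is allocated to the next cohort.
#'
#' @param fit an [fit_tox_lmm()] or [fit_joint_model()] object.
#' @param dose dose level(s); vectorized.
#' @param target elicited cycle-1 target nTTP \eqn{\pi_1}.
#' @param method \code{"expected_loss"} averages the absolute loss over
#'   posterior draws (the Bayesian risk proper); \code{"point_estimate"}
#'   takes the absolute distance of the posterior mean from the target, a
#'   cruder reading useful for cross-checks.  Both rank doses identically
#'   whenever the posterior spread is comparable across doses.
#' @return Numeric risk value(s), named by dose.
#' @export
bayes_risk <- function(fit, dose, target,
                       method = c("expected_loss", "point_estimate")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "rmd_tox_fit"), nrow(fit$draws) > 0L)
  out <- vapply(dose, function(x) {
    v <- mean_nttp_draws(fit, x, cycle = 1)
    if (method == "expected_loss") mean(abs(v - target))
    else abs(mean(v) - target)
  }, numeric(1L))
  names(out) <- dose
  out
}

#' 3+3 start-up rule
#'
#' Governs escalation before data on at least two dose levels are
#' available, based on cycle-1 DLT counts at the current dose: 0/3 DLTs
#' escalate one level, 1/3 expand the same dose, at most 1/6 escalate,
#' and 2 or more DLTs de-escalate (or stop the trial when already at the
#' lowest dose).
#'
#' @param data toxicity table (see [fit_tox_lmm()]); must contain at most
#'   one dose level.
#' @param cfg a [design_config()].
#' @return The next dose level, or \code{NA} when the rule terminates the
#'   trial.
#' @export
startup_rule <- function(data, cfg) {
  stopifnot(inherits(cfg, "design_config"))
  d <- as_tox_data(data)
  if (nrow(d) == 0L) return(cfg$start_dose)
  if (length(unique(d$dose)) > 1L)
    stop("start-up rule applies only while a single dose level has data",
         call. = FALSE)
  cur <- as.integer(d$dose[1L])
  c1 <- d[d$cycle == 1, , drop = FALSE]
  n <- nrow(c1)
  ndlt <- sum(c1$DLT)
  K <- max(cfg$doses)
  esc <- min(cur + 1L, K)
  deesc <- if (cur <= min(cfg$doses)) NA_integer_ else cur - 1L
  if (n < 3L) return(cur)
  if (n < 6L) {
    if (ndlt == 0L) return(esc)
    if (ndlt == 1L) return(cur)
    return(deesc)
  }
  if (ndlt <= 1L) esc else deesc
}

new_recommendation <- function(next_dose, stage, n_enrolled, n_cohorts, cfg,
                               risks = NULL, surface = NULL,
                               allowable = NULL, pred_eff = NULL,
                               efficacious = NULL, fit = NULL) {
  structure(list(next_dose = next_dose,
                 terminated = is.na(next_dose),
                 stage = stage, n_enrolled = n_enrolled,
                 n_cohorts = n_cohorts, cfg = cfg, risks = risks,
                 surface = surface, allowable = allowable,
                 pred_eff = pred_eff, efficacious = efficacious,
                 fit = fit),
            class = "rmd_recommendation")
}

count_patients <- function(d) length(unique(d$patient))
count_cohorts <- function(d, cfg) {
  if (nrow(d) == 0L) return(0L)
  if (all(!is.na(d$cohort))) length(unique(d$cohort))
  else as.integer(ceiling(count_patients(d) / cfg$cohort_size))
}

no_skip_cap <- function(d, cfg) {
  if (nrow(d) == 0L) return(cfg$start_dose)
  min(as.integer(max(d$dose)) + 1L, max(cfg$doses))
}

#' Recommend the next dose in the toxicity-only design
#'
#' Implements the dose-finding rule of the longitudinal-toxicity design:
#' a 3+3 start-up while fewer than two dose levels carry data, then a
#' model-based rule that fits the linear mixed model and allocates the
#' dose with minimum Bayesian risk, subject to no skipping of untested
#' doses (never more than one level above the highest dose tried) and
#' ties broken toward the lower dose.
#'
#' @param data toxicity table accumulated so far; may have zero rows, in
#'   which case the starting dose is recommended.
#' @param cfg a [design_config()].
#' @param priors,iter,burnin,thin,chains,seed passed to [fit_tox_lmm()].
#' @param risk_method passed to [bayes_risk()].
#' @return An object of class \code{"rmd_recommendation"} with the next
#'   dose (or \code{NA} on termination), the decision stage
#'   (\code{"startup"} or \code{"model_tox"}), per-dose risks, and the
#'   posterior toxicity surface when the model was fitted.
#' @export
recommend_dose_tox <- function(data, cfg, priors = default_priors(),
                               iter = 2000, burnin = 500, thin = 1,
                               chains = 1, seed = NULL,
                               risk_method = "expected_loss") {
  stopifnot(inherits(cfg, "design_config"))
  d <- if (is.data.frame(data) && nrow(data) > 0L) as_tox_data(data)
       else as_tox_data(data.frame(uniqueID = character(), dose = numeric(),
                                   cycle = numeric(), nTTP = numeric()))
  n <- count_patients(d)
  ncoh <- count_cohorts(d, cfg)
  if (nrow(d) == 0L)
    return(new_recommendation(cfg$start_dose, "startup", n, ncoh, cfg))
  if (length(unique(d$dose)) < 2L)
    return(new_recommendation(startup_rule(d, cfg), "startup", n, ncoh, cfg))
  fit <- fit_tox_lmm(d, priors = priors, iter = iter, burnin = burnin,
                     thin = thin, chains = chains, seed = seed,
                     cycle_coding = "index")
  risks <- bayes_risk(fit, cfg$doses, cfg$tox_target, method = risk_method)
  cap <- no_skip_cap(d, cfg)
  cand <- cfg$doses[cfg$doses <= cap]
  nxt <- cand[which.min(risks[as.character(cand)])]
  new_recommendation(nxt, "model_tox", n, ncoh, cfg, risks = risks,
                     surface = posterior_tox_surface(fit, cfg$doses,
                                                     seq_len(cfg$max_cycle)),
                     fit = fit)
}

#' Allowable (safe) doses from posterior safety conditions
#'
#' A dose is allowable when the posterior probability that its cycle-1
#' population mean nTTP stays below \code{c1} exceeds \code{p1}, and --
#' when \code{c2}/\code{p2} are supplied -- the posterior probability
#' that its late-cycle mean nTTP stays below \code{c2} exceeds \code{p2}.
#' An empty result signals early termination of the trial.
#'
#' @param fit an [fit_tox_lmm()] or [fit_joint_model()] object (the
#'   dual-endpoint design fits with binary cycle coding so that "late
#'   cycle" is a single aggregate level).
#' @param doses dose levels to screen.
#' @param c1,p1 cycle-1 nTTP bound and probability cutoff.
#' @param c2,p2 late-cycle bound and cutoff; omit for the stage-1
#'   (cycle-1 only) condition.
#' @return Integer vector of allowable dose levels (possibly empty).
#' @export
allowable_doses <- function(fit, doses, c1, p1, c2 = NULL, p2 = NULL) {
  stopifnot(inherits(fit, "rmd_tox_fit"), nrow(fit$draws) > 0L)
  ok <- vapply(doses, function(x) {
    f1 <- mean(mean_nttp_draws(fit, x, cycle = 1) < c1)
    pass <- f1 > p1
    if (pass && !is.null(c2)) {
      f2 <- mean(mean_nttp_draws(fit, x, cycle = 2) < c2)
      pass <- f2 > p2
    }
    pass
  }, logical(1L))
  as.integer(doses[ok])
}

#' Adaptive-randomization probabilities over allowable doses
#'
#' Softmax of the predicted efficacy: dose \eqn{a} is assigned with
#' probability \eqn{\exp\{\hat{E}_a\} / \sum_{x \in A} \exp\{\hat{E}_x\}},
#' so doses with higher predicted efficacy are favoured.  The
#' probabilities are invariant to adding a constant to every predicted
#' efficacy.
#'
#' @param pred_eff named numeric vector of predicted efficacy values over
#'   the allowable doses.
#' @return Probability vector with the same names, summing to 1.
#' @export
stage2_probs <- function(pred_eff) {
  if (length(pred_eff) == 0L)
    stop("no allowable doses to randomize among", call. = FALSE)
  w <- exp(pred_eff - max(pred_eff))
  w / sum(w)
}

#' Randomize the next cohort towards higher predicted efficacy
#'
#' Samples one dose from the allowable set with [stage2_probs()]
#' probabilities (stage 2 of the dual-endpoint design).
#'
#' @inheritParams stage2_probs
#' @param seed optional integer seed.
#' @return The sampled dose level (integer), with the probability vector
#'   attached as attribute \code{"prob"}.
#' @export
randomize_stage2 <- function(pred_eff, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stage2_probs(pred_eff)
  dose <- as.integer(names(p)[sample.int(length(p), 1L, prob = p)])
  structure(dose, prob = p)
}

#' Final selection among allowable doses
#'
#' Stage-3 rule: let \eqn{l} be the allowable dose with the largest
#' predicted efficacy; every allowable dose whose predicted efficacy lies
#' within \code{delta} of dose \eqn{l}'s is declared efficacious, and the
#' lowest (safest) efficacious dose is recommended.
#'
#' @inheritParams stage2_probs
#' @param delta proximity threshold on the predicted-efficacy scale.
#' @return A list with \code{best} (the efficacy-maximizing dose),
#'   \code{efficacious} (the set H), and \code{recommended}
#'   (\code{min(H)}).
#' @export
select_efficacious <- function(pred_eff, delta) {
  if (length(pred_eff) == 0L)
    stop("no allowable doses to select from", call. = FALSE)
  stopifnot(delta >= 0)
  doses <- as.integer(names(pred_eff))
  best <- min(doses[pred_eff >= max(pred_eff)])
  H <- sort(doses[abs(pred_eff - max(pred_eff)) <= delta + 1e-12])
  list(best = best, efficacious = H, recommended = min(H))
}

#' @rdname select_efficacious
#' @param fit an [fit_joint_model()] object.
#' @param A integer vector of allowable doses.
#' @export
final_selection <- function(fit, A, delta) {
  if (length(A) == 0L)
    stop("allowable set is empty: the trial terminates without a ",
         "recommendation", call. = FALSE)
  select_efficacious(predicted_efficacy(fit, sort(A)), delta)
}

#' Dose decision for the three-stage dual-endpoint design
#'
#' Turns the accumulated toxicity and efficacy tables into the next
#' action of the toxicity-efficacy design.  The stage is set by the
#' number of patients enrolled relative to the planned maximum N:
#' \itemize{
#'   \item Stage 1 (fewer than \code{stage1_fraction * N} patients):
#'     toxicity-driven escalation.  A 3+3 start-up runs until two dose
#'     levels carry data; afterwards the toxicity submodel is fitted
#'     (binary cycle coding) and the Bayesian-risk-minimizing dose is
#'     chosen among the stage-1 allowable doses (cycle-1 safety condition
#'     with cutoff \code{ps1}).
#'   \item Stage 2 (between \code{stage1_fraction * N} and N): the joint
#'     model is refitted at every cohort, the allowable set updated with
#'     both safety conditions, and the next cohort randomized among
#'     allowable doses towards higher predicted efficacy.
#'   \item Stage 3 (N reached): the joint model is fitted to the complete
#'     data and the final recommendation is the lowest allowable dose
#'     whose predicted efficacy is within \code{delta} of the best.
#' }
#' Skipping untested dose levels is never allowed, and an empty allowable
#' set terminates the trial at any stage.
#'
#' @param data toxicity table accumulated so far.
#' @param eff efficacy table (one row per patient); required once stage 2
#'   begins.
#' @param cfg a [dual_design_config()].
#' @param priors,iter,burnin,thin,chains,seed MCMC settings for the model
#'   fits (the seed also governs the stage-2 randomization draw).
#' @return An object of class \code{"rmd_recommendation"}; on early
#'   termination \code{next_dose} is \code{NA} and \code{terminated} is
#'   \code{TRUE}.
#' @export
run_trial_dual <- function(data, eff = NULL, cfg,
                           priors = default_priors(), iter = 2000,
                           burnin = 500, thin = 1, chains = 1,
                           seed = NULL) {
  stopifnot(inherits(cfg, "dual_design_config"))
  d <- if (is.data.frame(data) && nrow(data) > 0L) as_tox_data(data)
       else as_tox_data(data.frame(uniqueID = character(), dose = numeric(),
                                   cycle = numeric(), nTTP = numeric()))
  n <- count_patients(d)
  ncoh <- count_cohorts(d, cfg)
  N <- cfg$trial_size
  n1 <- ceiling(N * cfg$stage1_fraction)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(d) == 0L)
    return(new_recommendation(cfg$start_dose, "stage1", n, ncoh, cfg))
  cap <- no_skip_cap(d, cfg)

  if (n < n1) {                                   # stage 1: toxicity only
    if (length(unique(d$dose)) < 2L)
      return(new_recommendation(startup_rule(d, cfg), "stage1", n, ncoh,
                                cfg))
    fit <- fit_tox_lmm(d, priors = priors, iter = iter, burnin = burnin,
                       thin = thin, chains = chains,
                       cycle_coding = "binary")
    A <- allowable_doses(fit, cfg$doses, cfg$c1, cfg$ps1)
    if (length(A) == 0L)
      return(new_recommendation(NA_integer_, "stage1", n, ncoh, cfg,
                                allowable = A, fit = fit))
    cand <- A[A <= cap]
    nxt <- if (length(cand) == 0L) cap else {
      risks <- bayes_risk(fit, cand, cfg$tox_target)
      cand[which.min(risks)]
    }
    return(new_recommendation(as.integer(nxt), "stage1", n, ncoh, cfg,
                              risks = bayes_risk(fit, cfg$doses,
                                                 cfg$tox_target),
                              allowable = A,
                              surface = posterior_tox_surface(
                                fit, cfg$doses, 1:2),
                              fit = fit))
  }

  if (is.null(eff) || nrow(as_eff_data(eff)) == 0L)
    stop("efficacy data are required from stage 2 onwards", call. = FALSE)
  fit <- fit_joint_model(d, eff, priors = priors, iter = iter,
                         burnin = burnin, thin = thin, chains = chains,
                         cycle_coding = "binary")
  A <- allowable_doses(fit, cfg$doses, cfg$c1, cfg$p1, cfg$c2, cfg$p2)
  stage <- if (n < N) "stage2" else "stage3"
  if (length(A) == 0L)
    return(new_recommendation(NA_integer_, stage, n, ncoh, cfg,
                              allowable = A, fit = fit))
  pe <- predicted_efficacy(fit, sort(A))
  surface <- posterior_tox_surface(fit, cfg$doses, 1:2)

  if (stage == "stage2") {                        # adaptive randomization
    cand <- A[A <= cap]
    nxt <- if (length(cand) == 0L) cap
           else as.integer(randomize_stage2(predicted_efficacy(fit, sort(cand))))
    return(new_recommendation(as.integer(nxt), "stage2", n, ncoh, cfg,
                              allowable = A, pred_eff = pe,
                              surface = surface, fit = fit))
  }
  sel <- select_efficacious(pe, cfg$delta)        # stage 3
  new_recommendation(as.integer(sel$recommended), "stage3", n, ncoh, cfg,
                     allowable = A, pred_eff = pe,
                     efficacious = sel$efficacious, surface = surface,
                     fit = fit)
}

#' @export
print.rmd_recommendation <- function(x, ...) {
  cat("Model: RMD with longitudinal toxicity",
      if (x$stage %in% c("stage1", "stage2", "stage3"))
        " and efficacy" else "", "\n", sep = "")
  cat("Doses (skeleton):\n", paste(x$cfg$doses, collapse = "   "), "\n")
  cat("The maximum sample size is:", x$cfg$trial_size, "\n")
  cat("The current enrolled number of patients are:", x$n_enrolled, "\n")
  cat("The current enrolled cohort is:", x$n_cohorts, "\n")
  if (x$stage == "stage2")
    cat("You are right now in stage 2,\n",
        "randomizing the next cohort of patients towards higher",
        "predicted efficacy...\n")
  if (!is.null(x$surface)) print(x$surface)
  if (!is.null(x$allowable))
    cat("Allowable (safe) doses:",
        if (length(x$allowable)) paste(x$allowable, collapse = " ")
        else "(none)", "\n")
  if (x$terminated)
    cat("No allowable dose remains: the trial should be terminated.\n")
  else
    cat("Next recommended dose:", x$next_dose, "\n")
  invisible(x)
}
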