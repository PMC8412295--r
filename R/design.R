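#' Design configuration for the toxicity-only repeated-measures design
#'
#' @param doses ordered vector of dose levels under investigation
#'   (integer levels 1..K).
#' @param trial_size maximum number of patients N.
#' @param cohort_size cohort size m; a new cohort is enrolled when the
#'   previous cohort has finished one treatment cycle.
#' @param max_cycle maximum number of treatment cycles J per patient.
#' @param start_dose starting dose level.
#' @param tox_target elicited target mean nTTP at cycle 1 of treatment;
#'   the Bayesian risk is the posterior expected absolute distance of a
#'   dose's cycle-1 mean nTTP from this target.
#' @return An object of class \code{"design_config"}.
#' @export
design_config <- function(doses = 1:6, trial_size = 36, cohort_size = 3,
                          max_cycle = 5, start_dose = 1,
                          tox_target = 0.28) {
  doses <- as.integer(doses)
  if (length(doses) < 1L || any(doses != seq_along(doses)))
    stop("'doses' must be the ordered levels 1..K", call. = FALSE)
  if (cohort_size < 1 || trial_size < cohort_size)
    stop("need 0 < cohort_size <= trial_size", call. = FALSE)
  if (!start_dose %in% doses)
    stop("'start_dose' must be one of 'doses'", call. = FALSE)
  if (tox_target <= 0 || tox_target >= 1)
    stop("'tox_target' must lie in (0, 1)", call. = FALSE)
  if (max_cycle < 1) stop("'max_cycle' must be >= 1", call. = FALSE)
  structure(list(doses = doses, trial_size = as.integer(trial_size),
                 cohort_size = as.integer(cohort_size),
                 max_cycle = as.integer(max_cycle),
                 start_dose = as.integer(start_dose),
                 tox_target = as.numeric(tox_target)),
            class = "design_config")
}

#' Design configuration for the three-stage dual-endpoint design
#'
#' Extends [design_config()] with the safety and efficacy tuning
#' parameters of the toxicity-efficacy design.  A dose is allowable
#' (safe) when the posterior probability that its cycle-1 mean nTTP stays
#' below \code{c1} exceeds \code{p1} and the posterior probability that
#' its late-cycle mean nTTP stays below \code{c2} exceeds \code{p2};
#' stage 1, which has no efficacy data yet, applies the cycle-1 condition
#' alone with cutoff \code{ps1}.  At the end of the trial the best
#' allowable dose by predicted efficacy defines the efficacious set as
#' all allowable doses within \code{delta} of it, and the lowest of those
#' is recommended.
#'
#' @inheritParams design_config
#' @param c1,c2 upper bounds on the mean nTTP for cycle 1 and for the
#'   later cycles.
#' @param p1,p2 posterior-probability cutoffs paired with \code{c1},
#'   \code{c2}.
#' @param ps1 stage-1 probability cutoff (cycle-1 condition only).
#' @param delta proximity threshold on the predicted-efficacy scale used
#'   in the final selection; a tuning parameter of the same order as the
#'   efficacy outcome.
#' @param stage1_fraction fraction of \code{trial_size} enrolled during
#'   stage 1 (toxicity-only escalation).
#' @return An object of class \code{c("dual_design_config",
#'   "design_config")}.
#' @export
dual_design_config <- function(doses = 1:6, trial_size = 36,
                               cohort_size = 3, max_cycle = 6,
                               start_dose = 1, tox_target = 0.28,
                               c1 = tox_target, c2 = tox_target,
                               p1 = 0.2, p2 = 0.2, ps1 = p1,
                               delta = 0.1, stage1_fraction = 0.5) {
  cfg <- design_config(doses, trial_size, cohort_size, max_cycle,
                       start_dose, tox_target)
  for (v in list(c1 = c1, c2 = c2))
    if (v <= 0 || v >= 1)
      stop("'c1' and 'c2' must lie in (0, 1)", call. = FALSE)
  for (v in list(p1 = p1, p2 = p2, ps1 = ps1))
    if (v < 0 || v >= 1)
      stop("'p1', 'p2', 'ps1' must lie in [0, 1)", call. = FALSE)
  if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)
  if (stage1_fraction <= 0 || stage1_fraction >= 1)
    stop("'stage1_fraction' must lie in (0, 1)", call. = FALSE)
  cfg$c1 <- as.numeric(c1); cfg$c2 <- as.numeric(c2)
  cfg$p1 <- as.numeric(p1); cfg$p2 <- as.numeric(p2)
  cfg$ps1 <- as.numeric(ps1)
  cfg$delta <- as.numeric(delta)
  cfg$stage1_fraction <- as.numeric(stage1_fraction)
  class(cfg) <- c("dual_design_config", "design_config")
  cfg
}
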