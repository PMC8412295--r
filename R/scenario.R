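#' Proportional-odds toxicity scenario specification
#'
#' Parametric generator of ordinal toxicity grades.  For toxicity type
#' \eqn{l} at dose level \eqn{x} and cycle \eqn{t}, the cumulative
#' probability of observing grade at most \eqn{j} is
#' \deqn{\mathrm{logit}(c_j) = \lambda_j + \zeta_l x + \psi t, \quad j = 0,\dots,3,}
#' with grade probabilities obtained by differencing and the grade-4
#' probability as \eqn{1 - c_3}.  Negative dose coefficients shift mass to
#' higher grades as the dose increases.
#'
#' @param intercepts increasing numeric vector of 4 cumulative-logit
#'   intercepts \eqn{\lambda_0 < \lambda_1 < \lambda_2 < \lambda_3}.
#' @param dose_coefs numeric vector of per-type dose coefficients
#'   \eqn{\zeta_l} (per unit dose level), one per toxicity type.
#' @param cycle_coef scalar cycle coefficient \eqn{\psi} (per unit cycle);
#'   0 makes the scenario cycle-invariant.
#' @param type_names optional labels for the toxicity types.
#' @return An object of class \code{"po_model_spec"}.
#' @export
#' @examples
#' spec <- po_model_spec(c(2, 3, 4.2, 5.7), c(-0.2, -0.4, -0.7), 0)
po_model_spec <- function(intercepts, dose_coefs, cycle_coef = 0,
                          type_names = names(dose_coefs)) {
  intercepts <- as.numeric(intercepts)
  if (length(intercepts) != 4L)
    stop("'intercepts' must contain 4 cumulative-logit intercepts",
         call. = FALSE)
  if (is.unsorted(intercepts, strictly = TRUE))
    stop("'intercepts' must be strictly increasing", call. = FALSE)
  dose_coefs <- as.numeric(dose_coefs)
  if (length(dose_coefs) < 1L)
    stop("need at least one per-type dose coefficient", call. = FALSE)
  if (!is.numeric(cycle_coef) || length(cycle_coef) != 1L)
    stop("'cycle_coef' must be a scalar", call. = FALSE)
  if (is.null(type_names)) type_names <- paste0("tox", seq_along(dose_coefs))
  structure(list(intercepts = intercepts, dose_coefs = dose_coefs,
                 cycle_coef = as.numeric(cycle_coef),
                 type_names = as.character(type_names)),
            class = "po_model_spec")
}

po_grade_probs <- function(spec, type, dose, cycle) {
  cj <- stats::plogis(spec$intercepts + spec$dose_coefs[type] * dose +
                        spec$cycle_coef * cycle)
  c(cj[1L], diff(cj), 1 - cj[4L])
}

#' Build a 4-D toxicity probability array from a proportional-odds spec
#'
#' Evaluates the cumulative-logit model on a grid of dose levels and
#' cycles, producing the (dose x cycle x type x grade) probability array
#' that drives the trial simulators.  Dose enters as the integer dose
#' level 1..K and cycle as the integer cycle index.
#'
#' @param spec a [po_model_spec()].
#' @param n_dose number of dose levels K.
#' @param n_cycle number of treatment cycles J.
#' @return A numeric array of dimension \code{c(n_dose, n_cycle, L, 5)}
#'   whose (dose, cycle, type) slices each sum to 1.
#' @export
gen_tox_prob <- function(spec, n_dose = 6, n_cycle = 5) {
  stopifnot(inherits(spec, "po_model_spec"), n_dose >= 1, n_cycle >= 1)
  L <- length(spec$dose_coefs)
  probs <- array(NA_real_, dim = c(n_dose, n_cycle, L, 5L),
                 dimnames = list(paste0("dose", seq_len(n_dose)),
                                 paste0("cycle", seq_len(n_cycle)),
                                 spec$type_names, paste0("grade", 0:4)))
  for (d in seq_len(n_dose))
    for (t in seq_len(n_cycle))
      for (l in seq_len(L))
        probs[d, t, l, ] <- po_grade_probs(spec, l, d, t)
  validate_tox_prob(probs)
}

#' Validate a toxicity probability array
#'
#' Checks that a user-supplied (dose x cycle x type x grade) array has 5
#' grade columns, non-negative entries, and unit-sum grade distributions.
#' A pre-tabulated array is the non-parametric alternative to
#' [gen_tox_prob()] when historical dose-toxicity data are available.
#'
#' @param probs 4-D numeric array (dose, cycle, type, grade 0--4).
#' @return The validated array, invisibly unchanged.
#' @export
validate_tox_prob <- function(probs) {
  if (!is.array(probs) || length(dim(probs)) != 4L || dim(probs)[4L] != 5L)
    stop("'probs' must be a 4-D array (dose x cycle x type x grade0..4)",
         call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < -1e-12))
    stop("'probs' entries must be finite and non-negative", call. = FALSE)
  sums <- apply(probs, c(1L, 2L, 3L), sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("each (dose, cycle, type) grade distribution must sum to 1",
         call. = FALSE)
  probs
}

grade_grid <- function(L) {
  g <- as.matrix(expand.grid(rep(list(0:4), L), KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- NULL
  g
}

#' True cycle-1 DLT probability at a dose
#'
#' Analytic scenario truth: assuming independent toxicity types, the
#' probability that a patient treated at the given dose experiences at
#' least one dose-limiting grade during cycle 1 is one minus the product
#' over types of the probability of staying below the type's DLT grade.
#'
#' @param probs toxicity probability array from [gen_tox_prob()] or
#'   [validate_tox_prob()].
#' @param wm a [weight_matrix()] carrying the DLT rule.
#' @param dose dose level (row index of \code{probs}).
#' @return DLT probability in [0, 1].
#' @export
scenario_pdlt <- function(probs, wm, dose) {
  stopifnot(inherits(wm, "weight_matrix"))
  probs <- validate_tox_prob(probs)
  L <- dim(probs)[3L]
  if (L != n_tox_types(wm))
    stop("probability array and weight matrix disagree on the number of types",
         call. = FALSE)
  p_safe <- 1
  for (l in seq_len(L)) {
    mg <- wm$dlt_min_grade[l]
    if (is.na(mg)) next                     # this type is never dose limiting
    p_safe <- p_safe * sum(probs[dose, 1L, l, seq_len(mg)])
  }
  1 - p_safe
}

#' True mean nTTP at a dose and cycle
#'
#' Analytic scenario truth by exhaustive enumeration: the expected nTTP is
#' the sum over all 5^L grade combinations of the profile's nTTP score
#' weighted by the product of the per-type grade probabilities
#' (independent types).
#'
#' @inheritParams scenario_pdlt
#' @param cycle cycle index (column of \code{probs}).
#' @return Expected nTTP in [0, 1].
#' @export
scenario_mnttp <- function(probs, wm, dose, cycle = 1) {
  stopifnot(inherits(wm, "weight_matrix"))
  probs <- validate_tox_prob(probs)
  L <- dim(probs)[3L]
  if (L != n_tox_types(wm))
    stop("probability array and weight matrix disagree on the number of types",
         call. = FALSE)
  grid <- grade_grid(L)
  slice <- matrix(probs[dose, cycle, , ], nrow = L)   # L x 5
  scores <- apply(grid, 1L, compute_nttp, wm = wm)
  wts <- apply(grid, 1L, function(g)
    prod(slice[cbind(seq_len(L), g + 1L)]))
  sum(scores * wts)
}

#' Scenario-truth summary table
#'
#' Mean nTTP per cycle and cycle-1 DLT probability for each dose level,
#' the block a simulator reports alongside its operating characteristics.
#'
#' @inheritParams scenario_pdlt
#' @param eff_scenario optional [eff_scenario()]; when supplied a mean
#'   efficacy row is included.
#' @return A matrix with one \code{mnTTP} row per cycle, an optional
#'   \code{mEFF} row, and a \code{pDLT} row; columns are dose levels.
#' @export
scenario_truth <- function(probs, wm, eff_scenario = NULL) {
  probs <- validate_tox_prob(probs)
  K <- dim(probs)[1L]; J <- dim(probs)[2L]
  mn <- sapply(seq_len(K), function(d)
    sapply(seq_len(J), function(t) scenario_mnttp(probs, wm, d, t)))
  mn <- matrix(mn, nrow = J)
  out <- rbind(mn, pDLT = sapply(seq_len(K), function(d)
    scenario_pdlt(probs, wm, d)))
  rownames(out) <- c(paste0("mnTTP.", seq_len(J)), "pDLT")
  if (!is.null(eff_scenario)) {
    stopifnot(inherits(eff_scenario, "eff_scenario"))
    out <- rbind(out[seq_len(J), , drop = FALSE],
                 mEFF = eff_scenario$mean_eff[seq_len(K)],
                 pDLT = out[J + 1L, ])
  }
  colnames(out) <- paste0("Dose ", seq_len(K))
  out
}

#' Sample one patient-cycle toxicity outcome
#'
#' Draws an independent grade for each toxicity type from the (dose,
#' cycle, type) slice of the probability array and scores the resulting
#' profile.
#'
#' @inheritParams scenario_mnttp
#' @return A list with components \code{grades} (integer vector),
#'   \code{nttp}, and \code{dlt}.
#' @export
sample_patient_cycle <- function(probs, dose, cycle, wm) {
  L <- dim(probs)[3L]
  grades <- integer(L)
  for (l in seq_len(L))
    grades[l] <- sample.int(5L, 1L, prob = probs[dose, cycle, l, ]) - 1L
  list(grades = grades,
       nttp = compute_nttp(grades, wm),
       dlt = is_dlt(grades, wm))
}

#' Efficacy scenario
#'
#' Per-dose mean efficacy outcomes with a common standard deviation.
#' Patient-level efficacy is drawn from a beta distribution matched to the
#' dose's mean and the common SD by the method of moments, so samples stay
#' strictly inside (0, 1).
#'
#' @param mean_eff numeric vector of per-dose mean efficacy values in
#'   (0, 1).
#' @param sd_eff common standard deviation; must satisfy
#'   \code{sd_eff^2 < mu * (1 - mu)} at every dose for valid beta moments.
#' @return An object of class \code{"eff_scenario"}.
#' @export
eff_scenario <- function(mean_eff, sd_eff = 0.2) {
  mean_eff <- as.numeric(mean_eff)
  if (any(mean_eff <= 0) || any(mean_eff >= 1))
    stop("'mean_eff' entries must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(sd_eff) || length(sd_eff) != 1L || sd_eff <= 0)
    stop("'sd_eff' must be a positive scalar", call. = FALSE)
  if (any(sd_eff^2 >= mean_eff * (1 - mean_eff)))
    stop("'sd_eff'^2 must be below mu*(1-mu) at every dose", call. = FALSE)
  structure(list(mean_eff = mean_eff, sd_eff = as.numeric(sd_eff)),
            class = "eff_scenario")
}

beta_moments <- function(mu, sigma) {
  k <- mu * (1 - mu) / sigma^2 - 1
  c(shape1 = mu * k, shape2 = (1 - mu) * k)
}

#' Sample efficacy outcomes at a dose
#'
#' @param scen an [eff_scenario()].
#' @param dose dose level (index into \code{scen$mean_eff}).
#' @param n number of draws.
#' @return Numeric vector of efficacy values in (0, 1).
#' @export
sample_efficacy <- function(scen, dose, n = 1) {
  stopifnot(inherits(scen, "eff_scenario"))
  ab <- beta_moments(scen$mean_eff[dose], scen$sd_eff)
  stats::rbeta(n, ab[1L], ab[2L])
}
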