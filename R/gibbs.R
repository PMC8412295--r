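# Conjugate Gibbs samplers for the longitudinal-toxicity linear mixed
# model and the joint toxicity-efficacy model.  All full conditionals are
# Gaussian or inverse-gamma; the dose effect is sampled from its Gaussian
# conditional truncated to (0, Inf).

rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1L, shape, rate = scale)

# N(mu, sd^2) truncated to (0, Inf); exponential rejection (Robert 1995)
# when the untruncated mass below 0 is overwhelming.
rtnorm_pos <- function(mu, sd) {
  a <- -mu / sd
  if (a < 5) {
    u <- stats::runif(1L, stats::pnorm(a), 1)
    u <- min(u, 1 - 1e-16)
    mu + sd * stats::qnorm(u)
  } else {
    alpha <- (a + sqrt(a^2 + 4)) / 2
    repeat {
      z <- a + stats::rexp(1L, alpha)
      if (stats::runif(1L) <= exp(-(z - alpha)^2 / 2)) return(mu + sd * z)
    }
  }
}

# Exact draw of the fixed-effect block (beta0, beta1, beta2) from its
# joint Gaussian full conditional truncated to beta1 > 0: beta1 comes
# from its (truncated) Gaussian marginal, then (beta0, beta2) from their
# Gaussian conditional given beta1.  Blocking the fixed effects removes
# the heavy autocorrelation a one-at-a-time scan suffers when dose and
# intercept are nearly collinear (few distinct dose levels).
draw_fixed_block <- function(XtX, Xty, s2e, prior_prec, prior_mean) {
  V <- chol2inv(chol(XtX / s2e + prior_prec))
  mu <- as.numeric(V %*% (Xty / s2e + prior_prec %*% prior_mean))
  b1 <- rtnorm_pos(mu[2L], sqrt(V[2L, 2L]))
  cond_mu <- mu[c(1L, 3L)] + V[c(1L, 3L), 2L] / V[2L, 2L] * (b1 - mu[2L])
  cond_V <- V[c(1L, 3L), c(1L, 3L)] -
    tcrossprod(V[c(1L, 3L), 2L]) / V[2L, 2L]
  b02 <- as.numeric(cond_mu + t(chol(cond_V)) %*% stats::rnorm(2L))
  c(b02[1L], b1, b02[2L])
}

# Normalize a toxicity table to columns patient, cohort, dose, cycle,
# nTTP, DLT.  Accepts either of the conventional headers (uniqueID- or
# subID-keyed).
as_tox_data <- function(data) {
  stopifnot(is.data.frame(data))
  idcol <- intersect(c("uniqueID", "subID", "patient"), names(data))[1L]
  if (is.na(idcol))
    stop("toxicity data needs a patient identifier column ",
         "('uniqueID', 'subID' or 'patient')", call. = FALSE)
  need <- c("dose", "cycle", "nTTP")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("toxicity data is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  nr <- nrow(data)
  d <- data.frame(patient = as.character(data[[idcol]]),
                  cohort = if ("cohort" %in% names(data))
                    as.integer(data$cohort) else rep(NA_integer_, nr),
                  dose = as.numeric(data$dose),
                  cycle = as.numeric(data$cycle),
                  nTTP = as.numeric(data$nTTP),
                  DLT = if ("DLT" %in% names(data))
                    as.integer(data$DLT) else rep(0L, nr),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$dose)) || any(d$dose < 1))
    stop("dose levels must be positive numbers", call. = FALSE)
  if (any(!is.finite(d$cycle)) || any(d$cycle < 1) ||
      any(d$cycle != round(d$cycle)))
    stop("cycles must be positive integers", call. = FALSE)
  if (any(!is.finite(d$nTTP)))
    stop("nTTP values must be finite", call. = FALSE)
  if (!all(d$DLT %in% c(0L, 1L)))
    stop("DLT must be 0/1", call. = FALSE)
  if (anyDuplicated(d[c("patient", "cycle")]))
    stop("duplicate patient-cycle records", call. = FALSE)
  d
}

cycle_code <- function(cycle, coding) {
  if (coding == "index") as.numeric(cycle) else as.numeric(cycle > 1)
}

gibbs_tox_chain <- function(y, x, tc, pid, npat, priors, iter, burnin, thin) {
  pr <- priors
  m0 <- pr$beta.intercept$mean; v0 <- pr$beta.intercept$var
  m1 <- pr$beta.dose$mean;      v1 <- pr$beta.dose$var
  m2 <- pr$beta.cycle$mean;     v2 <- pr$beta.cycle$var
  gmean <- pr$gamma$mean
  ag <- pr$s2.gamma$shape;   bg <- pr$s2.gamma$scale
  ae <- pr$s2.epsilon$shape; be <- pr$s2.epsilon$scale
  n <- length(y)
  ni <- tabulate(pid, npat)
  X <- cbind(1, x, tc)
  XtX <- crossprod(X)
  prior_prec <- diag(1 / c(v0, v1, v2))
  prior_mean <- c(m0, m1, m2)
  s2e <- 1; s2g <- 1
  g <- rep(0, npat)
  keep <- rep(FALSE, iter); keep[seq.int(burnin + 1L, iter, by = thin)] <- TRUE
  nkeep <- sum(keep)
  draws <- matrix(NA_real_, nkeep, 5L,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2",
                                          "sigma_eps", "sigma_gamma")))
  gdraws <- matrix(NA_real_, nkeep, npat)
  k <- 0L
  for (it in seq_len(iter)) {
    gp <- g[pid]
    b <- draw_fixed_block(XtX, crossprod(X, y - gp), s2e, prior_prec,
                          prior_mean)
    b0 <- b[1L]; b1 <- b[2L]; b2 <- b[3L]
    r <- y - b0 - b1 * x - b2 * tc
    rs <- as.numeric(rowsum(r, pid))
    gprec <- ni / s2e + 1 / s2g
    g <- stats::rnorm(npat, (rs / s2e + gmean / s2g) / gprec,
                      sqrt(1 / gprec))
    s2g <- rinvgamma1(ag + npat / 2, bg + sum((g - gmean)^2) / 2)
    resid <- r - g[pid]
    s2e <- rinvgamma1(ae + n / 2, be + sum(resid^2) / 2)
    if (keep[it]) {
      k <- k + 1L
      draws[k, ] <- c(b0, b1, b2, sqrt(s2e), sqrt(s2g))
      gdraws[k, ] <- g
    }
  }
  list(draws = draws, gamma = gdraws)
}

#' Fit the longitudinal-toxicity linear mixed model by Gibbs sampling
#'
#' Bayesian random-intercept model for repeated nTTP measurements,
#' \deqn{y_{ij} = \beta_0 + \beta_1 x_i + \beta_2 t_j + \gamma_i +
#'   \varepsilon_{ij}, \qquad \beta_1 > 0,}
#' with patient random intercepts \eqn{\gamma_i \sim N(0, \sigma^2_\gamma)}
#' and measurement error \eqn{\varepsilon_{ij} \sim N(0,
#' \sigma^2_\varepsilon)}.  The positivity restriction on the dose effect
#' encodes the monotone dose-toxicity assumption.  All full conditionals
#' are conjugate (Gaussian for the fixed and random effects, the dose
#' effect truncated to the positive half line, inverse-gamma for both
#' variances), so the posterior is explored by a Gibbs scan with a
#' deterministic warm start (variances at 1, random intercepts at 0).
#' The fixed effects are drawn as one block from their joint Gaussian
#' conditional, which keeps the chain well mixed even when only a few
#' dose levels carry data.
#'
#' Unequal numbers of cycles per patient are handled naturally, which is
#' how post-DLT dropout enters the likelihood.
#'
#' @param data toxicity table: one row per patient-cycle with a patient
#'   identifier column (\code{uniqueID}, \code{subID} or \code{patient})
#'   plus \code{dose}, \code{cycle}, \code{nTTP} and optionally
#'   \code{DLT}/\code{cohort}.
#' @param priors prior blocks as from [default_priors()]; missing blocks
#'   are filled with the defaults.  The \code{gamma} block centres the
#'   random intercepts; their spread is the hierarchical variance
#'   \code{s2.gamma}.
#' @param iter,burnin,thin,chains MCMC sizes; the retained sample pools
#'   post-burn-in, thinned draws from all chains.
#' @param seed optional integer seed for reproducibility.
#' @param cycle_coding \code{"index"} codes cycle \eqn{t_j = j} (the
#'   longitudinal toxicity design); \code{"binary"} codes cycle 1 as 0 and
#'   all later cycles as 1 (the dual-endpoint design, whose safety rules
#'   evaluate first-cycle and aggregate late-cycle toxicity).
#' @return An object of class \code{"rmd_tox_fit"}: retained draws of
#'   \eqn{(\beta_0, \beta_1, \beta_2, \sigma_\varepsilon, \sigma_\gamma)},
#'   random-intercept draws, the normalized data, and the MCMC metadata.
#' @seealso [posterior_tox_surface()], [bayes_risk()], [fit_joint_model()]
#' @export
fit_tox_lmm <- function(data, priors = default_priors(), iter = 2000,
                        burnin = 500, thin = 1, chains = 1, seed = NULL,
                        cycle_coding = c("index", "binary")) {
  cycle_coding <- match.arg(cycle_coding)
  priors <- check_priors(priors)
  d <- as_tox_data(data)
  if (nrow(d) == 0L) stop("no toxicity observations", call. = FALSE)
  if (iter <= 0 || burnin < 0 || burnin >= iter || thin < 1 || chains < 1)
    stop("invalid MCMC sizes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pats <- unique(d$patient)
  pid <- match(d$patient, pats)
  tc <- cycle_code(d$cycle, cycle_coding)
  res <- lapply(seq_len(chains), function(ch)
    gibbs_tox_chain(d$nTTP, d$dose, tc, pid, length(pats), priors,
                    iter, burnin, thin))
  structure(
    list(draws = do.call(rbind, lapply(res, `[[`, "draws")),
         gamma = do.call(rbind, lapply(res, `[[`, "gamma")),
         patients = pats, data = d, cycle_coding = cycle_coding,
         priors = priors,
         mcmc = list(iter = iter, burnin = burnin, thin = thin,
                     chains = chains, seed = seed)),
    class = "rmd_tox_fit")
}

gibbs_joint_chain <- function(y, x, tc, pid, npat, E, epat, xe, priors,
                              iter, burnin, thin) {
  pr <- priors
  m0 <- pr$beta.intercept$mean; v0 <- pr$beta.intercept$var
  m1 <- pr$beta.dose$mean;      v1 <- pr$beta.dose$var
  m2 <- pr$beta.cycle$mean;     v2 <- pr$beta.cycle$var
  gmean <- pr$gamma$mean
  ag <- pr$s2.gamma$shape;   bg <- pr$s2.gamma$scale
  ae <- pr$s2.epsilon$shape; be <- pr$s2.epsilon$scale
  af <- pr$s2.eff$shape;     bf <- pr$s2.eff$scale
  phi_m <- c(rep(pr$alpha$mean, 3L), pr$nu$mean)
  phi_prec0 <- diag(1 / c(rep(pr$alpha$var, 3L), pr$nu$var))
  n <- length(y); ne <- length(E)
  ni <- tabulate(pid, npat)
  # per-patient efficacy bookkeeping (0/1 indicator, value, dose)
  has_eff <- rep(0, npat); Epat <- rep(0, npat); xpat <- rep(0, npat)
  has_eff[epat] <- 1; Epat[epat] <- E; xpat[epat] <- xe
  X <- cbind(1, x, tc)
  XtX <- crossprod(X)
  prior_prec <- diag(1 / c(v0, v1, v2))
  prior_mean <- c(m0, m1, m2)
  s2e <- 1; s2g <- 1; s2f <- 1
  phi <- c(0, 0, 0, 0)   # (alpha0, alpha1, alpha2, nu)
  g <- rep(0, npat)
  keep <- rep(FALSE, iter); keep[seq.int(burnin + 1L, iter, by = thin)] <- TRUE
  nkeep <- sum(keep)
  draws <- matrix(NA_real_, nkeep, 10L, dimnames = list(NULL,
    c("beta0", "beta1", "beta2", "alpha0", "alpha1", "alpha2", "nu",
      "sigma_eps", "sigma_gamma", "sigma_e")))
  gdraws <- matrix(NA_real_, nkeep, npat)
  k <- 0L
  for (it in seq_len(iter)) {
    gp <- g[pid]
    b <- draw_fixed_block(XtX, crossprod(X, y - gp), s2e, prior_prec,
                          prior_mean)
    b0 <- b[1L]; b1 <- b[2L]; b2 <- b[3L]
    # random intercepts: toxicity residuals + efficacy residuals + prior
    r <- y - b0 - b1 * x - b2 * tc
    rs <- as.numeric(rowsum(r, pid))
    nu <- phi[4L]
    Eres <- Epat - phi[1L] - phi[2L] * xpat - phi[3L] * xpat^2
    gprec <- ni / s2e + 1 / s2g + has_eff * nu^2 / s2f
    gnum <- rs / s2e + gmean / s2g + has_eff * nu * Eres / s2f
    g <- stats::rnorm(npat, gnum / gprec, sqrt(1 / gprec))
    # efficacy regression (alpha0, alpha1, alpha2, nu) as one block
    Z <- cbind(1, xe, xe^2, g[epat])
    V <- chol2inv(chol(crossprod(Z) / s2f + phi_prec0))
    mn <- V %*% (crossprod(Z, E) / s2f + phi_prec0 %*% phi_m)
    phi <- as.numeric(mn + t(chol(V)) %*% stats::rnorm(4L))
    # variances
    s2g <- rinvgamma1(ag + npat / 2, bg + sum((g - gmean)^2) / 2)
    resid <- r - g[pid]
    s2e <- rinvgamma1(ae + n / 2, be + sum(resid^2) / 2)
    eres <- E - Z %*% phi
    s2f <- rinvgamma1(af + ne / 2, bf + sum(eres^2) / 2)
    if (keep[it]) {
      k <- k + 1L
      draws[k, ] <- c(b0, b1, b2, phi, sqrt(s2e), sqrt(s2g), sqrt(s2f))
      gdraws[k, ] <- g
    }
  }
  list(draws = draws, gamma = gdraws)
}

# Normalize an efficacy table to columns patient, dose, efficacy.
as_eff_data <- function(eff) {
  stopifnot(is.data.frame(eff))
  idcol <- intersect(c("subID", "uniqueID", "patient"), names(eff))[1L]
  if (is.na(idcol))
    stop("efficacy data needs a patient identifier column", call. = FALSE)
  effcol <- intersect(c("Efficacy", "efficacy"), names(eff))[1L]
  if (is.na(effcol) || !"dose" %in% names(eff))
    stop("efficacy data needs 'dose' and 'Efficacy' columns", call. = FALSE)
  d <- data.frame(patient = as.character(eff[[idcol]]),
                  dose = as.numeric(eff$dose),
                  efficacy = as.numeric(eff[[effcol]]),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(d$efficacy)) || any(d$efficacy <= 0) ||
      any(d$efficacy >= 1))
    stop("efficacy outcomes must lie strictly in (0, 1)", call. = FALSE)
  if (anyDuplicated(d$patient))
    stop("duplicate efficacy records for a patient", call. = FALSE)
  d
}

#' Fit the joint toxicity-efficacy model by Gibbs sampling
#'
#' Extends [fit_tox_lmm()] with a second submodel for a single continuous
#' efficacy outcome per patient,
#' \deqn{E_i = \alpha_0 + \alpha_1 x_i + \alpha_2 x_i^2 + \nu \gamma_i +
#'   \epsilon_{ei},}
#' sharing the patient random intercept \eqn{\gamma_i} with the toxicity
#' submodel (a compound-symmetric toxicity-efficacy linkage whose strength
#' is the loading \eqn{\nu}).  The quadratic dose term admits
#' non-monotone dose-efficacy shapes.  Given \eqn{\gamma} all full
#' conditionals remain conjugate; the efficacy regression block
#' \eqn{(\alpha_0, \alpha_1, \alpha_2, \nu)} is drawn jointly from its
#' multivariate-Gaussian conditional.
#'
#' @inheritParams fit_tox_lmm
#' @param eff efficacy table: one row per patient with columns
#'   \code{subID} (or \code{patient}), \code{dose}, \code{Efficacy}.
#'   Every efficacy patient must appear in the toxicity table.
#' @param cycle_coding defaults to \code{"binary"} (cycle 1 coded 0,
#'   later cycles 1), the coding under which the dual-endpoint safety
#'   conditions evaluate first-cycle and late-cycle mean toxicity.
#' @return An object of class \code{c("rmd_joint_fit", "rmd_tox_fit")}
#'   whose draws additionally contain \eqn{\alpha_0, \alpha_1, \alpha_2,
#'   \nu, \sigma_e}.
#' @seealso [predicted_efficacy()], [allowable_doses()]
#' @export
fit_joint_model <- function(data, eff, priors = default_priors(),
                            iter = 2000, burnin = 500, thin = 1, chains = 1,
                            seed = NULL,
                            cycle_coding = c("binary", "index")) {
  cycle_coding <- match.arg(cycle_coding)
  priors <- check_priors(priors)
  d <- as_tox_data(data)
  e <- as_eff_data(eff)
  if (nrow(d) == 0L || nrow(e) == 0L)
    stop("both toxicity and efficacy data are required", call. = FALSE)
  if (iter <= 0 || burnin < 0 || burnin >= iter || thin < 1 || chains < 1)
    stop("invalid MCMC sizes", call. = FALSE)
  pats <- unique(d$patient)
  orphan <- setdiff(e$patient, pats)
  if (length(orphan))
    stop("efficacy records without toxicity data: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pid <- match(d$patient, pats)
  epat <- match(e$patient, pats)
  tc <- cycle_code(d$cycle, cycle_coding)
  res <- lapply(seq_len(chains), function(ch)
    gibbs_joint_chain(d$nTTP, d$dose, tc, pid, length(pats),
                      e$efficacy, epat, e$dose, priors, iter, burnin, thin))
  structure(
    list(draws = do.call(rbind, lapply(res, `[[`, "draws")),
         gamma = do.call(rbind, lapply(res, `[[`, "gamma")),
         patients = pats, data = d, eff = e, cycle_coding = cycle_coding,
         priors = priors,
         mcmc = list(iter = iter, burnin = burnin, thin = thin,
                     chains = chains, seed = seed)),
    class = c("rmd_joint_fit", "rmd_tox_fit"))
}

# Draw-wise population mean nTTP at a dose for a given treatment cycle,
# honoring the fit's cycle coding.
mean_nttp_draws <- function(fit, dose, cycle = 1) {
  tc <- cycle_code(cycle, fit$cycle_coding)
  fit$draws[, "beta0"] + fit$draws[, "beta1"] * dose +
    fit$draws[, "beta2"] * tc
}

#' Posterior summary surface of mean nTTP by dose and cycle
#'
#' Summarizes, for each requested dose and cycle, the draw-wise
#' population-level mean nTTP \eqn{\beta_0 + \beta_1 x + \beta_2 t}
#' (random intercepts excluded).
#'
#' @param fit an [fit_tox_lmm()] or [fit_joint_model()] object.
#' @param doses dose levels to evaluate.
#' @param cycles cycle indices to evaluate.
#' @return A 3-D array \code{[cycle, statistic, dose]} of class
#'   \code{"tox_surface"} with statistics mean, sd, median and the 2.5,
#'   25, 50, 75 and 97.5 percent quantiles.
#' @export
posterior_tox_surface <- function(fit, doses = 1:6, cycles = 1:6) {
  stopifnot(inherits(fit, "rmd_tox_fit"), nrow(fit$draws) > 0L)
  stats_names <- c("mean", "sd", "median", "2.5%", "25%", "50%", "75%",
                   "97.5%")
  out <- array(NA_real_,
               dim = c(length(cycles), length(stats_names), length(doses)),
               dimnames = list(paste0("cycle", cycles), stats_names,
                               paste0("Dose ", doses)))
  for (ci in seq_along(cycles)) {
    for (di in seq_along(doses)) {
      v <- mean_nttp_draws(fit, doses[di], cycles[ci])
      q <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
      out[ci, , di] <- c(mean(v), stats::sd(v), stats::median(v), q)
    }
  }
  structure(out, class = "tox_surface", doses = doses, cycles = cycles)
}

#' @export
print.tox_surface <- function(x, digits = 3, ...) {
  cat("Posterior estimates (mean) of toxicity:\n")
  m <- t(x[, "mean", , drop = TRUE])
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                   dimnames = list(NULL, dimnames(x)[[3L]]))
  m <- t(m)
  rownames(m) <- paste0("toxpf", attr(x, "cycles"))
  print(round(m, digits), ...)
  invisible(x)
}

#' Posterior predicted efficacy at a dose
#'
#' The posterior mean of the population-level efficacy
#' \eqn{\alpha_0 + \alpha_1 x + \alpha_2 x^2} (random effect excluded),
#' the quantity driving adaptive randomization and final dose selection
#' in the dual-endpoint design.
#'
#' @param fit an [fit_joint_model()] object.
#' @param dose dose level(s); vectorized.
#' @return Numeric vector of predicted efficacy values, named by dose.
#' @export
predicted_efficacy <- function(fit, dose) {
  stopifnot(inherits(fit, "rmd_joint_fit"))
  out <- vapply(dose, function(x)
    mean(fit$draws[, "alpha0"] + fit$draws[, "alpha1"] * x +
           fit$draws[, "alpha2"] * x^2), numeric(1L))
  names(out) <- dose
  out
}

#' @export
print.rmd_tox_fit <- function(x, ...) {
  cat(if (inherits(x, "rmd_joint_fit"))
    "Joint toxicity-efficacy model fit" else
      "Longitudinal toxicity mixed-model fit",
    sprintf("(%d retained draws, %d patients, %d observations)\n",
            nrow(x$draws), length(x$patients), nrow(x$data)))
  print(round(colMeans(x$draws), 4))
  invisible(x)
}
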