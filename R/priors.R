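#' Prior distribution specification for one parameter block
#'
#' Mirrors the usual control-list idiom of Bayesian dose-finding software:
#' normal priors for location parameters, inverse-gamma priors for
#' variances.
#'
#' @param dist \code{"normal"} or \code{"invgamma"}.
#' @param mean,var mean and variance of a normal prior.
#' @param shape,scale shape and scale of an inverse-gamma prior (density
#'   proportional to \code{x^-(shape+1) * exp(-scale/x)}).
#' @return A list of class \code{"rmd_parm"}.
#' @export
#' @examples
#' parm("normal", mean = 0, var = 1000)
#' parm("invgamma", shape = 0.001, scale = 0.001)
parm <- function(dist = c("normal", "invgamma"), mean = 0, var = 1000,
                 shape = 0.001, scale = 0.001) {
  dist <- match.arg(dist)
  if (dist == "normal") {
    if (var <= 0) stop("normal prior variance must be positive", call. = FALSE)
    out <- list(dist = dist, mean = mean, var = var)
  } else {
    if (shape <= 0 || scale <= 0)
      stop("inverse-gamma shape and scale must be positive", call. = FALSE)
    out <- list(dist = dist, shape = shape, scale = scale)
  }
  structure(out, class = "rmd_parm")
}

#' Default vague priors for the longitudinal toxicity and joint models
#'
#' Normal(0, 1000) on the intercept, dose and cycle effects (the dose
#' effect is additionally restricted positive at sampling time),
#' Normal(0, 100) as the prior centre for the patient random intercepts,
#' Inverse-Gamma(0.001, 0.001) on both variance components, and for the
#' joint model Normal(0, 1000) on the efficacy regression coefficients and
#' the shared random-effect loading with Inverse-Gamma(0.001, 0.001) on
#' the efficacy error variance.
#'
#' @return Named list of [parm()] blocks: \code{beta.intercept},
#'   \code{beta.dose}, \code{beta.cycle}, \code{gamma}, \code{s2.gamma},
#'   \code{s2.epsilon}, \code{alpha}, \code{nu}, \code{s2.eff}.
#' @export
default_priors <- function() {
  list(
    beta.intercept = parm("normal", mean = 0, var = 1000),
    beta.dose = parm("normal", mean = 0, var = 1000),
    beta.cycle = parm("normal", mean = 0, var = 1000),
    gamma = parm("normal", mean = 0, var = 100),
    s2.gamma = parm("invgamma", shape = 0.001, scale = 0.001),
    s2.epsilon = parm("invgamma", shape = 0.001, scale = 0.001),
    alpha = parm("normal", mean = 0, var = 1000),
    nu = parm("normal", mean = 0, var = 1000),
    s2.eff = parm("invgamma", shape = 0.001, scale = 0.001))
}

check_priors <- function(priors) {
  base <- default_priors()
  if (is.null(priors)) return(base)
  stopifnot(is.list(priors))
  unknown <- setdiff(names(priors), names(base))
  if (length(unknown))
    stop("unknown prior block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(priors)] <- priors
  for (b in base)
    if (!inherits(b, "rmd_parm"))
      stop("prior blocks must be built with parm()", call. = FALSE)
  base
}
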