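#' Elicited toxicity weight matrix
#'
#' Container for the clinician-elicited severity weights that turn a
#' multi-type, multi-grade toxicity profile into a single quasi-continuous
#' score (the normalized total toxicity profile, nTTP), together with the
#' per-type dose-limiting-toxicity (DLT) rule and the normalization
#' constant.
#'
#' Each row of \code{weights} holds the severity weights of one toxicity
#' type across CTCAE grades 0 to 4.  Weights must be non-negative,
#' non-decreasing in grade, and zero at grade 0 (no toxicity carries no
#' burden).  The normalization constant \code{toxmax} must be at least the
#' Euclidean norm of the per-type maximal weights so that every possible
#' profile scores in [0, 1].
#'
#' @param weights numeric matrix with one row per toxicity type and 5
#'   columns (grades 0--4).
#' @param type_names character vector of toxicity-type labels; defaults to
#'   the row names of \code{weights}.
#' @param toxmax positive normalization constant.
#' @param dlt_min_grade integer vector, one entry per type: the smallest
#'   grade whose occurrence counts as a DLT for that type, or \code{NA}
#'   if no grade of the type is dose limiting.
#'
#' @return An object of class \code{"weight_matrix"}.
#' @seealso [default_weight_matrix()], [compute_nttp()], [is_dlt()]
#' @export
#' @examples
#' wm <- default_weight_matrix()
#' compute_nttp(c(1, 2, 0), wm)
weight_matrix <- function(weights, type_names = rownames(weights), toxmax,
                          dlt_min_grade) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (ncol(weights) != 5L)
    stop("'weights' must have 5 columns (grades 0 to 4)", call. = FALSE)
  L <- nrow(weights)
  if (L < 1L) stop("'weights' must have at least one row", call. = FALSE)
  if (is.null(type_names)) type_names <- paste0("tox", seq_len(L))
  if (length(type_names) != L)
    stop("'type_names' must have one entry per toxicity type", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("severity weights must be finite and non-negative", call. = FALSE)
  if (any(weights[, 1L] != 0))
    stop("grade-0 weights must be 0 for every toxicity type", call. = FALSE)
  if (any(apply(weights, 1L, is.unsorted)))
    stop("weights must be non-decreasing in grade within each type",
         call. = FALSE)
  if (!is.numeric(toxmax) || length(toxmax) != 1L || toxmax <= 0)
    stop("'toxmax' must be a positive scalar", call. = FALSE)
  max_score <- sqrt(sum(apply(weights, 1L, max)^2))
  if (toxmax < max_score)
    stop(sprintf(
      "'toxmax' (%g) is below the maximal profile score (%g); nTTP would exceed 1",
      toxmax, max_score), call. = FALSE)
  dlt_min_grade <- as.integer(dlt_min_grade)
  if (length(dlt_min_grade) != L)
    stop("'dlt_min_grade' must have one entry per toxicity type", call. = FALSE)
  if (any(!is.na(dlt_min_grade) & (dlt_min_grade < 1L | dlt_min_grade > 4L)))
    stop("'dlt_min_grade' entries must be in 1..4 or NA", call. = FALSE)
  dimnames(weights) <- list(type_names, paste0("grade", 0:4))
  structure(
    list(type_names = as.character(type_names), weights = weights,
         toxmax = as.numeric(toxmax), dlt_min_grade = dlt_min_grade),
    class = "weight_matrix")
}

#' Default three-type weight matrix
#'
#' The worked example used throughout the package: renal, neurological and
#' hematological toxicities with grade weights (0, 0.5, 0.75, 1, 1.5) for
#' the first two types and (0, 0, 0, 0.5, 1) for the hematological type,
#' normalization constant 2.5, and the DLT rule "grade >= 3 renal or
#' neurological, or grade 4 hematological".
#'
#' @return A \code{"weight_matrix"} object with three toxicity types.
#' @export
default_weight_matrix <- function() {
  weight_matrix(
    weights = rbind(
      Renal = c(0, 0.5, 0.75, 1, 1.5),
      Neurological = c(0, 0.5, 0.75, 1, 1.5),
      Hematological = c(0, 0, 0, 0.5, 1)),
    toxmax = 2.5,
    dlt_min_grade = c(3L, 3L, 4L))
}

n_tox_types <- function(wm) length(wm$type_names)

validate_grades <- function(grades, wm) {
  if (length(grades) != n_tox_types(wm))
    stop(sprintf("expected %d grades (one per toxicity type), got %d",
                 n_tox_types(wm), length(grades)), call. = FALSE)
  if (any(!is.finite(grades)) || any(grades != round(grades)) ||
      any(grades < 0) || any(grades > 4))
    stop("grades must be integers between 0 and 4", call. = FALSE)
  as.integer(grades)
}

#' Normalized total toxicity profile (nTTP) score
#'
#' Scores one patient-cycle toxicity profile.  With \eqn{w_{lh}} the
#' elicited weight of toxicity type \eqn{l} at grade \eqn{h} and
#' \eqn{G_l} the maximum observed grade of type \eqn{l}, the score is the
#' Euclidean norm of the realized weights divided by the normalization
#' constant \eqn{v}:
#' \deqn{\mathrm{nTTP} = \sqrt{\sum_l w_{l,G_l}^2} \; / \; v.}
#' The normalization constraint on \eqn{v} (see [weight_matrix()])
#' guarantees a value in [0, 1]; a profile with no toxicity scores 0.
#'
#' @param grades integer vector of observed maximum grades (0--4), one per
#'   toxicity type, in the order of \code{wm$type_names}.
#' @param wm a [weight_matrix()].
#' @return nTTP score in [0, 1].
#' @export
#' @examples
#' compute_nttp(c(1, 2, 0), default_weight_matrix())
compute_nttp <- function(grades, wm) {
  stopifnot(inherits(wm, "weight_matrix"))
  grades <- validate_grades(grades, wm)
  w <- wm$weights[cbind(seq_along(grades), grades + 1L)]
  sqrt(sum(w^2)) / wm$toxmax
}

#' Dose-limiting toxicity status of a profile
#'
#' A profile is a DLT when any toxicity type reaches its per-type minimal
#' dose-limiting grade (by default grade 3 for renal/neurological and
#' grade 4 for hematological toxicity).
#'
#' @inheritParams compute_nttp
#' @return \code{TRUE} if the profile constitutes a DLT.
#' @export
is_dlt <- function(grades, wm) {
  stopifnot(inherits(wm, "weight_matrix"))
  grades <- validate_grades(grades, wm)
  any(!is.na(wm$dlt_min_grade) & grades >= wm$dlt_min_grade)
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat("Toxicity weight matrix (", length(x$type_names), " types, toxmax = ",
      x$toxmax, ")\n", sep = "")
  m <- cbind(as.data.frame(x$weights),
             DLT.at.grade = ifelse(is.na(x$dlt_min_grade), "-",
                                   paste0(">=", x$dlt_min_grade)))
  print(m, ...)
  invisible(x)
}
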