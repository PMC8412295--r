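# Tabular interchange (CSV), YAML configuration, and the fixture
# generator that reconstructs the package's worked-example inputs.

stop_parse <- function(path, row, msg)
  stop(sprintf("%s: row %s: %s", path, row, msg), call. = FALSE)

#' Read a longitudinal toxicity table
#'
#' Reads a CSV with one row per patient-cycle.  The header must contain a
#' patient identifier (\code{uniqueID} or \code{subID}) plus
#' \code{dose}, \code{cycle}, \code{nTTP}, and optionally \code{cohort},
#' \code{subj} and \code{DLT}.  Validation failures report the offending
#' row.
#'
#' @param path CSV file path.
#' @return A validated data frame with canonical columns
#'   (\code{patient}, \code{cohort}, \code{dose}, \code{cycle},
#'   \code{nTTP}, \code{DLT}).
#' @export
read_tox_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("uniqueID", "subID", "patient"), names(raw))[1L]
  if (is.na(idcol))
    stop(path, ": missing patient identifier column ",
         "('uniqueID' or 'subID')", call. = FALSE)
  for (col in c("dose", "cycle", "nTTP")) {
    if (!col %in% names(raw))
      stop(path, ": missing required column '", col, "'", call. = FALSE)
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_parse(path, bad[1L], paste0("non-numeric '", col, "'"))
    raw[[col]] <- v
  }
  bad <- which(raw$cycle < 1 | raw$cycle != round(raw$cycle))
  if (length(bad)) stop_parse(path, bad[1L], "cycle must be a positive integer")
  bad <- which(raw$nTTP < 0 | raw$nTTP > 1)
  if (length(bad)) stop_parse(path, bad[1L], "nTTP outside [0, 1]")
  if ("DLT" %in% names(raw)) {
    bad <- which(!raw$DLT %in% c(0, 1))
    if (length(bad)) stop_parse(path, bad[1L], "DLT must be 0 or 1")
  }
  dup <- which(duplicated(raw[c(idcol, "cycle")]))
  if (length(dup)) stop_parse(path, dup[1L], "duplicate patient-cycle record")
  as_tox_data(raw)
}

#' Read a per-patient efficacy table
#'
#' Reads a CSV with columns \code{subID}, \code{dose}, \code{Efficacy}
#' (one row per patient, efficacy strictly inside (0, 1)).
#'
#' @param path CSV file path.
#' @return A validated data frame with columns \code{patient},
#'   \code{dose}, \code{efficacy}.
#' @export
read_eff_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  idcol <- intersect(c("subID", "uniqueID", "patient"), names(raw))[1L]
  if (is.na(idcol))
    stop(path, ": missing patient identifier column ('subID')",
         call. = FALSE)
  if (!all(c("dose") %in% names(raw)) ||
      !any(c("Efficacy", "efficacy") %in% names(raw)))
    stop(path, ": needs 'dose' and 'Efficacy' columns", call. = FALSE)
  effcol <- intersect(c("Efficacy", "efficacy"), names(raw))[1L]
  v <- suppressWarnings(as.numeric(raw[[effcol]]))
  bad <- which(!is.finite(v))
  if (length(bad)) stop_parse(path, bad[1L], "non-numeric efficacy")
  bad <- which(v <= 0 | v >= 1)
  if (length(bad))
    stop_parse(path, bad[1L], "efficacy outside the open interval (0, 1)")
  dup <- which(duplicated(raw[[idcol]]))
  if (length(dup)) stop_parse(path, dup[1L], "duplicate patient record")
  as_eff_data(raw)
}

#' Write toxicity / efficacy tables in the conventional layout
#'
#' @param data a toxicity table (any accepted layout) or efficacy table.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_tox_table <- function(data, path) {
  d <- as_tox_data(data)
  out <- data.frame(uniqueID = d$patient, cohort = d$cohort,
                    subj = stats::ave(seq_len(nrow(d)), d$patient,
                                      FUN = function(i) seq_along(i)),
                    dose = d$dose, cycle = d$cycle, nTTP = d$nTTP,
                    DLT = d$DLT)
  # subj is the within-cohort subject number when cohorts are known
  if (all(!is.na(d$cohort))) {
    key <- !duplicated(d$patient)
    idx <- stats::ave(as.integer(key[key]),
                      d$cohort[key], FUN = seq_along)
    out$subj <- idx[match(d$patient, d$patient[key])]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tox_table
#' @export
write_eff_table <- function(data, path) {
  d <- as_eff_data(data)
  utils::write.csv(data.frame(subID = d$patient, dose = d$dose,
                              Efficacy = d$efficacy),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The nine-record worked-example trial table
#'
#' Two cohorts of three patients: cohort 1 at dose 1 observed for two
#' cycles (one patient with a cycle-2 DLT), cohort 2 at dose 2 observed
#' for one cycle (one DLT).  Used throughout the documentation and tests
#' as the running dose-recommendation example.
#'
#' @return A data frame with columns \code{uniqueID}, \code{cohort},
#'   \code{subj}, \code{dose}, \code{cycle}, \code{nTTP}, \code{DLT}.
#' @export
example_trial_data <- function() {
  data.frame(
    uniqueID = c(paste0("cohort1subj", 1:3), paste0("cohort1subj", 1:3),
                 paste0("cohort2subj", 1:3)),
    cohort = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L),
    subj = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L),
    dose = c(1, 1, 1, 1, 1, 1, 2, 2, 2),
    cycle = c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L),
    nTTP = c(0.2, 0, 0, 0.2, 0, 0.2, 0.3, 0.2, 0.2),
    DLT = c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L))
}

wm_to_config <- function(wm) {
  list(weight_matrix = list(
    toxmax = wm$toxmax,
    types = lapply(seq_along(wm$type_names), function(l) list(
      name = wm$type_names[l],
      weights = as.numeric(wm$weights[l, ]),
      dlt_min_grade = if (is.na(wm$dlt_min_grade[l])) "none"
                      else wm$dlt_min_grade[l]))))
}

wm_from_config <- function(block) {
  types <- block$types
  weight_matrix(
    weights = do.call(rbind, lapply(types, function(t)
      as.numeric(t$weights))),
    type_names = vapply(types, function(t) as.character(t$name),
                        character(1L)),
    toxmax = as.numeric(block$toxmax),
    dlt_min_grade = vapply(types, function(t) {
      g <- t$dlt_min_grade
      if (is.null(g) || identical(g, "none")) NA_integer_
      else as.integer(g)
    }, integer(1L)))
}

#' Read a run configuration from YAML
#'
#' Recognized top-level blocks: \code{weight_matrix} (types with 5
#' weights and a per-type DLT grade, plus \code{toxmax}),
#' \code{po_model} (\code{intercepts}, \code{dose_coefs},
#' \code{cycle_coef}), \code{efficacy} (\code{mean_eff}, \code{sd_eff}),
#' \code{design} (the [design_config()] / [dual_design_config()] fields),
#' and \code{mcmc} (\code{iter}, \code{burnin}, \code{thin},
#' \code{chains}).  Absent blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A list with elements \code{wm}, \code{po_spec},
#'   \code{eff_scen}, \code{design}, \code{mcmc} (those present).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$weight_matrix))
    out$wm <- wm_from_config(cfg$weight_matrix)
  if (!is.null(cfg$po_model))
    out$po_spec <- po_model_spec(
      as.numeric(cfg$po_model$intercepts),
      as.numeric(cfg$po_model$dose_coefs),
      as.numeric(cfg$po_model$cycle_coef %||% 0))
  if (!is.null(cfg$efficacy))
    out$eff_scen <- eff_scenario(as.numeric(cfg$efficacy$mean_eff),
                                 as.numeric(cfg$efficacy$sd_eff %||% 0.2))
  if (!is.null(cfg$design)) {
    d <- cfg$design
    base <- list(doses = seq_len(d$n_dose %||% 6),
                 trial_size = d$trial_size %||% 36,
                 cohort_size = d$cohort_size %||% 3,
                 max_cycle = d$max_cycle %||% 5,
                 start_dose = d$start_dose %||% 1,
                 tox_target = d$tox_target %||% 0.28)
    dual_keys <- intersect(c("c1", "c2", "p1", "p2", "ps1", "delta",
                             "stage1_fraction"), names(d))
    out$design <- if (length(dual_keys))
      do.call(dual_design_config, c(base, d[dual_keys]))
    else do.call(design_config, base)
  }
  if (!is.null(cfg$mcmc)) out$mcmc <- cfg$mcmc
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize a named fixture on disk
#'
#' Reconstructs one of the package's worked-example inputs, byte-stable
#' for a given seed:
#' \describe{
#'   \item{\code{"patdata"}}{the nine-record example trial table (CSV).}
#'   \item{\code{"weights"}}{the default three-type weight matrix, DLT
#'     rule and normalization constant (YAML).}
#'   \item{\code{"po_scenario_tox"}}{the proportional-odds scenario used
#'     by the toxicity-only simulator examples (YAML).}
#'   \item{\code{"po_scenario_dual"}}{the flatter dual-endpoint scenario
#'     with flat mean efficacy 0.5 and its design block (YAML).}
#'   \item{\code{"synthetic-lmm"}}{a seeded synthetic longitudinal
#'     toxicity table drawn from the linear mixed model (CSV); synthetic
#'     data, not an in-trial dataset.}
#' }
#'
#' @param name fixture name.
#' @param dir output directory.
#' @param seed integer seed (used by the synthetic fixtures).
#' @return The written file path, invisibly.
#' @export
make_fixture <- function(name, dir = ".", seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- switch(
    name,
    "patdata" = {
      p <- file.path(dir, "patdata.csv")
      utils::write.csv(example_trial_data(), p, row.names = FALSE,
                       quote = FALSE)
      p
    },
    "weights" = {
      p <- file.path(dir, "weights.yaml")
      yaml::write_yaml(wm_to_config(default_weight_matrix()), p)
      p
    },
    "po_scenario_tox" = {
      p <- file.path(dir, "po_scenario_tox.yaml")
      yaml::write_yaml(c(
        list(po_model = list(intercepts = c(2, 3, 4.2, 5.7),
                             dose_coefs = c(-0.2, -0.4, -0.7),
                             cycle_coef = 0),
             design = list(n_dose = 6L, trial_size = 36L,
                           cohort_size = 3L, max_cycle = 5L,
                           start_dose = 1L, tox_target = 0.28)),
        wm_to_config(default_weight_matrix())), p)
      p
    },
    "po_scenario_dual" = {
      p <- file.path(dir, "po_scenario_dual.yaml")
      yaml::write_yaml(c(
        list(po_model = list(intercepts = c(1.9, 2.3, 2.6, 3.1),
                             dose_coefs = c(-0.3, -0.2, -0.25),
                             cycle_coef = 0),
             efficacy = list(mean_eff = rep(0.5, 6), sd_eff = 0.2),
             design = list(n_dose = 6L, trial_size = 36L,
                           cohort_size = 3L, max_cycle = 6L,
                           start_dose = 1L, tox_target = 0.23,
                           c1 = 0.23, c2 = 0.23, p1 = 0.1, p2 = 0.1,
                           ps1 = 0.1, delta = 0.1)),
        wm_to_config(default_weight_matrix())), p)
      p
    },
    "synthetic-lmm" = {
      p <- file.path(dir, "synthetic_lmm.csv")
      d <- simulate_lmm_data(n_patients = 30, n_cycles = 3, seed = seed)
      write_tox_table(d, p)
      p
    },
    stop("unknown fixture name: ", name, call. = FALSE))
  invisible(path)
}

#' Draw a synthetic longitudinal toxicity dataset from the mixed model
#'
#' Generates balanced patient-cycle nTTP data directly from the
#' random-intercept linear mixed model with known parameters -- the
#' parameter-recovery workhorse of the test suite.  Doses rotate over the
#' available levels; values are truncated to [0, 1] only if
#' \code{clamp = TRUE} (off by default so that recovery checks see the
#' exact Gaussian model).
#'
#' @param n_patients,n_cycles data dimensions.
#' @param beta fixed effects (intercept, dose, cycle).
#' @param sigma_eps,sigma_gamma error and random-intercept SDs.
#' @param doses dose levels to rotate through.
#' @param cycle_coding \code{"index"} or \code{"binary"} cycle covariate.
#' @param clamp clamp responses into [0, 1].
#' @param seed integer seed.
#' @return Toxicity table in canonical layout.
#' @export
simulate_lmm_data <- function(n_patients = 30, n_cycles = 3,
                              beta = c(0.05, 0.05, 0.01),
                              sigma_eps = 0.1, sigma_gamma = 0.05,
                              doses = 1:6,
                              cycle_coding = c("index", "binary"),
                              clamp = FALSE, seed = NULL) {
  cycle_coding <- match.arg(cycle_coding)
  if (!is.null(seed)) set.seed(seed)
  dose_i <- rep(doses, length.out = n_patients)
  gam <- stats::rnorm(n_patients, 0, sigma_gamma)
  d <- expand.grid(subj = seq_len(n_patients), cycle = seq_len(n_cycles))
  d <- d[order(d$subj, d$cycle), ]
  tc <- cycle_code(d$cycle, cycle_coding)
  mu <- beta[1L] + beta[2L] * dose_i[d$subj] + beta[3L] * tc + gam[d$subj]
  y <- mu + stats::rnorm(nrow(d), 0, sigma_eps)
  if (clamp) y <- pmin(pmax(y, 0), 1)
  data.frame(uniqueID = sprintf("subj%03d", d$subj),
             cohort = NA_integer_,
             dose = dose_i[d$subj], cycle = d$cycle,
             nTTP = y, DLT = 0L)
}

#' Draw a synthetic dataset from the joint toxicity-efficacy model
#'
#' Generates paired longitudinal toxicity and one-per-patient efficacy
#' data from the shared-random-intercept joint model with known
#' parameters, for parameter-recovery checks.
#'
#' @inheritParams simulate_lmm_data
#' @param alpha efficacy fixed effects (intercept, dose, dose squared).
#' @param nu shared random-effect loading linking the two submodels.
#' @param sigma_e efficacy error SD.
#' @return A list with elements \code{tox} (toxicity table) and
#'   \code{eff} (efficacy table).
#' @export
simulate_joint_data <- function(n_patients = 120, n_cycles = 3,
                                beta = c(0.05, 0.05, 0.01),
                                alpha = c(0.1, 0.15, -0.015), nu = 0.5,
                                sigma_eps = 0.1, sigma_gamma = 0.05,
                                sigma_e = 0.05, doses = 1:6,
                                cycle_coding = c("binary", "index"),
                                seed = NULL) {
  cycle_coding <- match.arg(cycle_coding)
  if (!is.null(seed)) set.seed(seed)
  dose_i <- rep(doses, length.out = n_patients)
  gam <- stats::rnorm(n_patients, 0, sigma_gamma)
  d <- expand.grid(subj = seq_len(n_patients), cycle = seq_len(n_cycles))
  d <- d[order(d$subj, d$cycle), ]
  tc <- cycle_code(d$cycle, cycle_coding)
  y <- beta[1L] + beta[2L] * dose_i[d$subj] + beta[3L] * tc +
    gam[d$subj] + stats::rnorm(nrow(d), 0, sigma_eps)
  eff <- alpha[1L] + alpha[2L] * dose_i + alpha[3L] * dose_i^2 +
    nu * gam + stats::rnorm(n_patients, 0, sigma_e)
  list(tox = data.frame(uniqueID = sprintf("subj%03d", d$subj),
                        cohort = NA_integer_, dose = dose_i[d$subj],
                        cycle = d$cycle, nTTP = y, DLT = 0L),
       eff = data.frame(subID = sprintf("subj%03d", seq_len(n_patients)),
                        dose = dose_i,
                        Efficacy = pmin(pmax(eff, 1e-4), 1 - 1e-4)))
}
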