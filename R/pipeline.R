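#' Study configuration
#'
#' Bundles every setting of the end-to-end synthetic study: phantom
#' geometry, montages, conductivities, ROI radius, cohort generator
#' parameters, statistical settings (family-wise alpha and the two
#' Bonferroni families: 16 group-comparison tests and 12 mediation
#' analyses), and mediation bootstrap size.
#'
#' @param n_control,n_psychosis,n_relative cohort sizes (relatives are
#'   optional and excluded from mediation, mirroring the analysis design).
#' @param cohort generator parameters, see [cohort_params()].
#' @param layers phantom [layer_spec()].
#' @param montages named list of [montage()]s.
#' @param cond conductivities, S/m.
#' @param roi_radius ROI radius, mm (10 default; 20 is the common
#'   robustness variant).
#' @param mode `"surrogate"` (calibrated thickness-to-field spline) or
#'   `"fem"` (one solve per subject and montage; small cohorts only).
#' @param surrogate optional pre-calibrated `field_surrogate`; when `NULL`
#'   and `mode = "surrogate"`, one is calibrated during the run.
#' @param surrogate_scalp_range,surrogate_points calibration ladder.
#' @param alpha family-wise significance level.
#' @param m_regressions,m_mediations Bonferroni family sizes.
#' @param n_boot mediation bootstrap replicates.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_control = 150, n_psychosis = 150,
                         n_relative = 0,
                         cohort = cohort_params(),
                         layers = layer_spec(),
                         montages = list(fp1fp2 = standard_montage("fp1fp2"),
                                         f3fp2 = standard_montage("f3fp2")),
                         cond = conductivity_defaults(),
                         roi_radius = 10,
                         mode = c("surrogate", "fem"),
                         surrogate = NULL,
                         surrogate_scalp_range = c(4, 10),
                         surrogate_points = 6L,
                         alpha = 0.05, m_regressions = 16L,
                         m_mediations = 12L, n_boot = 1000L) {
  structure(list(
    n_control = n_control, n_psychosis = n_psychosis,
    n_relative = n_relative, cohort = cohort, layers = layers,
    montages = montages, cond = cond, roi_radius = roi_radius,
    mode = match.arg(mode), surrogate = surrogate,
    surrogate_scalp_range = surrogate_scalp_range,
    surrogate_points = surrogate_points,
    alpha = alpha, m_regressions = m_regressions,
    m_mediations = m_mediations, n_boot = n_boot),
    class = "study_config")
}

#' Run the end-to-end synthetic study
#'
#' Executes the full chain: cohort generation, anatomy and field outcomes,
#' covariate-adjusted group regressions for the field, scalp-to-cortex
#' and individual-layer outcomes (Bonferroni family of
#' `m_regressions` tests), and mediation analyses of BMI, scalp-to-cortex
#' and scalp thickness on the four field outcomes (family of
#' `m_mediations`), each with bootstrap intervals. All stage seeds are
#' derived deterministically from `seed` and echoed in the report, so a
#' run is reproducible from the configuration plus one integer.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @return object of class `study_report`: list with `cohort` (outcomes
#'   attached), `demographics`, `regressions`, `mediations`,
#'   `group_means`, `seeds`, `log`, and the `config`.
#' @export
run_study <- function(config = study_config(), seed = 1L) {
  stopifnot(inherits(config, "study_config"))
  seeds <- list(cohort = seed, outcomes = seed + 10000L,
                mediation = seed + 20000L)
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0)
    log[[name]] <<- list(stage = name, seconds = round(tic() - t0, 3))
  t0 <- tic()
  surro <- config$surrogate
  if (config$mode == "surrogate" && is.null(surro)) {
    surro <- calibrate_field_surrogate(
      layers = config$layers, montages = config$montages,
      cond = config$cond, scalp_range = config$surrogate_scalp_range,
      n_points = config$surrogate_points, roi_radius = config$roi_radius)
    stage("calibrate_surrogate", t0)
  }
  t0 <- tic()
  cohort <- simulate_cohort(config$n_control, config$n_psychosis,
                            config$n_relative, config$cohort,
                            seed = seeds$cohort)
  stage("simulate_cohort", t0)
  t0 <- tic()
  cohort <- cohort_to_outcomes(cohort, mode = config$mode,
                               surrogate = surro, layers = config$layers,
                               montages = config$montages,
                               cond = config$cond,
                               roi_radius = config$roi_radius,
                               seed = seeds$outcomes)
  stage("outcomes", t0)
  t0 <- tic()
  demo <- demographic_tests(cohort)
  field_cols <- as.vector(outer(paste0("E_", names(config$montages)),
                                c("left", "right"), paste, sep = "_"))
  thick_cols <- c("scalp_to_cortex_mm", "scalp_mm", "skull_mm", "CSF_mm")
  contrasts <- list(c("control", "psychosis"))
  if (config$n_relative > 0)
    contrasts <- c(contrasts, list(c("control", "relative")))
  a_reg <- bonferroni_alpha(config$alpha, config$m_regressions)$alpha
  reg_rows <- list()
  for (gp in contrasts) for (oc in c(field_cols, thick_cols)) {
    r <- fit_group_model(cohort, oc, groups = gp)
    reg_rows[[length(reg_rows) + 1L]] <- data.frame(
      contrast = paste(gp, collapse = "_vs_"), outcome = oc,
      estimate = r$estimate, se = r$se, t = r$t, p = r$p, f2 = r$f2,
      n = r$n, alpha_corrected = a_reg, significant = r$p < a_reg)
  }
  regressions <- do.call(rbind, reg_rows)
  stage("regressions", t0)
  t0 <- tic()
  a_med <- bonferroni_alpha(config$alpha, config$m_mediations)$alpha
  med_rows <- list()
  k <- 0L
  for (md in c("BMI", "scalp_to_cortex_mm", "scalp_mm"))
    for (oc in field_cols) {
      k <- k + 1L
      mr <- mediate(cohort, outcome = oc, mediator = md,
                    n_boot = config$n_boot, seed = seeds$mediation + k)
      med_rows[[k]] <- data.frame(
        mediator = md, outcome = oc,
        acme = mr$estimates[["acme"]], acme_lo = mr$ci["acme", 1L],
        acme_hi = mr$ci["acme", 2L], acme_p = mr$p[["acme"]],
        ade = mr$estimates[["ade"]], ade_lo = mr$ci["ade", 1L],
        ade_hi = mr$ci["ade", 2L], ade_p = mr$p[["ade"]],
        total = mr$estimates[["total"]], total_p = mr$p[["total"]],
        prop_mediated = as.numeric(mr$prop_mediated),
        alpha_corrected = a_med,
        classification = classify_mediation(mr, a_med))
    }
  mediations <- do.call(rbind, med_rows)
  stage("mediations", t0)
  gm <- stats::aggregate(
    cohort[, c("BMI", "scalp_mm", "scalp_to_cortex_mm", field_cols)],
    by = list(group = cohort$group), FUN = mean)
  structure(list(cohort = cohort, demographics = demo,
                 regressions = regressions, mediations = mediations,
                 group_means = gm, seeds = seeds, log = log,
                 surrogate = surro, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$cohort), "subjects;",
      nrow(x$regressions), "regressions;", nrow(x$mediations),
      "mediation analyses\n\ngroup means:\n")
  print(x$group_means, digits = 3)
  cat("\nregressions (control vs psychosis):\n")
  print(x$regressions[x$regressions$contrast == "control_vs_psychosis",
                      c("outcome", "estimate", "t", "p", "f2",
                        "significant")],
        digits = 3, row.names = FALSE)
  cat("\nmediations:\n")
  print(x$mediations[, c("mediator", "outcome", "acme", "acme_p", "ade",
                         "ade_p", "prop_mediated", "classification")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Emits `cohort.csv`, `demographics.csv`, `regressions.csv`,
#' `mediations.csv`, `group_means.csv` and a JSON echo of seeds, stage
#' log and configuration scalars sufficient to re-run the study.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(report$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$regressions, file.path(dir, "regressions.csv"),
                   row.names = FALSE)
  utils::write.csv(report$mediations, file.path(dir, "mediations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_means, file.path(dir, "group_means.csv"),
                   row.names = FALSE)
  cfg <- report$config
  jsonlite::write_json(list(
    seeds = report$seeds,
    log = report$log,
    config = list(
      n_control = cfg$n_control, n_psychosis = cfg$n_psychosis,
      n_relative = cfg$n_relative, mode = cfg$mode,
      roi_radius = cfg$roi_radius, alpha = cfg$alpha,
      m_regressions = cfg$m_regressions, m_mediations = cfg$m_mediations,
      n_boot = cfg$n_boot,
      layers = as.list(cfg$layers$radii),
      edge_length = cfg$layers$edge_length,
      conductivities = as.list(cfg$cond),
      cohort = cfg$cohort)),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
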