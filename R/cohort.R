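# truncated-normal draws by inverse-CDF
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (!is.finite(sd) || sd <= 0) stop("parameter error: sd must be > 0")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi <= plo) stop("parameter error: empty truncation interval")
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Cohort generation parameters
#'
#' Default parameters of the synthetic cohort generator. Group BMI and age
#' moments and male fractions follow the study demographics (healthy
#' controls: BMI 25.5 (5.5), age 38.2 (13.1), 48% male; psychosis: 31.4
#' (7.4), 38.8 (12.3), 56.6%; first-degree relatives: 29.1 (6.6), 44.6
#' (13.8), 31.5%). BMI is truncated to [10, 70] kg/m^2 and age to [18, 90]
#' years. The BMI to scalp-thickness link and downstream field noise
#' define the causal chain (group -> BMI -> scalp thickness -> field) the
#' analysis pipeline is meant to recover.
#'
#' @param null if `TRUE`, all groups share the control BMI/age/sex
#'   distributions and the BMI to thickness slope is zero (no group effect
#'   anywhere downstream).
#' @return a list of generator settings.
#' @export
cohort_params <- function(null = FALSE) {
  p <- list(
    bmi = list(control = c(mean = 25.5, sd = 5.5),
               psychosis = c(mean = 31.4, sd = 7.4),
               relative = c(mean = 29.1, sd = 6.6)),
    bmi_range = c(10, 70),
    age = list(control = c(mean = 38.2, sd = 13.1),
               psychosis = c(mean = 38.8, sd = 12.3),
               relative = c(mean = 44.6, sd = 13.8)),
    age_range = c(18, 90),
    male_fraction = c(control = 0.48, psychosis = 0.566, relative = 0.315),
    medication = list(enabled = FALSE, prevalence = 0.67,
                      bmi_medicated = c(mean = 31.6, sd = 6.3),
                      bmi_unmedicated = c(mean = 28.0, sd = 7.0)),
    thickness_link = list(slope = 0.15, intercept = 2.5, noise_sd = 0.5,
                          floor_mm = 2),
    other_layers = list(skull = c(mean = 6, sd = 0.5, lo = 3),
                        CSF = c(mean = 2, sd = 0.3, lo = 0.5),
                        cortex = c(mean = 3, sd = 0.3, lo = 1)),
    field_noise_sd = 0.06)
  if (null) {
    p$bmi$psychosis <- p$bmi$relative <- p$bmi$control
    p$age$psychosis <- p$age$relative <- p$age$control
    p$male_fraction[] <- p$male_fraction[["control"]]
    p$thickness_link$slope <- 0
  }
  p
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject group, age, sex and BMI from the group distributions
#' in [cohort_params()] (truncated normals for the continuous variables).
#' When the medication sub-model is enabled, psychosis-group BMI is drawn
#' from a medicated/unmedicated mixture instead of the single group
#' distribution, so the flag raises the within-group BMI mean.
#'
#' @param n_control,n_psychosis,n_relative group sizes (the study's own
#'   sizes, 43/136/73, are the defaults).
#' @param params generator parameters, see [cohort_params()].
#' @param seed integer seed; recorded in the result.
#' @return a `cohort_table`: a data.frame with columns `subject`, `group`,
#'   `age`, `sex`, `BMI`, `medication`, carrying `params` and `seed` as
#'   attributes.
#' @export
simulate_cohort <- function(n_control = 43, n_psychosis = 136,
                            n_relative = 73, params = cohort_params(),
                            seed = 1L) {
  ns <- c(control = n_control, psychosis = n_psychosis,
          relative = n_relative)
  if (any(ns < 0) || any(ns != round(ns))) stop("group sizes must be >= 0")
  set.seed(seed)
  rows <- lapply(names(ns), function(g) {
    n <- ns[[g]]
    if (n == 0) return(NULL)
    age <- rtrunc_norm(n, params$age[[g]]["mean"], params$age[[g]]["sd"],
                       params$age_range[1], params$age_range[2])
    sex <- ifelse(stats::runif(n) < params$male_fraction[[g]],
                  "male", "female")
    med <- rep(NA, n)
    if (g == "psychosis" && isTRUE(params$medication$enabled)) {
      med <- stats::runif(n) < params$medication$prevalence
      bm <- ifelse(med, params$medication$bmi_medicated["mean"],
                   params$medication$bmi_unmedicated["mean"])
      bs <- ifelse(med, params$medication$bmi_medicated["sd"],
                   params$medication$bmi_unmedicated["sd"])
      bmi <- stats::qnorm(
        stats::pnorm(params$bmi_range[1], bm, bs) +
          stats::runif(n) * (stats::pnorm(params$bmi_range[2], bm, bs) -
                               stats::pnorm(params$bmi_range[1], bm, bs)),
        bm, bs)
    } else {
      bmi <- rtrunc_norm(n, params$bmi[[g]]["mean"], params$bmi[[g]]["sd"],
                         params$bmi_range[1], params$bmi_range[2])
    }
    data.frame(group = g, age = age, sex = sex, BMI = bmi,
               medication = med, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject = sprintf("S%04d", seq_len(nrow(out))), out)
  out$group <- factor(out$group,
                      levels = c("control", "psychosis", "relative"))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Calibrate the thickness-to-field surrogate
#'
#' Runs the full FEM chain over a ladder of scalp thicknesses for each
#' montage ([attenuation_ladder()]) and fits a monotone Hermite spline of
#' ROI field strength against scalp-to-cortex thickness per montage and
#' hemisphere. The surrogate lets cohort-scale studies map each subject's
#' thickness to a field value without one FEM solve per subject; its
#' monotone-decreasing shape is inherited from the calibration data.
#'
#' @param layers base [layer_spec()] (inner radii are held fixed).
#' @param montages named list of [montage()]s.
#' @param cond conductivities, S/m.
#' @param scalp_range range of scalp thicknesses to calibrate over, mm.
#' @param n_points number of ladder points (>= 5).
#' @param roi_radius ROI radius, mm.
#' @return object of class `field_surrogate`.
#' @export
calibrate_field_surrogate <- function(layers = layer_spec(),
                                      montages = list(
                                        fp1fp2 = standard_montage("fp1fp2"),
                                        f3fp2 = standard_montage("f3fp2")),
                                      cond = conductivity_defaults(),
                                      scalp_range = c(4, 10),
                                      n_points = 6L, roi_radius = 10) {
  if (n_points < 5L) stop("calibration error: need at least 5 ladder points")
  th <- seq(scalp_range[1], scalp_range[2], length.out = n_points)
  tabs <- lapply(names(montages), function(nm) {
    lad <- attenuation_ladder(th, layers, montages[[nm]], cond, roi_radius)
    lad$montage <- nm
    lad
  })
  tab <- do.call(rbind, tabs)
  funs <- list()
  for (nm in names(montages)) {
    sub <- tab[tab$montage == nm, ]
    for (side in c("left", "right")) {
      E <- sub[[paste0("E_", side)]]
      if (any(diff(E) >= 0))
        warning("surrogate calibration for ", nm, "/", side,
                " is not strictly decreasing in thickness")
      funs[[paste(nm, side, sep = ".")]] <-
        stats::splinefun(sub$scalp_to_cortex_mm, E, method = "hyman")
    }
  }
  structure(list(table = tab, funs = funs,
                 s2c_range = range(tab$scalp_to_cortex_mm)),
            class = "field_surrogate")
}

#' @rdname calibrate_field_surrogate
#' @param surrogate a calibrated `field_surrogate`.
#' @param montage_name,side montage and hemisphere of the wanted curve.
#' @param s2c scalp-to-cortex thicknesses, mm (clamped to the calibrated
#'   range).
#' @return `predict_surrogate()`: noiseless field values, V/m.
#' @export
predict_surrogate <- function(surrogate, montage_name, side, s2c) {
  if (!inherits(surrogate, "field_surrogate"))
    stop("calibration error: surrogate has not been calibrated")
  f <- surrogate$funs[[paste(montage_name, side, sep = ".")]]
  if (is.null(f))
    stop("surrogate has no curve for ", montage_name, "/", side)
  f(pmin(pmax(s2c, surrogate$s2c_range[1]), surrogate$s2c_range[2]))
}

#' Attach anatomy and field outcomes to a cohort
#'
#' Realizes the causal chain: per-subject scalp thickness from the BMI
#' link, group-independent skull/CSF/cortex thicknesses, and ROI field
#' strengths per montage and hemisphere, either through one FEM solve per
#' subject and montage (`mode = "fem"`, feasible for small cohorts only)
#' or through the calibrated monotone surrogate (`mode = "surrogate"`).
#' Field values receive multiplicative log-normal noise
#' (`field_noise_sd` on the log scale); fields are positive so the noise
#' model is multiplicative by construction.
#'
#' @param table a `cohort_table`.
#' @param mode `"surrogate"` or `"fem"`.
#' @param surrogate a `field_surrogate` (required for surrogate mode).
#' @param layers base [layer_spec()] for per-subject phantoms (fem mode).
#' @param montages named list of [montage()]s.
#' @param cond conductivities.
#' @param roi_radius ROI radius in mm.
#' @param seed integer seed for the outcome noise.
#' @return the cohort with added columns `scalp_mm`, `skull_mm`, `CSF_mm`,
#'   `cortex_mm`, `scalp_to_cortex_mm`, and `E_<montage>_<side>` (V/m).
#' @export
cohort_to_outcomes <- function(table, mode = c("surrogate", "fem"),
                               surrogate = NULL, layers = layer_spec(),
                               montages = list(
                                 fp1fp2 = standard_montage("fp1fp2"),
                                 f3fp2 = standard_montage("f3fp2")),
                               cond = conductivity_defaults(),
                               roi_radius = 10, seed = 1L) {
  mode <- match.arg(mode)
  params <- attr(table, "params")
  if (is.null(params)) params <- cohort_params()
  if (mode == "surrogate" && !inherits(surrogate, "field_surrogate"))
    stop("calibration error: surrogate mode needs a calibrated ",
         "field_surrogate (see calibrate_field_surrogate)")
  set.seed(seed)
  n <- nrow(table)
  tl <- params$thickness_link
  table$scalp_mm <- scalp_thickness_from_bmi(
    table$BMI, slope = tl$slope, intercept = tl$intercept,
    noise_sd = tl$noise_sd, floor_mm = tl$floor_mm)
  for (nm in c("skull", "CSF", "cortex")) {
    o <- params$other_layers[[nm]]
    table[[paste0(nm, "_mm")]] <- if (o[["sd"]] > 0)
      rtrunc_norm(n, o[["mean"]], o[["sd"]], lo = o[["lo"]]) else
        rep(o[["mean"]], n)
  }
  table$scalp_to_cortex_mm <- table$scalp_mm + table$skull_mm + table$CSF_mm
  # one noise column per montage x side, drawn in a fixed order so the two
  # modes see identical noise for the same seed
  cols <- as.vector(t(outer(names(montages), c("left", "right"),
                            paste, sep = "_")))
  noise_mat <- matrix(1, n, length(cols), dimnames = list(NULL, cols))
  if (params$field_noise_sd > 0)
    noise_mat[] <- exp(stats::rnorm(n * length(cols), 0,
                                    params$field_noise_sd))
  if (mode == "surrogate") {
    for (nm in names(montages)) for (side in c("left", "right"))
      table[[paste0("E_", nm, "_", side)]] <-
        predict_surrogate(surrogate, nm, side, table$scalp_to_cortex_mm) *
        noise_mat[, paste(nm, side, sep = "_")]
  } else {
    r <- layers$radii
    base <- matrix(NA_real_, n, 2L * length(montages))
    colnames(base) <- as.vector(outer(names(montages), c("left", "right"),
                                      paste, sep = "_"))
    for (i in seq_len(n)) {
      wm <- r[["white_matter"]]
      gm <- wm + table$cortex_mm[i]
      cs <- gm + table$CSF_mm[i]
      sk <- cs + table$skull_mm[i]
      sc <- sk + table$scalp_mm[i]
      ls_i <- suppressWarnings(layer_spec(
        scalp = sc, skull = sk, CSF = cs, gray_matter = gm,
        white_matter = wm, edge_length = layers$edge_length))
      ph <- build_layered_sphere(ls_i)
      for (nm in names(montages)) {
        sim <- simulate_montage(ph, montages[[nm]], cond,
                                rois = dlpfc_targets(ls_i, roi_radius))
        base[i, paste0(nm, "_left")] <- sim$roi_mean["left"]
        base[i, paste0(nm, "_right")] <- sim$roi_mean["right"]
      }
    }
    for (cn in cols)
      table[[paste0("E_", cn)]] <- base[, cn] * noise_mat[, cn]
  }
  attr(table, "outcome_seed") <- seed
  attr(table, "outcome_mode") <- mode
  table
}
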