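# End-to-end drivers: feature extraction from a volume, and the prognostic
# modelling pipeline on a cohort table.

#' Extract vascularization features from a series or NIfTI file
#'
#' Runs segmentation, heterogeneity and most-suspect-compartment analysis
#' end-to-end. When \code{output_dir} is given, writes the 14 features as
#' JSON and the category label map as a 3D NIfTI (codes 0 = excluded,
#' 1..9 = A..I); reruns with the same input and config produce byte-identical
#' JSON. Voxel counts per category are reported via \code{message()}.
#'
#' @param input a \code{\link{dynamic_series}} or a path to a 4D NIfTI file.
#' @param voi optional VOI when \code{input} is a path.
#' @param config a \code{\link{run_config}}.
#' @param output_dir optional output directory.
#' @param prefix file name prefix for outputs.
#' @return A list with \code{features} (\code{vav_features}) and
#'   \code{label_map} (3D integer array).
#' @export
vav_extract <- function(input, voi = NULL, config = run_config(),
                        output_dir = NULL, prefix = "vav") {
  series <- if (inherits(input, "dynamic_series")) {
    input
  } else {
    read_dynamic_series(input, voi = voi)
  }
  kc <- config$kinetics
  features <- extract_vav_features(series, kc)
  labels <- pattern_label_map(series, kc)
  counts <- tabulate(labels[labels > 0], nbins = 9L)
  message("enhancing voxels per category: ",
          paste(sprintf("%s=%d", pattern_categories(), counts), collapse = " "),
          " (", attr(features, "n_invalid"), " zero-baseline voxels excluded)")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_vav_features_json(features,
                            file.path(output_dir, paste0(prefix, "_features.json")))
    write_label_map(labels, file.path(output_dir, paste0(prefix, "_labels.nii.gz")),
                    series$voxel_size_mm)
  }
  list(features = features, label_map = labels)
}

#' Full prognostic modelling report for a cohort
#'
#' Mirrors the published analysis on any cohort table: univariate Cox
#' screening of the vascularization features, backward-selected Cox models
#' for the imaging features alone (VAV), the NPI alone, and the compound
#' NPI + imaging model (NPI_VAV); Harrell's C for each model's linear
#' predictor; Youden-optimal risk stratification with Kaplan-Meier, logrank
#' and hazard-ratio comparison; and a bootstrap CI on the concordance gain of
#' the compound model over NPI alone.
#'
#' @param cohort cohort data.frame (columns \code{time_months}, \code{event},
#'   \code{npi} and the vascularization features) or a CSV path.
#' @param config a \code{\link{run_config}}.
#' @param vav_features candidate imaging features; default the three
#'   published ones present in the table.
#' @param n_boot bootstrap replicates for the concordance-gain CI (0 skips).
#' @return A list of class \code{"prognostic_report"}: \code{screen},
#'   \code{model_npi}, \code{model_vav}, \code{model_npi_vav},
#'   \code{concordance} (named vector), \code{stratification} (per model),
#'   \code{delta_c} (gain, with bootstrap CI when requested), \code{seed}.
#' @export
prognostic_report <- function(cohort, config = run_config(),
                              vav_features = NULL, n_boot = 200) {
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (sum(cohort$event) < 2) {
    stop("cohort has fewer than 2 events; no survival model can be fit",
         call. = FALSE)
  }
  if (is.null(vav_features)) {
    vav_features <- intersect(c("ttv_cm3", "het_A_pct", "ttp_min"),
                              names(cohort))
  }
  scr <- univariate_screen(cohort, vav_features, alpha = config$screen_alpha)
  eligible <- scr$eligible

  fit_or_null <- function(covs) {
    if (length(covs) == 0) return(NULL)
    fit_cox_backward(cohort, covs, p_enter = config$p_enter,
                     p_remove = config$p_remove)
  }
  model_npi <- fit_cox_backward(cohort, "npi", p_enter = config$p_enter,
                                p_remove = 1)  # reference model is never emptied
  model_vav <- fit_or_null(eligible)
  model_npi_vav <- fit_cox_backward(cohort, union(eligible, "npi"),
                                    p_enter = config$p_enter,
                                    p_remove = config$p_remove)

  cindex <- function(m) {
    if (is.null(m) || length(m$covariates) == 0) return(NA_real_)
    harrells_c(m$linear_predictors, cohort$time_months, cohort$event)
  }
  conc <- c(npi = cindex(model_npi), vav = cindex(model_vav),
            npi_vav = cindex(model_npi_vav))

  strat <- list()
  for (nm in c("npi", "npi_vav")) {
    m <- if (nm == "npi") model_npi else model_npi_vav
    if (!is.null(m) && length(m$covariates) > 0) {
      strat[[nm]] <- tryCatch(
        stratify_cohort(m$linear_predictors, cohort$time_months, cohort$event,
                        horizon = config$youden_horizon),
        error = function(e) {
          warning("stratification for ", nm, " failed: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
    }
  }

  delta <- list(estimate = unname(conc["npi_vav"] - conc["npi"]))
  if (n_boot > 0 && !is.na(delta$estimate)) {
    delta_boot <- with_seed(config$seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(cohort), replace = TRUE)
        boot <- cohort[idx, , drop = FALSE]
        if (sum(boot$event) < 2) return(NA_real_)
        m1 <- tryCatch(fit_cox_backward(boot, "npi", p_remove = 1),
                       error = function(e) NULL)
        m2 <- tryCatch(fit_cox_backward(boot, union(eligible, "npi"),
                                        p_remove = 1),
                       error = function(e) NULL)
        if (is.null(m1) || is.null(m2)) return(NA_real_)
        harrells_c(m2$linear_predictors, boot$time_months, boot$event) -
          harrells_c(m1$linear_predictors, boot$time_months, boot$event)
      }, numeric(1))
    })
    delta$ci <- unname(stats::quantile(delta_boot, c(0.025, 0.975), na.rm = TRUE))
    delta$n_boot <- n_boot
  }

  message(sprintf(
    "%d subjects, %d events; screen retained: %s; C(npi)=%.3f C(npi_vav)=%.3f",
    nrow(cohort), sum(cohort$event),
    if (length(eligible)) paste(eligible, collapse = ", ") else "(none)",
    conc["npi"], conc["npi_vav"]))

  structure(
    list(screen = scr, model_npi = model_npi, model_vav = model_vav,
         model_npi_vav = model_npi_vav, concordance = conc,
         stratification = strat, delta_c = delta, seed = config$seed),
    class = "prognostic_report"
  )
}

#' Serialize a prognostic report as JSON
#' @param report a \code{\link{prognostic_report}}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(m) {
    if (is.null(m)) return(NULL)
    list(covariates = m$covariates,
         coefficients = as.list(stats::setNames(unname(m$coefficients), m$covariates)),
         se = unname(m$se), hr = unname(m$hr),
         ci_lower = unname(m$ci_lower), ci_upper = unname(m$ci_upper),
         p = unname(m$p), chi_squared = m$chi_squared)
  }
  strip_strat <- function(s) {
    if (is.null(s)) return(NULL)
    list(cutoff = s$cutoff, J = s$J, logrank_p = s$logrank_p,
         hr = s$hr, ci_lower = s$ci_lower, ci_upper = s$ci_upper,
         group_sizes = as.list(s$group_sizes))
  }
  out <- list(screen = report$screen$table,
              eligible = report$screen$eligible,
              models = list(npi = strip(report$model_npi),
                            vav = strip(report$model_vav),
                            npi_vav = strip(report$model_npi_vav)),
              concordance = as.list(report$concordance),
              stratification = lapply(report$stratification, strip_strat),
              delta_c = report$delta_c,
              seed = report$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cohort characteristic counts bundled with the package
#'
#' Loads the bundled table of tumor-characteristic counts (T stage,
#' histological subtype, grade) stratified by outcome group (disease-specific
#' survival vs death) and recomputes each percentage from the counts.
#'
#' @return data.frame with \code{category}, \code{level}, \code{dss},
#'   \code{dsd}, \code{total} counts and the derived \code{pct_dss},
#'   \code{pct_dsd}, \code{pct_total} (one-decimal percentages).
#' @export
load_cohort_characteristics <- function() {
  path <- system.file("extdata", "cohort_characteristics.csv",
                      package = "vavmri", mustWork = TRUE)
  tab <- utils::read.csv(path)
  n_dss <- sum(tab$dss[tab$category == "grade"])
  n_dsd <- sum(tab$dsd[tab$category == "grade"])
  tab$total <- tab$dss + tab$dsd
  tab$pct_dss <- proportion_pct(tab$dss, n_dss)
  tab$pct_dsd <- proportion_pct(tab$dsd, n_dsd)
  tab$pct_total <- proportion_pct(tab$total, n_dss + n_dsd)
  tab
}

#' Percentage of a count, rounded to one decimal
#' @param n numerator count(s).
#' @param d denominator.
#' @return \code{round(100 n / d, 1)}.
#' @export
proportion_pct <- function(n, d) round(100 * n / d, 1)
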