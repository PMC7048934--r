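# File formats: NIfTI for volumes, CSV for tables, JSON for derived results,
# YAML for run configuration. One format per role.

#' Run configuration
#'
#' Bundles every tunable of the pipeline: kinetic thresholds and cluster
#' settings, selection P-values, screening alpha, Youden mode and the seed.
#' Round-trips losslessly through YAML.
#'
#' @param kinetics a \code{\link{kinetic_config}}.
#' @param screen_alpha univariate screening threshold (default 0.007).
#' @param p_enter,p_remove backward-selection thresholds (defaults 0.001 and
#'   0.05).
#' @param youden_horizon \code{NULL} (Youden on observed event indicators;
#'   default) or a fixed horizon in months.
#' @param seed integer seed governing all randomness.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(kinetics = kinetic_config(),
                       screen_alpha = 0.007,
                       p_enter = 0.001,
                       p_remove = 0.05,
                       youden_horizon = NULL,
                       seed = 1L) {
  structure(
    list(kinetics = kinetics, screen_alpha = screen_alpha,
         p_enter = p_enter, p_remove = p_remove,
         youden_horizon = youden_horizon, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#' @param config a \code{\link{run_config}}.
#' @param path file path.
#' @return \code{read_run_config} returns the reconstructed
#'   \code{\link{run_config}}; the writer returns \code{path} invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$kinetics <- unclass(x$kinetics)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  kc <- do.call(kinetic_config, x$kinetics)
  run_config(kinetics = kc, screen_alpha = x$screen_alpha,
             p_enter = x$p_enter, p_remove = x$p_remove,
             youden_horizon = x$youden_horizon, seed = x$seed)
}

# 4D internal array [t,z,y,x] <-> NIfTI [x,y,z,t]; 3D [z,y,x] <-> [x,y,z].
to_nifti_order <- function(a) {
  if (length(dim(a)) == 4L) aperm(a, c(4, 3, 2, 1)) else aperm(a, c(3, 2, 1))
}
from_nifti_order <- function(a) {
  if (length(dim(a)) == 4L) aperm(a, c(4, 3, 2, 1)) else aperm(a, c(3, 2, 1))
}

#' Write a dynamic series as a 4D NIfTI volume
#'
#' The internal \code{[t, z, y, x]} array is stored in NIfTI's
#' \code{[x, y, z, t]} axis order with the voxel size in the header (time
#' spacing 60 s).
#'
#' @param series a \code{\link{dynamic_series}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_dynamic_series <- function(series, path) {
  arr <- to_nifti_order(series$signal)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rev(series$voxel_size_mm), 60)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI volume as a dynamic series
#'
#' @param path path to a 4D NIfTI file with 8 timepoints.
#' @param voi optional VOI (half-open, 0-based index ranges per axis; see
#'   \code{\link{dynamic_series}}); default full grid.
#' @param voxel_size_mm optional override; default taken from the header.
#' @return A \code{\link{dynamic_series}}.
#' @export
read_dynamic_series <- function(path, voi = NULL, voxel_size_mm = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 8L) {
    stop("expected a 4D NIfTI with 8 timepoints, got dimensions (",
         paste(d, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(voxel_size_mm)) {
    voxel_size_mm <- rev(RNifti::pixdim(img)[1:3])
  }
  dynamic_series(from_nifti_order(array(as.numeric(img), dim = d)),
                 voxel_size_mm = voxel_size_mm, voi = voi)
}

#' Write a 3D label volume (pattern codes or ground truth) as NIfTI
#' @param labels 3D integer array \code{[z, y, x]}.
#' @param path output path.
#' @param voxel_size_mm voxel edge lengths (z, y, x).
#' @return \code{path}, invisibly.
#' @export
write_label_map <- function(labels, path, voxel_size_mm = c(3.0, 0.9, 1.1)) {
  img <- RNifti::asNifti(to_nifti_order(labels))
  RNifti::pixdim(img) <- rev(voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D label volume written by \code{\link{write_label_map}}
#' @param path NIfTI path.
#' @return 3D integer array \code{[z, y, x]}.
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  a <- from_nifti_order(array(as.integer(img), dim = dim(img)))
  a
}

#' Write a phantom to disk (dynamic series, truth labels, spec sidecar)
#'
#' Produces \code{<prefix>.nii.gz} (4D series), \code{<prefix>_labels.nii.gz}
#' (ground-truth categories) and \code{<prefix>.json} (the phantom spec and
#' realized composition).
#'
#' @param phantom result of \code{\link{make_phantom}}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p_series <- file.path(dir, paste0(prefix, ".nii.gz"))
  p_labels <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
  p_json <- file.path(dir, paste0(prefix, ".json"))
  write_dynamic_series(phantom$series, p_series)
  write_label_map(phantom$truth$labels, p_labels,
                  phantom$series$voxel_size_mm)
  spec <- phantom$truth$spec
  sidecar <- list(
    spec = list(grid_shape = spec$grid_shape,
                voxel_size_mm = spec$voxel_size_mm,
                tumor_extent = spec$tumor_extent,
                pattern_mix = as.list(spec$pattern_mix),
                necrotic_fraction = spec$necrotic_fraction,
                baseline_signal = spec$baseline_signal,
                noise_sd = spec$noise_sd,
                seed = spec$seed),
    truth = list(counts = as.list(phantom$truth$counts),
                 fractions = as.list(phantom$truth$fractions),
                 n_tumor = phantom$truth$n_tumor,
                 n_necrotic = phantom$truth$n_necrotic),
    voi = phantom$series$voi
  )
  jsonlite::write_json(sidecar, p_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(series = p_series, labels = p_labels, sidecar = p_json))
}

#' Write / read a cohort table as CSV
#'
#' Columns: \code{id}, the covariates (\code{ttv_cm3}, \code{het_A_pct},
#' \code{ttp_min}, \code{npi}), \code{time_months}, \code{event}.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @return The reader returns the data.frame; the writer returns \code{path}
#'   invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path)
  needed <- c("time_months", "event")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("cohort CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Write extracted vascularization features as JSON
#' @param features a \code{\link{extract_vav_features}} result.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
write_vav_features_json <- function(features, path) {
  jsonlite::write_json(unclass(features), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
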