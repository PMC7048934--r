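#' Kinetic analysis configuration
#'
#' Thresholds governing voxel-wise enhancement classification. Wash-in (the
#' percent signal increase during the first post-contrast minute, relative to
#' the pre-contrast baseline) is binned as weak \code{[30, 50)}, intermediate
#' \code{[50, 100]} or strong \code{(100, Inf)}; voxels below the enhancement
#' threshold are excluded from the enhancing tumor volume. Delayed enhancement
#' (percent change between the seventh and the first post-contrast minute,
#' relative to the first post-contrast frame) is binned as persistent
#' (\code{> +band}), plateau (\code{[-band, +band]}) or wash-out
#' (\code{< -band}).
#'
#' The enhancement threshold is inclusive (a voxel at exactly 30\% wash-in is
#' enhancing), so the nominal threshold value itself is part of the weak bin.
#'
#' @param enhancement_threshold_pct minimum wash-in (\%) for a voxel to count
#'   as enhancing tumor; default 30.
#' @param weak_max,intermediate_max upper bounds (\%) of the weak and
#'   intermediate wash-in bins; defaults 50 and 100.
#' @param plateau_band half-width (\%) of the delayed-phase plateau band;
#'   default 10.
#' @param washout_form how the cluster wash-out ratio is scored:
#'   \code{"difference"} (wash-in minus delayed change; default) or
#'   \code{"quotient"} (wash-in divided by the wash-out magnitude).
#' @param quotient_eps floor (\%) on the wash-out magnitude in the quotient
#'   form, guarding against division by values near zero.
#' @param cluster_mode \code{"sliding"} (stride-1 3x3 windows; default) or
#'   \code{"tiled"} (disjoint 3x3 tiling).
#' @return A list of class \code{"kinetic_config"}.
#' @export
kinetic_config <- function(enhancement_threshold_pct = 30,
                           weak_max = 50,
                           intermediate_max = 100,
                           plateau_band = 10,
                           washout_form = c("difference", "quotient"),
                           quotient_eps = 1,
                           cluster_mode = c("sliding", "tiled")) {
  washout_form <- match.arg(washout_form)
  cluster_mode <- match.arg(cluster_mode)
  if (!(weak_max < intermediate_max)) {
    stop("wash-in bin bounds must be strictly increasing: ",
         "weak_max < intermediate_max", call. = FALSE)
  }
  if (enhancement_threshold_pct <= 0) {
    stop("`enhancement_threshold_pct` must be positive", call. = FALSE)
  }
  if (plateau_band <= 0) stop("`plateau_band` must be positive", call. = FALSE)
  if (quotient_eps <= 0) stop("`quotient_eps` must be positive", call. = FALSE)
  structure(
    list(enhancement_threshold_pct = enhancement_threshold_pct,
         weak_max = weak_max,
         intermediate_max = intermediate_max,
         plateau_band = plateau_band,
         washout_form = washout_form,
         quotient_eps = quotient_eps,
         cluster_mode = cluster_mode),
    class = "kinetic_config"
  )
}

#' Dynamic contrast-enhanced MRI series
#'
#' Container for an 8-frame dynamic series (one pre-contrast frame followed by
#' seven post-contrast frames at one-minute spacing) with voxel geometry and a
#' rectangular volume of interest (VOI).
#'
#' @param signal 4D nonnegative array indexed \code{[t, z, y, x]} with exactly
#'   8 timepoints.
#' @param voxel_size_mm voxel edge lengths in mm along (z, y, x); default
#'   \code{c(3.0, 0.9, 1.1)} (3 mm slices, 0.9 x 1.1 mm in plane).
#' @param voi rectangular cuboid as half-open, 0-based voxel index ranges:
#'   a list with elements \code{z}, \code{y}, \code{x}, each \code{c(from, to)}
#'   meaning indices \code{from .. to-1}. \code{NULL} (default) means the full
#'   grid.
#' @return An object of class \code{"dynamic_series"}.
#' @export
dynamic_series <- function(signal, voxel_size_mm = c(3.0, 0.9, 1.1), voi = NULL) {
  d <- dim(signal)
  if (length(d) != 4L || d[1] != 8L) {
    stop("`signal` must be a 4D array [t, z, y, x] with exactly 8 timepoints",
         call. = FALSE)
  }
  if (anyNA(signal)) stop("`signal` contains missing values", call. = FALSE)
  if (min(signal) < 0) stop("`signal` must be nonnegative", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be three positive lengths (z, y, x)", call. = FALSE)
  }
  grid <- d[2:4]
  if (is.null(voi)) {
    voi <- list(z = c(0L, grid[1]), y = c(0L, grid[2]), x = c(0L, grid[3]))
  }
  validate_voi(voi, grid)
  structure(
    list(signal = signal, voxel_size_mm = as.numeric(voxel_size_mm), voi = voi),
    class = "dynamic_series"
  )
}

validate_voi <- function(voi, grid) {
  if (!is.list(voi) || !all(c("z", "y", "x") %in% names(voi))) {
    stop("`voi` must be a list with elements z, y, x", call. = FALSE)
  }
  for (i in 1:3) {
    ax <- c("z", "y", "x")[i]
    r <- voi[[ax]]
    if (length(r) != 2L || r[1] < 0 || r[2] > grid[i] || r[1] >= r[2]) {
      stop(sprintf(
        "VOI range for axis %s (%s:%s) falls outside the grid (0:%d) or is empty",
        ax, r[1], r[2], grid[i]), call. = FALSE)
    }
  }
  invisible(voi)
}

# 1-based index sequences for the (half-open, 0-based) VOI along each axis.
voi_indices <- function(series) {
  lapply(series$voi, function(r) seq.int(r[1] + 1L, r[2]))
}

#' Voxel volume of a dynamic series in cm^3
#' @param series a \code{dynamic_series}.
#' @return Scalar voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(series) {
  prod(series$voxel_size_mm) / 1000
}

#' Compute the kinetic descriptors of one enhancement curve
#'
#' From an 8-point signal-intensity curve (pre-contrast baseline SI0 then
#' post-contrast SI1..SI7) compute wash-in \eqn{100 (SI_1 - SI_0)/SI_0},
#' delayed change \eqn{100 (SI_7 - SI_1)/SI_1}, peak enhancement
#' \eqn{\max_t 100 (SI_t - SI_0)/SI_0} over the post-contrast frames, and the
#' time to peak (the earliest minute attaining the maximum).
#'
#' A curve whose baseline (or first post-contrast frame) is not positive
#' cannot be normalized; it is returned flagged invalid rather than raising,
#' so whole-volume callers can exclude such voxels and keep going.
#'
#' @param curve numeric vector of 8 nonnegative signal intensities.
#' @param config a \code{\link{kinetic_config}} (unused by the formulas but
#'   accepted for interface symmetry).
#' @return A list of class \code{"voxel_kinetics"} with fields
#'   \code{wash_in_pct}, \code{delayed_pct}, \code{peak_pct}, \code{ttp_min},
#'   \code{valid}.
#' @examples
#' compute_voxel_kinetics(c(100, 270, 250, 230, 200, 175, 150, 135))
#' @export
compute_voxel_kinetics <- function(curve, config = kinetic_config()) {
  if (length(curve) != 8L) {
    stop("`curve` must contain exactly 8 signal intensities", call. = FALSE)
  }
  if (anyNA(curve) || any(!is.finite(curve))) {
    stop("`curve` contains non-finite values", call. = FALSE)
  }
  si0 <- curve[1]
  si1 <- curve[2]
  if (si0 <= 0 || si1 <= 0) {
    return(structure(list(wash_in_pct = NA_real_, delayed_pct = NA_real_,
                          peak_pct = NA_real_, ttp_min = NA_integer_,
                          valid = FALSE),
                     class = "voxel_kinetics"))
  }
  enh <- 100 * (curve[2:8] - si0) / si0
  structure(
    list(wash_in_pct = enh[1],
         delayed_pct = 100 * (curve[8] - si1) / si1,
         peak_pct = max(enh),
         ttp_min = which.max(enh),   # which.max takes the earliest maximum
         valid = TRUE),
    class = "voxel_kinetics"
  )
}

# Vectorized classification of (wash_in, delayed) pairs into pattern codes:
# 0 = excluded, 1..9 = categories A..I laid out initial-phase-major
# (A = weak/persistent ... I = strong/wash-out). NA kinetics -> 0.
classify_pattern_code <- function(wash_in, delayed, config = kinetic_config()) {
  code <- integer(length(wash_in))
  ok <- !is.na(wash_in) & !is.na(delayed) &
    wash_in >= config$enhancement_threshold_pct
  initial <- ifelse(wash_in < config$weak_max, 1L,
                    ifelse(wash_in <= config$intermediate_max, 2L, 3L))
  phase <- ifelse(delayed > config$plateau_band, 1L,
                  ifelse(delayed < -config$plateau_band, 3L, 2L))
  code[ok] <- (initial[ok] - 1L) * 3L + phase[ok]
  code
}

#' Names of the nine enhancement-pattern categories
#'
#' Letters A..I in the canonical layout: initial phase (weak, intermediate,
#' strong) crossed with delayed phase (persistent, plateau, wash-out), the
#' initial phase varying slowest. So A = weak + persistent, E = intermediate +
#' plateau, I = strong + wash-out.
#' @return Character vector \code{LETTERS[1:9]}.
#' @export
pattern_categories <- function() LETTERS[1:9]

#' Classify a voxel's kinetics into one of the nine enhancement patterns
#'
#' @param k a \code{voxel_kinetics} (from \code{\link{compute_voxel_kinetics}}),
#'   or a list with \code{wash_in_pct} and \code{delayed_pct}.
#' @param config a \code{\link{kinetic_config}}.
#' @return \code{"excluded"} (sub-threshold wash-in or invalid kinetics) or
#'   one of \code{"A"}..\code{"I"}.
#' @examples
#' classify_voxel(list(wash_in_pct = 40, delayed_pct = 20))   # "A"
#' classify_voxel(list(wash_in_pct = 170, delayed_pct = -50)) # "I"
#' @export
classify_voxel <- function(k, config = kinetic_config()) {
  code <- classify_pattern_code(k$wash_in_pct, k$delayed_pct, config)
  c("excluded", pattern_categories())[code + 1L]
}

# Per-voxel kinetic maps over the VOI of a series. Returns 3D arrays (VOI
# dims, order z,y,x): wash_in, delayed, peak, ttp, plus logical `valid`
# (baseline and first post-contrast frame positive).
voxel_kinetics_volume <- function(series) {
  idx <- voi_indices(series)
  sig <- series$signal[, idx$z, idx$y, idx$x, drop = FALSE]
  d <- dim(sig)[2:4]
  grab <- function(t) array(sig[t, , , ], dim = d)
  si0 <- grab(1)
  si1 <- grab(2)
  si7 <- grab(8)
  valid <- si0 > 0 & si1 > 0
  safe0 <- ifelse(valid, si0, 1)
  safe1 <- ifelse(valid, si1, 1)
  wash_in <- ifelse(valid, 100 * (si1 - si0) / safe0, NA_real_)
  delayed <- ifelse(valid, 100 * (si7 - si1) / safe1, NA_real_)
  peak <- wash_in
  ttp <- array(1L, dim = d)
  for (t in 3:8) {
    enh_t <- ifelse(valid, 100 * (grab(t) - si0) / safe0, NA_real_)
    better <- !is.na(enh_t) & enh_t > peak   # strict: earliest max wins ties
    ttp[better] <- t - 1L
    peak[better] <- enh_t[better]
  }
  list(wash_in = wash_in, delayed = delayed, peak = peak, ttp = ttp,
       valid = valid, voi_dim = d)
}

#' Segment the total enhancing tumor volume (TTV)
#'
#' Marks every VOI voxel whose wash-in reaches the enhancement threshold and
#' converts the voxel count to cm^3. Sub-threshold voxels (perifocal tissue,
#' necrosis) and voxels whose baseline signal is zero (air) are excluded; the
#' latter are counted in \code{n_invalid}.
#'
#' @param series a \code{\link{dynamic_series}}.
#' @param config a \code{\link{kinetic_config}}.
#' @return A list with \code{mask} (3D logical over the full grid, FALSE
#'   outside the VOI), \code{ttv_cm3}, \code{n_voxels} and \code{n_invalid}.
#'   An empty mask with \code{ttv_cm3 = 0} is allowed.
#' @export
segment_ttv <- function(series, config = kinetic_config()) {
  kin <- voxel_kinetics_volume(series)
  enh <- kin$valid & kin$wash_in >= config$enhancement_threshold_pct
  grid <- dim(series$signal)[2:4]
  mask <- array(FALSE, dim = grid)
  idx <- voi_indices(series)
  mask[idx$z, idx$y, idx$x] <- enh
  n <- sum(enh)
  list(mask = mask,
       ttv_cm3 = n * voxel_volume_cm3(series),
       n_voxels = n,
       n_invalid = sum(!kin$valid))
}

#' Heterogeneity-of-vascularization matrix
#'
#' Distributes the enhancing tumor voxels over the nine enhancement patterns
#' and expresses each as a percentage of the TTV. Laid out as a 3x3 matrix,
#' initial phase (weak, intermediate, strong) by delayed phase (persistent,
#' plateau, wash-out); cell \code{[1,1]} is category A, cell \code{[3,3]}
#' category I. The nine cells sum to 100.
#'
#' @param series a \code{\link{dynamic_series}}.
#' @param mask enhancing-voxel mask from \code{\link{segment_ttv}} (full-grid
#'   logical array); must contain at least one voxel.
#' @param config a \code{\link{kinetic_config}}.
#' @return 3x3 numeric matrix of percentages with dimnames
#'   \code{initial x delayed}; attribute \code{"n_voxels"} carries the TTV
#'   voxel count.
#' @export
heterogeneity_matrix <- function(series, mask, config = kinetic_config()) {
  if (!any(mask)) {
    stop("empty enhancing mask: handle ttv = 0 before requesting the ",
         "heterogeneity matrix", call. = FALSE)
  }
  kin <- voxel_kinetics_volume(series)
  idx <- voi_indices(series)
  mask_voi <- mask[idx$z, idx$y, idx$x, drop = FALSE]
  codes <- classify_pattern_code(kin$wash_in[mask_voi], kin$delayed[mask_voi],
                                 config)
  counts <- tabulate(codes, nbins = 9L)
  m <- matrix(100 * counts / sum(mask_voi), nrow = 3, byrow = TRUE,
              dimnames = list(initial = c("weak", "intermediate", "strong"),
                              delayed = c("persistent", "plateau", "wash-out")))
  attr(m, "n_voxels") <- sum(mask_voi)
  m
}

#' Flatten a heterogeneity matrix to the named A..I percentage vector
#' @param m matrix from \code{\link{heterogeneity_matrix}}.
#' @return Named numeric vector \code{A}..\code{I}.
#' @export
heterogeneity_vector <- function(m) {
  stats::setNames(as.vector(t(m)), pattern_categories())
}

#' Full-grid map of enhancement-pattern codes
#'
#' Integer codes per voxel: 0 = excluded (outside the VOI, sub-threshold or
#' invalid), 1..9 = categories A..I. Suitable for writing as a 3D label
#' volume for heat-map rendering.
#'
#' @inheritParams heterogeneity_matrix
#' @return 3D integer array with the grid shape of \code{series}.
#' @export
pattern_label_map <- function(series, config = kinetic_config()) {
  kin <- voxel_kinetics_volume(series)
  codes <- classify_pattern_code(kin$wash_in, kin$delayed, config)
  grid <- dim(series$signal)[2:4]
  lab <- array(0L, dim = grid)
  idx <- voi_indices(series)
  lab[idx$z, idx$y, idx$x] <- codes
  lab
}

#' Extract the 14 vascularization features of a dynamic series
#'
#' Runs the complete volumetric analysis: TTV segmentation, the nine-cell
#' heterogeneity matrix, and the four most-suspect-compartment descriptors
#' from the sliding 3x3 cluster search.
#'
#' @param series a \code{\link{dynamic_series}} whose VOI encloses the tumor.
#' @param config a \code{\link{kinetic_config}}.
#' @return A list of class \code{"vav_features"}: \code{ttv_cm3}, the nine
#'   heterogeneity percentages \code{het_A}..\code{het_I}, and
#'   \code{msc_ttp_min}, \code{msc_peak_pct}, \code{msc_wash_in_pct},
#'   \code{msc_washout_ratio}.
#' @export
extract_vav_features <- function(series, config = kinetic_config()) {
  seg <- segment_ttv(series, config)
  if (seg$n_voxels == 0L) {
    stop("no enhancing voxels inside the VOI: TTV is zero, no features to extract",
         call. = FALSE)
  }
  het <- heterogeneity_vector(heterogeneity_matrix(series, seg$mask, config))
  msc <- find_most_suspect(series, seg$mask, config)
  out <- c(list(ttv_cm3 = seg$ttv_cm3),
           as.list(stats::setNames(het, paste0("het_", names(het)))),
           list(msc_ttp_min = msc$ttp_min,
                msc_peak_pct = msc$peak_pct,
                msc_wash_in_pct = msc$wash_in_pct,
                msc_washout_ratio = msc$washout_ratio))
  structure(out, class = "vav_features", n_voxels = seg$n_voxels,
            n_invalid = seg$n_invalid, msc = msc)
}

#' @export
print.vav_features <- function(x, ...) {
  cat("Vascularization features (14 parameters)\n")
  cat(sprintf("  TTV: %.3f cm^3 (%d voxels)\n", x$ttv_cm3, attr(x, "n_voxels")))
  het <- unlist(x[paste0("het_", pattern_categories())])
  cat("  Heterogeneity (% of TTV):\n")
  print(round(matrix(het, 3, byrow = TRUE,
                     dimnames = list(c("weak", "intermediate", "strong"),
                                     c("persistent", "plateau", "wash-out"))), 1))
  cat(sprintf("  Most suspect compartment: wash-in %.1f%%, peak %.1f%% at %d min, washout ratio %.1f\n",
              x$msc_wash_in_pct, x$msc_peak_pct, x$msc_ttp_min,
              x$msc_washout_ratio))
  invisible(x)
}
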