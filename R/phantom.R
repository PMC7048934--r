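# Synthetic DCE-MRI tumor phantoms with known kinetic composition.

#' Canonical curve templates for the nine enhancement patterns
#'
#' One template per category, placed at the center of its (wash-in x delayed)
#' cell so that classification margins stay wide under modest noise: wash-in
#' +40\% (weak), +75\% (intermediate), +170\% (strong); delayed change +20\%
#' (persistent), 0\% (plateau), -30\% (wash-out). Category I therefore
#' matches the textbook malignant curve: +170\% wash-in followed by a 50-unit
#' drop of enhancement relative to baseline by minute seven.
#'
#' @return data.frame with columns \code{category}, \code{wash_in_pct},
#'   \code{delayed_pct}.
#' @export
pattern_templates <- function() {
  data.frame(
    category = pattern_categories(),
    wash_in_pct = rep(c(40, 75, 170), each = 3),
    delayed_pct = rep(c(20, 0, -30), times = 3)
  )
}

# 8-point curve realizing a (wash-in, delayed) template: baseline, then
# linear interpolation between SI1 and SI7 across the post-contrast minutes.
template_curve <- function(wash_in_pct, delayed_pct, baseline) {
  si1 <- baseline * (1 + wash_in_pct / 100)
  si7 <- si1 * (1 + delayed_pct / 100)
  c(baseline, si1 + (si7 - si1) * (0:6) / 6)
}

#' Specification of a DCE-MRI tumor phantom
#'
#' Describes an ellipsoidal tumor embedded in a flat background: which of the
#' nine enhancement patterns its voxels follow (\code{pattern_mix}), how much
#' of it is non-enhancing necrotic core, and the acquisition geometry and
#' noise level. Defaults mimic a heterogeneous invasive carcinoma: a little
#' over half the enhancing volume in the persistent weak/intermediate columns
#' and about 10\% in the strong wash-out pattern, with a necrotic core.
#'
#' @param grid_shape voxels per axis (z, y, x).
#' @param voxel_size_mm voxel edge lengths in mm (z, y, x); default
#'   \code{c(3.0, 0.9, 1.1)}.
#' @param tumor_extent ellipsoid semi-axes in voxels (z, y, x).
#' @param pattern_mix nine nonnegative fractions over categories A..I summing
#'   to 1 (named or in A..I order).
#' @param necrotic_fraction fraction of tumor voxels given sub-threshold
#'   enhancement, in \code{[0, 1)}.
#' @param baseline_signal pre-contrast signal intensity (a.u.), positive.
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param seed integer seed; the whole phantom is a pure function of the spec.
#' @param templates optional replacement for \code{\link{pattern_templates}}.
#' @return A list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(grid_shape = c(12, 40, 40),
                         voxel_size_mm = c(3.0, 0.9, 1.1),
                         tumor_extent = c(4, 12, 12),
                         pattern_mix = c(A = 0.306, B = 0.060, C = 0.040,
                                         D = 0.253, E = 0.080, F = 0.050,
                                         G = 0.058, H = 0.050, I = 0.103),
                         necrotic_fraction = 0.15,
                         baseline_signal = 100,
                         noise_sd = 2,
                         seed = 1L,
                         templates = pattern_templates()) {
  if (length(pattern_mix) != 9L || any(pattern_mix < 0)) {
    stop("`pattern_mix` must be 9 nonnegative fractions (categories A..I)",
         call. = FALSE)
  }
  if (is.null(names(pattern_mix))) names(pattern_mix) <- pattern_categories()
  pattern_mix <- pattern_mix[pattern_categories()]
  if (abs(sum(pattern_mix) - 1) > 1e-9) {
    stop("`pattern_mix` must sum to 1 (got ", sum(pattern_mix), ")", call. = FALSE)
  }
  if (necrotic_fraction < 0 || necrotic_fraction >= 1) {
    stop("`necrotic_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (any(grid_shape < 1) || any(tumor_extent <= 0)) {
    stop("grid and tumor extents must be positive", call. = FALSE)
  }
  if (baseline_signal <= 0) stop("`baseline_signal` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         tumor_extent = as.numeric(tumor_extent),
         pattern_mix = pattern_mix,
         necrotic_fraction = necrotic_fraction,
         baseline_signal = baseline_signal,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         templates = templates),
    class = "phantom_spec"
  )
}

# Ground-truth label codes for phantom voxels.
LABEL_BACKGROUND <- 0L
LABEL_NECROTIC <- 10L

#' Generate a DCE-MRI tumor phantom with known composition
#'
#' Builds an 8-frame dynamic series: an ellipsoidal tumor centered in the
#' grid whose voxels follow the canonical curve of their assigned category
#' (allocated to the nine patterns by largest-remainder apportionment of
#' \code{pattern_mix}, after carving out the necrotic core), a flat
#' background at baseline signal, and a weakly enhancing (+10\% wash-in,
#' sub-threshold) necrotic core. Gaussian noise is added after template
#' assignment and intensities are clipped at zero. The VOI is the tumor
#' bounding box padded by two voxels.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with \code{series} (a \code{\link{dynamic_series}}) and
#'   \code{truth}: \code{labels} (3D integer array; 0 background, 1..9
#'   categories A..I, 10 necrotic), realized per-category \code{counts} and
#'   \code{fractions} (of enhancing tumor voxels), \code{n_tumor},
#'   \code{n_necrotic} and the \code{spec}.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  ctr <- (g + 1) / 2
  z <- slice.index(array(0, g), 1)
  y <- slice.index(array(0, g), 2)
  x <- slice.index(array(0, g), 3)
  inside <- ((z - ctr[1]) / spec$tumor_extent[1])^2 +
    ((y - ctr[2]) / spec$tumor_extent[2])^2 +
    ((x - ctr[3]) / spec$tumor_extent[3])^2 <= 1
  n_tumor <- sum(inside)
  if (n_tumor == 0L) {
    stop("tumor extent (", paste(spec$tumor_extent, collapse = ", "),
         ") yields zero tumor voxels on grid (",
         paste(g, collapse = ", "), ")", call. = FALSE)
  }

  with_seed(spec$seed, {
    vox <- sample(which(inside))  # random spatial arrangement of patterns
    n_necrotic <- round(spec$necrotic_fraction * n_tumor)
    n_enh <- n_tumor - n_necrotic
    counts <- apportion_counts(n_enh, spec$pattern_mix)

    labels <- array(LABEL_BACKGROUND, g)
    if (n_necrotic > 0) labels[vox[seq_len(n_necrotic)]] <- LABEL_NECROTIC
    at <- n_necrotic
    for (k in 1:9) {
      if (counts[k] > 0) {
        labels[vox[at + seq_len(counts[k])]] <- k
        at <- at + counts[k]
      }
    }

    nvox <- prod(g)
    signal <- matrix(spec$baseline_signal, nrow = 8, ncol = nvox)
    curves <- vapply(1:9, function(k) {
      template_curve(spec$templates$wash_in_pct[k], spec$templates$delayed_pct[k],
                     spec$baseline_signal)
    }, numeric(8))
    necro_curve <- template_curve(10, 0, spec$baseline_signal)
    lab_vec <- as.vector(labels)
    for (k in 1:9) {
      sel <- lab_vec == k
      if (any(sel)) signal[, sel] <- curves[, k]
    }
    sel <- lab_vec == LABEL_NECROTIC
    if (any(sel)) signal[, sel] <- necro_curve
    if (spec$noise_sd > 0) {
      signal <- signal + stats::rnorm(length(signal), sd = spec$noise_sd)
      signal[signal < 0] <- 0
    }
    signal <- array(signal, dim = c(8L, g))

    bb <- lapply(1:3, function(ax) {
      r <- range(slice.index(labels, ax)[labels != LABEL_BACKGROUND])
      c(max(0L, r[1] - 1L - 2L), min(g[ax], r[2] + 2L))  # 0-based half-open
    })
    names(bb) <- c("z", "y", "x")

    series <- dynamic_series(signal, spec$voxel_size_mm, voi = bb)
    list(series = series,
         truth = list(labels = labels,
                      counts = stats::setNames(counts, pattern_categories()),
                      fractions = stats::setNames(counts / n_enh, pattern_categories()),
                      n_tumor = n_tumor,
                      n_necrotic = n_necrotic,
                      spec = spec))
  })
}
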