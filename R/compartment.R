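# Most-suspect-compartment search: 3x3 in-plane clusters over the enhancing
# mask, scored by their wash-out ratio.

# Sum of each 3x3 window of a matrix (stride 1); returns an
# (nrow-2) x (ncol-2) matrix. Used to average member curves without looping
# over windows.
win3_sum <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr - 2L, nc - 2L)
  for (dy in 0:2) {
    for (dx in 0:2) {
      out <- out + m[(1L + dy):(nr - 2L + dy), (1L + dx):(nc - 2L + dx)]
    }
  }
  out
}

#' Enumerate 3x3 in-plane clusters of the enhancing tumor volume
#'
#' Slides a 3x3-voxel window (stride 1) across every slice of the grid and
#' keeps windows containing at least one enhancing voxel. Each cluster's
#' curve is the mean signal curve over its enhancing member voxels only.
#' Clusters never span slices. With \code{config$cluster_mode = "tiled"} the
#' windows form a disjoint tiling (stride 3, anchored at the slice origin)
#' instead.
#'
#' @param series a \code{\link{dynamic_series}}.
#' @param mask full-grid logical enhancing mask (see \code{\link{segment_ttv}}).
#' @param config a \code{\link{kinetic_config}}.
#' @return A list with \code{index}: data.frame of \code{slice}, \code{row},
#'   \code{col} (1-based top-left corner of each window, in deterministic
#'   slice/row/col order) and \code{n_members}; and \code{curves}: numeric
#'   matrix (clusters x 8) of mean member curves.
#' @export
enumerate_clusters <- function(series, mask, config = kinetic_config()) {
  if (!any(mask)) stop("empty enhancing mask: no clusters to enumerate", call. = FALSE)
  grid <- dim(series$signal)[2:4]
  if (grid[2] < 3L || grid[3] < 3L) {
    stop("grid in-plane dimensions must be at least 3x3 for cluster analysis",
         call. = FALSE)
  }
  stride_rows <- if (config$cluster_mode == "tiled") seq(1L, grid[2] - 2L, by = 3L) else seq_len(grid[2] - 2L)
  stride_cols <- if (config$cluster_mode == "tiled") seq(1L, grid[3] - 2L, by = 3L) else seq_len(grid[3] - 2L)

  idx_list <- list()
  curve_list <- list()
  for (z in seq_len(grid[1])) {
    mz <- mask[z, , ]
    if (!any(mz)) next
    counts <- win3_sum(mz * 1)[stride_rows, stride_cols, drop = FALSE]
    keep <- which(counts > 0, arr.ind = TRUE)
    if (nrow(keep) == 0L) next
    sums <- vapply(1:8, function(t) {
      st <- win3_sum(matrix(series$signal[t, z, , ], grid[2], grid[3]) * mz)
      st[stride_rows, stride_cols, drop = FALSE][keep]
    }, numeric(nrow(keep)))
    curves <- matrix(sums, nrow = nrow(keep), ncol = 8L) / counts[keep]
    ord <- order(keep[, 1], keep[, 2])  # row-major within slice
    idx_list[[length(idx_list) + 1L]] <- data.frame(
      slice = z,
      row = stride_rows[keep[ord, 1]],
      col = stride_cols[keep[ord, 2]],
      n_members = counts[keep][ord]
    )
    curve_list[[length(curve_list) + 1L]] <- curves[ord, , drop = FALSE]
  }
  list(index = do.call(rbind, idx_list),
       curves = do.call(rbind, curve_list))
}

#' Wash-out suspicion score of a cluster's mean curve
#'
#' Scores how strongly a curve combines fast wash-in with delayed wash-out.
#' The default \code{"difference"} form is wash-in minus delayed change (in
#' percentage points): it grows with wash-in and with wash-out magnitude and
#' stays stable when the delayed change is near zero. The \code{"quotient"}
#' form divides wash-in by the wash-out magnitude floored at
#' \code{quotient_eps}.
#'
#' @param curve numeric vector of 8 signal intensities (a cluster mean curve).
#' @param config a \code{\link{kinetic_config}} (fields \code{washout_form},
#'   \code{quotient_eps}).
#' @return Scalar score; higher is more suspect.
#' @examples
#' washout_score(c(100, 270, 250, 230, 200, 175, 150, 135)) # 170 - (-50) = 220
#' @export
washout_score <- function(curve, config = kinetic_config()) {
  k <- compute_voxel_kinetics(curve, config)
  if (!k$valid) return(-Inf)
  washout_score_values(k$wash_in_pct, k$delayed_pct, config)
}

# Vectorized score from precomputed wash-in / delayed percentages.
washout_score_values <- function(wash_in, delayed, config) {
  if (config$washout_form == "difference") {
    wash_in - delayed
  } else {
    wash_in / pmax(config$quotient_eps, -delayed)
  }
}

#' Locate the most suspect tumor compartment
#'
#' Finds the 3x3 cluster with the highest wash-out score; ties resolve to the
#' first cluster in the deterministic slice/row/col enumeration order. The
#' four compartment features are computed on the winner's mean member curve.
#'
#' @inheritParams enumerate_clusters
#' @return A list of class \code{"msc_features"}: \code{washout_ratio},
#'   \code{wash_in_pct}, \code{peak_pct}, \code{ttp_min}, plus the winning
#'   window location (\code{slice}, \code{row}, \code{col},
#'   \code{n_members}) and its \code{mean_curve}.
#' @export
find_most_suspect <- function(series, mask, config = kinetic_config()) {
  cl <- enumerate_clusters(series, mask, config)
  si0 <- cl$curves[, 1]
  si1 <- cl$curves[, 2]
  valid <- si0 > 0 & si1 > 0
  scores <- rep(-Inf, nrow(cl$curves))
  scores[valid] <- washout_score_values(
    100 * (si1[valid] - si0[valid]) / si0[valid],
    100 * (cl$curves[valid, 8] - si1[valid]) / si1[valid],
    config
  )
  if (!any(valid)) stop("no cluster has a positive baseline signal", call. = FALSE)
  win <- which.max(scores)  # earliest on ties
  k <- compute_voxel_kinetics(cl$curves[win, ], config)
  structure(
    list(washout_ratio = scores[win],
         wash_in_pct = k$wash_in_pct,
         peak_pct = k$peak_pct,
         ttp_min = k$ttp_min,
         slice = cl$index$slice[win],
         row = cl$index$row[win],
         col = cl$index$col[win],
         n_members = cl$index$n_members[win],
         mean_curve = cl$curves[win, ]),
    class = "msc_features"
  )
}
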