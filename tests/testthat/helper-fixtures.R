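# Shared fixture builders and independent oracles. Oracles are coded as
# plainly as possible (scalar logic, explicit loops) so they share nothing
# with the vectorized implementation paths they check.

# Build a dynamic series from a 3D integer label array and a list mapping
# label -> 8-point curve; unlabeled voxels stay flat at `baseline`.
series_from_labels <- function(labels, curve_map, baseline = 100,
                               voxel_size_mm = c(3.0, 0.9, 1.1), voi = NULL) {
  g <- dim(labels)
  signal <- array(baseline, dim = c(8L, g))
  for (lab in names(curve_map)) {
    sel <- which(labels == as.integer(lab))
    for (t in 1:8) {
      frame <- array(signal[t, , , ], dim = g)
      frame[sel] <- curve_map[[lab]][t]
      signal[t, , , ] <- frame
    }
  }
  dynamic_series(signal, voxel_size_mm = voxel_size_mm, voi = voi)
}

# The canonical strong wash-out curve (wash-in +170%, delayed -50% of the
# first post-contrast value): the textbook malignant kinetic.
curve_strong_washout <- function(baseline = 100) {
  si1 <- baseline * 2.7
  si7 <- si1 * 0.5
  c(baseline, si1 + (si7 - si1) * (0:6) / 6)
}

# Scalar reference classifier: independent nested-condition lookup.
naive_classify <- function(wash_in, delayed,
                           threshold = 30, weak_max = 50,
                           intermediate_max = 100, band = 10) {
  if (is.na(wash_in) || is.na(delayed)) return("excluded")
  if (wash_in < threshold) return("excluded")
  row <- if (wash_in < weak_max) {
    "weak"
  } else if (wash_in <= intermediate_max) {
    "intermediate"
  } else {
    "strong"
  }
  col <- if (delayed > band) {
    "persistent"
  } else if (delayed >= -band) {
    "plateau"
  } else {
    "wash-out"
  }
  lut <- matrix(LETTERS[1:9], nrow = 3, byrow = TRUE,
                dimnames = list(c("weak", "intermediate", "strong"),
                                c("persistent", "plateau", "wash-out")))
  lut[row, col]
}

# Naive O(n^2) concordance: explicit double loop over unordered pairs.
naive_concordance <- function(lp, time, event) {
  num <- 0
  den <- 0
  n <- length(lp)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # which subject is the determinably earlier death, if any?
      first <- 0L
      if (time[i] < time[j] && event[i] == 1) first <- i
      if (time[j] < time[i] && event[j] == 1) first <- j
      if (time[i] == time[j] && event[i] != event[j]) {
        first <- if (event[i] == 1) i else j
      }
      if (first == 0L) next
      second <- if (first == i) j else i
      den <- den + 1
      if (lp[first] > lp[second]) {
        num <- num + 1
      } else if (lp[first] == lp[second]) {
        num <- num + 0.5
      }
    }
  }
  num / den
}

# Exhaustive most-suspect search: loop every in-plane 3x3 window, average
# the enhancing members, score with the difference form.
brute_force_msc <- function(series, mask) {
  g <- dim(series$signal)[2:4]
  best <- NULL
  for (z in seq_len(g[1])) {
    for (r in seq_len(g[2] - 2)) {
      for (c in seq_len(g[3] - 2)) {
        members <- which(mask[z, r:(r + 2), c:(c + 2)])
        if (length(members) == 0) next
        sub <- series$signal[, z, r:(r + 2), c:(c + 2)]
        curve <- sapply(1:8, function(t) {
          mean(matrix(sub[t, , ], 3, 3)[members])
        })
        if (curve[1] <= 0 || curve[2] <= 0) next
        wi <- 100 * (curve[2] - curve[1]) / curve[1]
        del <- 100 * (curve[8] - curve[2]) / curve[2]
        score <- wi - del
        if (is.null(best) || score > best$score) {
          best <- list(score = score, slice = z, row = r, col = c)
        }
      }
    }
  }
  best
}

# Exhaustive Youden scan over all observed cutoffs.
brute_force_youden <- function(lp, lab) {
  best <- NULL
  for (c in sort(unique(lp))) {
    sens <- sum(lp >= c & lab == 1) / sum(lab == 1)
    spec <- sum(lp < c & lab == 0) / sum(lab == 0)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J) best <- list(cutoff = c, J = J)
  }
  best
}

# Random phantom spec with a Dirichlet-distributed pattern mix.
random_phantom_spec <- function(seed, grid_shape = c(8, 24, 24),
                                tumor_extent = c(3, 8, 8),
                                noise_sd = 2) {
  set.seed(seed)
  w <- rgamma(9, shape = 1)
  phantom_spec(grid_shape = grid_shape, tumor_extent = tumor_extent,
               pattern_mix = w / sum(w),
               necrotic_fraction = runif(1, 0, 0.3),
               noise_sd = noise_sd, seed = seed)
}
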