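test_that("voxel kinetics follow the normalization formulas", {
  k <- compute_voxel_kinetics(c(100, 160, 158, 156, 154, 152, 151, 150))
  expect_equal(k$wash_in_pct, 60)
  expect_equal(k$delayed_pct, 100 * (150 - 160) / 160)  # -6.25
  expect_equal(k$peak_pct, 60)
  expect_equal(k$ttp_min, 1)

  # the textbook malignant curve: strong wash-in then deep wash-out
  k <- compute_voxel_kinetics(curve_strong_washout())
  expect_equal(k$wash_in_pct, 170)
  expect_equal(k$delayed_pct, -50)
  expect_equal(k$peak_pct, 170)
  expect_equal(k$ttp_min, 1)

  # flat curve: no enhancement, earliest-maximum tie rule puts TTP at 1
  k <- compute_voxel_kinetics(rep(100, 8))
  expect_equal(k$wash_in_pct, 0)
  expect_equal(k$delayed_pct, 0)
  expect_equal(k$peak_pct, 0)
  expect_equal(k$ttp_min, 1)
})

test_that("degenerate curves are flagged or rejected", {
  expect_error(compute_voxel_kinetics(c(100, NA, rep(100, 6))), "non-finite")
  expect_error(compute_voxel_kinetics(rep(100, 7)), "exactly 8")
  k <- compute_voxel_kinetics(c(0, rep(100, 7)))
  expect_false(k$valid)
  expect_true(is.na(k$wash_in_pct))
})

test_that("peak is never below wash-in and TTP is the earliest maximum", {
  set.seed(42)
  for (i in 1:200) {
    curve <- c(100, pmax(0.1, 100 + cumsum(rnorm(7, sd = 30))))
    k <- compute_voxel_kinetics(curve)
    expect_gte(k$peak_pct, k$wash_in_pct)
    enh <- 100 * (curve[2:8] - curve[1]) / curve[1]
    expect_equal(k$ttp_min, min(which(enh == max(enh))))
  }
})

test_that("classification respects the bin boundaries", {
  cls <- function(wi, del) classify_voxel(list(wash_in_pct = wi, delayed_pct = del))
  expect_equal(cls(40, 20), "A")
  expect_equal(cls(170, -50), "I")
  expect_equal(cls(29.999, 0), "excluded")
  expect_equal(cls(30, 0), "B")       # the threshold value itself is included
  expect_equal(cls(49.999, 0), "B")
  expect_equal(cls(50, 0), "E")       # weak bin is right-open
  expect_equal(cls(100, 0), "E")      # intermediate bin includes 100
  expect_equal(cls(100.001, 0), "H")
  expect_equal(cls(60, 10), "E")      # plateau band is closed
  expect_equal(cls(60, 10.001), "D")
  expect_equal(cls(60, -10), "E")
  expect_equal(cls(60, -10.001), "F")
})

test_that("TTV segmentation converts voxel counts to cm^3", {
  # 1000 voxels of 3.0 x 0.9 x 1.1 mm = 2.97 mm^3 each -> 2.97 cm^3
  labels <- array(0L, c(10, 12, 12))
  labels[seq_len(1000)] <- 5L
  series <- series_from_labels(
    labels, list("5" = c(100, 175, 175, 175, 175, 175, 175, 175)))
  seg <- segment_ttv(series)
  expect_equal(seg$n_voxels, 1000)
  expect_equal(seg$ttv_cm3, 2.97)

  flat <- dynamic_series(array(100, c(8, 4, 6, 6)))
  seg0 <- segment_ttv(flat)
  expect_equal(seg0$ttv_cm3, 0)
  expect_false(any(seg0$mask))
})

test_that("TTV is monotone non-increasing in the enhancement threshold", {
  ph <- make_phantom(random_phantom_spec(7))
  ttv <- vapply(seq(30, 80, by = 10), function(thr) {
    segment_ttv(ph$series, kinetic_config(enhancement_threshold_pct = thr))$ttv_cm3
  }, numeric(1))
  expect_true(all(diff(ttv) <= 0))
})

test_that("zero-baseline voxels are excluded from TTV, not errors", {
  labels <- array(0L, c(4, 6, 6))
  labels[1, 1:2, 1] <- 5L
  series <- series_from_labels(
    labels, list("5" = c(100, 175, 175, 175, 175, 175, 175, 175)))
  series$signal[1, 2, 3, 3] <- 0  # an air voxel
  seg <- segment_ttv(series)
  expect_equal(seg$n_voxels, 2)
  expect_equal(seg$n_invalid, 1)
})

test_that("heterogeneity matrix puts a single-pattern tumor in one cell", {
  labels <- array(0L, c(4, 8, 8))
  labels[2:3, 3:6, 3:6] <- 1L
  series <- series_from_labels(
    labels, list("1" = c(100, 175, 175, 175, 175, 175, 175, 175)))  # E
  seg <- segment_ttv(series)
  m <- heterogeneity_matrix(series, seg$mask)
  expect_equal(unname(m["intermediate", "plateau"]), 100)
  expect_equal(sum(m), 100)
  expect_equal(unname(heterogeneity_vector(m)["E"]), 100)
})

test_that("heterogeneity matrix demands a nonempty mask", {
  flat <- dynamic_series(array(100, c(8, 4, 6, 6)))
  seg <- segment_ttv(flat)
  expect_error(heterogeneity_matrix(flat, seg$mask), "empty")
})

test_that("VOI outside the grid is rejected", {
  expect_error(
    dynamic_series(array(100, c(8, 4, 6, 6)),
                   voi = list(z = c(0, 5), y = c(0, 6), x = c(0, 6))),
    "outside the grid")
  expect_error(
    dynamic_series(array(100, c(8, 4, 6, 6)),
                   voi = list(z = c(2, 2), y = c(0, 6), x = c(0, 6))),
    "empty")
})

test_that("kinetic config rejects non-increasing thresholds", {
  expect_error(kinetic_config(weak_max = 120), "strictly increasing")
  expect_error(kinetic_config(plateau_band = 0), "positive")
})
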