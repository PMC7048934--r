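curve_E <- c(100, 175, 175, 175, 175, 175, 175, 175)

test_that("a lone enhancing voxel is the sole member of every covering window", {
  labels <- array(0L, c(2, 8, 8))
  labels[1, 4, 4] <- 1L
  series <- series_from_labels(labels, list("1" = curve_E))
  seg <- segment_ttv(series)
  cl <- enumerate_clusters(series, seg$mask)
  expect_equal(nrow(cl$index), 9)  # 3x3 window positions covering (4,4)
  expect_true(all(cl$index$n_members == 1))
  expect_true(all(apply(cl$curves, 1, function(x) all(x == curve_E))))
})

test_that("a full 3x3 patch on a 3x3 slice yields exactly one window", {
  labels <- array(0L, c(1, 3, 3))
  labels[1, , ] <- 1L
  series <- series_from_labels(labels, list("1" = curve_E))
  seg <- segment_ttv(series)
  cl <- enumerate_clusters(series, seg$mask)
  expect_equal(nrow(cl$index), 1)
  expect_equal(cl$index$n_members, 9)
})

test_that("clusters never span slices", {
  labels <- array(0L, c(2, 6, 6))
  labels[1, 2:4, 2:4] <- 1L
  labels[2, 2:4, 2:4] <- 2L
  series <- series_from_labels(
    labels, list("1" = curve_E, "2" = curve_strong_washout()))
  seg <- segment_ttv(series)
  cl <- enumerate_clusters(series, seg$mask)
  # every window's curve must be a pure mix of its own slice's template
  for (i in seq_len(nrow(cl$index))) {
    tpl <- if (cl$index$slice[i] == 1) curve_E else curve_strong_washout()
    expect_equal(unname(cl$curves[i, ]), tpl)
  }
})

test_that("tiled mode produces disjoint windows", {
  labels <- array(1L, c(1, 9, 9))
  series <- series_from_labels(labels, list("1" = curve_E))
  seg <- segment_ttv(series)
  cl <- enumerate_clusters(series, seg$mask, kinetic_config(cluster_mode = "tiled"))
  expect_equal(nrow(cl$index), 9)           # 9x9 slice tiles into 3x3 blocks
  expect_true(all(cl$index$n_members == 9))
  expect_true(all(diff(sort(unique(cl$index$row))) == 3))
})

test_that("washout score orders curves by suspicion", {
  expect_equal(washout_score(curve_strong_washout()), 220)  # 170 - (-50)
  persistent_weak <- c(100, 140, 142, 145, 148, 150, 154, 168)  # +40%, +20%
  expect_equal(washout_score(persistent_weak), 20)
  expect_lt(washout_score(persistent_weak), washout_score(curve_strong_washout()))
  expect_identical(washout_score(curve_E), washout_score(curve_E))
  # quotient form: wash-in over wash-out magnitude, floored at eps
  qc <- kinetic_config(washout_form = "quotient")
  expect_equal(washout_score(curve_strong_washout(), qc), 170 / 50)
  shallow_washout <- c(100, 270, 260, 255, 250, 245, 240, 237.6)  # -12%
  expect_gt(washout_score(shallow_washout, qc),
            washout_score(curve_strong_washout(), qc))
})

test_that("the most suspect compartment is the strong wash-out patch", {
  labels <- array(1L, c(3, 10, 10))  # category-A background
  labels[2, 4:6, 4:6] <- 2L          # category-I patch
  curve_A <- c(100, 140, 142, 145, 148, 150, 154, 168)
  series <- series_from_labels(labels, list("1" = curve_A,
                                            "2" = curve_strong_washout()))
  seg <- segment_ttv(series)
  msc <- find_most_suspect(series, seg$mask)
  expect_equal(msc$slice, 2)
  expect_equal(msc$wash_in_pct, 170)
  expect_equal(msc$peak_pct, 170)
  expect_equal(msc$ttp_min, 1)
  expect_equal(msc$washout_ratio, 220)
  expect_equal(unname(c(msc$row, msc$col)), c(4, 4))
})

test_that("a uniform phantom makes every full window score identically", {
  labels <- array(1L, c(1, 6, 6))
  series <- series_from_labels(labels, list("1" = curve_E))
  seg <- segment_ttv(series)
  cl <- enumerate_clusters(series, seg$mask)
  scores <- apply(cl$curves, 1, washout_score)
  expect_equal(max(scores) - min(scores), 0)
  msc <- find_most_suspect(series, seg$mask)
  expect_equal(msc$washout_ratio, scores[1])
})

test_that("sliding search matches exhaustive enumeration on random volumes", {
  set.seed(314)
  for (rep in 1:10) {
    g <- c(sample(1:3, 1), sample(4:10, 1), sample(4:10, 1))
    signal <- array(runif(8 * prod(g), 50, 300), c(8, g))
    signal[1, , , ] <- 100  # common positive baseline
    series <- dynamic_series(signal)
    mask <- array(runif(prod(g)) < 0.4, g)
    if (!any(mask)) next
    msc <- find_most_suspect(series, mask)
    ref <- brute_force_msc(series, mask)
    expect_equal(msc$washout_ratio, ref$score)
    expect_equal(c(msc$slice, msc$row, msc$col), c(ref$slice, ref$row, ref$col))
  }
})

test_that("an empty mask is rejected", {
  series <- dynamic_series(array(100, c(8, 2, 4, 4)))
  mask <- array(FALSE, c(2, 4, 4))
  expect_error(enumerate_clusters(series, mask), "empty")
  expect_error(find_most_suspect(series, mask), "empty")
})
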