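test_that("NPI follows the formula with the nodal-score mapping", {
  expect_equal(compute_npi(5.8, 5, 2)$npi_1dp, 6.2)
  expect_equal(compute_npi(1.0, 0, 1)$npi, 2.2)   # minimum for a 1 cm tumor
  # the 4-vs-5 node boundary moves the score by a whole point
  expect_equal(compute_npi(2.0, 4, 3)$npi, 5.4)
  expect_equal(compute_npi(2.0, 5, 3)$npi, 6.4)
  expect_equal(compute_npi(c(1, 2), c(0, 5), c(1, 3))$node_points, c(1, 3))
  expect_error(compute_npi(2, 0, 4), "grade")
  expect_error(compute_npi(0, 0, 1), "positive")
  expect_error(compute_npi(2, -1, 1), "nonnegative")
})

test_that("univariate screening keeps signal and honours alpha = 1", {
  co <- make_cohort(cohort_spec(n_subjects = 600, seed = 10))
  tab <- co$table
  tab$true_lp <- co$truth$linear_predictor
  set.seed(1)
  tab$noise <- rnorm(nrow(tab))
  scr <- univariate_screen(tab, c("true_lp", "noise", "ttp_min"))
  expect_true("true_lp" %in% scr$eligible)
  scr_all <- univariate_screen(tab, c("true_lp", "noise"), alpha = 1)
  expect_setequal(scr_all$eligible, c("true_lp", "noise"))
  expect_error(univariate_screen(tab[tab$event == 0, ], "noise"), "2 events")
})

test_that("backward selection drops noise and keeps informative covariates", {
  co <- make_cohort(cohort_spec(n_subjects = 800, seed = 14))
  tab <- co$table
  tab$true_lp <- co$truth$linear_predictor
  removed <- 0
  for (s in 1:5) {
    set.seed(s)
    tab$noise <- rnorm(nrow(tab))
    fit <- fit_cox_backward(tab, c("true_lp", "noise"))
    if (!"noise" %in% fit$covariates) removed <- removed + 1
    expect_true("true_lp" %in% fit$covariates)
  }
  expect_gte(removed, 4)  # noise survives a 5% threshold only ~5% of the time
})

test_that("selection leaves a single significant covariate untouched", {
  co <- make_cohort(cohort_spec(n_subjects = 400, seed = 6))
  fit <- fit_cox_backward(co$table, "ttp_min")
  expect_equal(fit$covariates, "ttp_min")
  full <- survival::coxph(survival::Surv(time_months, event) ~ ttp_min,
                          data = co$table, ties = "efron")
  expect_equal(unname(fit$coefficients), unname(coef(full)))
})

test_that("hazard ratios are exactly exponentiated coefficients with bracketing CIs", {
  co <- make_cohort(cohort_spec(n_subjects = 500, seed = 17))
  fit <- fit_cox_backward(co$table, names(published_coefficients()),
                          p_remove = 1)
  expect_equal(unname(fit$hr), unname(exp(fit$coefficients)), tolerance = 1e-12)
  expect_true(all(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper))
})

test_that("model chi-squared never decreases when adding an informative covariate", {
  co <- make_cohort(cohort_spec(n_subjects = 500, seed = 19))
  chi <- vapply(list("npi", c("npi", "ttp_min"),
                     c("npi", "ttp_min", "het_A_pct")), function(covs) {
    fit_cox_backward(co$table, covs, p_remove = 1)$chi_squared
  }, numeric(1))
  expect_true(all(diff(chi) >= 0))
})

test_that("concordance handles the canonical edge cases", {
  expect_equal(harrells_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrells_c(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(harrells_c(c(2, 2, 2), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_error(harrells_c(c(1, 2), c(5, 6), c(0, 0)), "no usable pairs")
})

test_that("concordance equals naive pair enumeration and survival::concordance", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    lp <- sample(1:5, n, replace = TRUE)          # forces predictor ties
    time <- sample(1:10, n, replace = TRUE)       # forces time ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) next
    ref <- naive_concordance(lp, time, event)
    if (is.nan(ref)) next
    expect_equal(harrells_c(lp, time, event), ref)
  }
  # tie-free data: also agrees with the survival package's estimator
  for (rep in 1:10) {
    n <- 30
    lp <- rnorm(n)
    time <- rexp(n)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    cs <- survival::concordance(survival::Surv(time, event) ~ lp, reverse = TRUE)
    expect_equal(harrells_c(lp, time, event), unname(cs$concordance))
  }
})

test_that("concordance is invariant under strictly monotone transforms", {
  set.seed(4)
  lp <- rnorm(60)
  time <- rexp(60)
  event <- rbinom(60, 1, 0.5)
  c0 <- harrells_c(lp, time, event)
  expect_equal(harrells_c(exp(lp), time, event), c0)
  expect_equal(harrells_c(rank(lp, ties.method = "average"), time, event), c0)
})

test_that("with no censoring and a binary score, concordance is the early-death probability", {
  # all 3-subject configurations with distinct times, enumerated directly
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (lp in list(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))) {
    for (tm in perms) {
      pairs <- utils::combn(3, 2)
      num <- 0
      den <- 0
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        if (lp[i] == lp[j]) { num <- num + 0.5; den <- den + 1; next }
        hi <- if (lp[i] > lp[j]) i else j
        lo <- if (lp[i] > lp[j]) j else i
        den <- den + 1
        if (tm[hi] < tm[lo]) num <- num + 1
      }
      expect_equal(harrells_c(lp, tm, c(1, 1, 1)), num / den)
    }
  }
})

test_that("Youden cutoff separates a separable cohort and matches brute force", {
  yc <- youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(yc$J, 1)
  expect_equal(yc$cutoff, 3)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    lp <- round(rnorm(n), 1)
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    ref <- brute_force_youden(lp, lab)
    yc <- youden_cutoff(lp, lab)
    expect_equal(yc$J, ref$J)
    expect_equal(yc$cutoff, ref$cutoff)
  }
  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("Youden J is near zero when scores carry no information", {
  set.seed(23)
  J <- replicate(20, {
    lp <- rnorm(400)
    lab <- rbinom(400, 1, 0.3)
    youden_cutoff(lp, lab)$J
  })
  expect_lt(mean(J), 0.15)
})

test_that("duplicated groups give a null Kaplan-Meier comparison", {
  co <- make_cohort(cohort_spec(n_subjects = 150, seed = 31))
  tab <- rbind(co$table, co$table)
  grp <- rep(c("a", "b"), each = nrow(co$table))
  km <- km_compare(tab$time_months, tab$event, grp)
  expect_equal(km$hr, 1, tolerance = 1e-6)
  expect_gt(km$logrank_p, 0.99)
  expect_true(all(km$curves$survival <= 1))
  # survival starts at 1 in both groups
  sf <- survival::survfit(survival::Surv(tab$time_months, tab$event) ~ grp)
  expect_equal(unname(summary(sf, times = 0)$surv), c(1, 1))
})

test_that("Kaplan-Meier comparison recovers a fourfold-and-a-half hazard ratio", {
  true_hr <- 4.5
  set.seed(55)
  est <- replicate(10, {
    n <- 300
    g <- rep(0:1, each = n / 2)
    rate <- 6.7e-4 * true_hr^g
    t_event <- rexp(n, rate)
    t_cens <- runif(n, 27, 93)
    km <- km_compare(pmin(t_event, t_cens), as.integer(t_event <= t_cens),
                     factor(g, levels = 0:1, labels = c("low", "high")))
    log(km$hr)
  })
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(true_hr)), 4 * se_mean + 0.05)
})

test_that("the published linear predictor is a plain dot product", {
  f <- data.frame(ttv_cm3 = 10, het_A_pct = 20, ttp_min = 2, npi = 4.4)
  expect_equal(apply_published_model(f),
               0.01 * 10 - 0.05 * 20 + 0.61 * 2 + 0.70 * 4.4)
  expect_equal(apply_published_model(
    data.frame(ttv_cm3 = 0, het_A_pct = 0, ttp_min = 0, npi = 0)), 0)
  expect_error(apply_published_model(data.frame(ttv_cm3 = 1)), "het_A_pct")
})

test_that("stratification errors when one risk group would be empty", {
  expect_error(stratify_cohort(rep(1, 10), rexp(10) + 1, rbinom(10, 1, 0.5)),
               "both outcome classes|empty")
})
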