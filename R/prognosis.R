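# Prognostic modelling: NPI, Cox screening and backward selection,
# concordance, Youden cutoff and Kaplan-Meier group comparison.

#' Nottingham Prognostic Index
#'
#' \eqn{NPI = 0.2 S + N + G}, where S is the index-lesion diameter in cm,
#' N the nodal score (0 positive nodes = 1; 1-4 nodes = 2; more than 4
#' nodes = 3) and G the histological grade (1-3). Vectorized.
#'
#' @param size_cm tumor diameter in cm, positive.
#' @param n_positive_nodes count of positive loco-regional lymph nodes.
#' @param grade histological grade, 1, 2 or 3.
#' @return data.frame with \code{size_cm}, \code{n_positive_nodes},
#'   \code{node_points}, \code{grade}, raw \code{npi} and \code{npi_1dp}
#'   (rounded to one decimal, the conventional reporting precision).
#' @examples
#' compute_npi(5.8, 5, 2)  # npi_1dp = 6.2
#' @export
compute_npi <- function(size_cm, n_positive_nodes, grade) {
  if (any(size_cm <= 0)) stop("`size_cm` must be positive", call. = FALSE)
  if (any(n_positive_nodes < 0 | n_positive_nodes != round(n_positive_nodes))) {
    stop("`n_positive_nodes` must be a nonnegative integer count", call. = FALSE)
  }
  if (!all(grade %in% 1:3)) {
    stop("`grade` must be 1, 2 or 3 (got ",
         paste(unique(grade[!grade %in% 1:3]), collapse = ", "), ")",
         call. = FALSE)
  }
  node_points <- 1L + (n_positive_nodes >= 1) + (n_positive_nodes > 4)
  npi <- 0.2 * size_cm + node_points + grade
  data.frame(size_cm = size_cm, n_positive_nodes = n_positive_nodes,
             node_points = node_points, grade = grade,
             npi = npi, npi_1dp = round(npi, 1))
}

cox_surv <- function(cohort) {
  survival::Surv(cohort$time_months, cohort$event)
}

# Likelihood-ratio p-value of a fitted coxph model against the null model.
cox_lrt_p <- function(fit) {
  lrt <- 2 * (fit$loglik[2] - fit$loglik[1])
  stats::pchisq(lrt, df = sum(!is.na(stats::coef(fit))), lower.tail = FALSE)
}

#' Univariate Cox screening of candidate features
#'
#' Fits one Cox model per candidate (Efron ties) and retains features whose
#' likelihood-ratio P falls below \code{alpha}. The default alpha of 0.007 is
#' a Bonferroni correction of a 10\% error level over 14 candidate features.
#' Features whose fit fails to converge are dropped with a warning.
#'
#' @param cohort data.frame with \code{time_months}, \code{event} and the
#'   candidate columns; at least 2 events.
#' @param candidate_features character vector of column names.
#' @param alpha retention threshold on the likelihood-ratio P-value.
#' @return A list with \code{eligible} (character vector of retained
#'   features) and \code{table} (per-feature coef, HR, and LRT P).
#' @export
univariate_screen <- function(cohort, candidate_features, alpha = 0.007) {
  if (sum(cohort$event) < 2) stop("need at least 2 events to screen", call. = FALSE)
  rows <- lapply(candidate_features, function(f) {
    fit <- tryCatch(
      survival::coxph(stats::as.formula(paste("cox_surv(cohort) ~", f)),
                      data = cohort, ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      warning("univariate fit for '", f, "' did not converge; feature dropped",
              call. = FALSE)
      return(data.frame(feature = f, coef = NA_real_, hr = NA_real_,
                        p = NA_real_))
    }
    data.frame(feature = f, coef = unname(stats::coef(fit)),
               hr = unname(exp(stats::coef(fit))), p = cox_lrt_p(fit))
  })
  tab <- do.call(rbind, rows)
  list(eligible = tab$feature[!is.na(tab$p) & tab$p < alpha], table = tab)
}

#' Multivariable Cox model with backward feature selection
#'
#' Starts from the full model over \code{covariates} and iteratively removes
#' the least significant covariate whose drop-one likelihood-ratio P is at or
#' above \code{p_remove}, until all remaining covariates are significant (or
#' none remain). \code{p_enter} is kept for interface parity with stepwise
#' procedures; pure backward elimination never re-enters a covariate. Ties in
#' event times use the Efron approximation.
#'
#' @param cohort data.frame with \code{time_months}, \code{event} and the
#'   covariate columns.
#' @param covariates nonempty character vector of starting covariates.
#' @param p_enter entry threshold (unused by pure backward elimination).
#' @param p_remove removal threshold on the drop-one likelihood-ratio P.
#' @return A list of class \code{"cox_model"}: \code{covariates},
#'   \code{coefficients}, \code{se}, \code{hr}, \code{ci_lower},
#'   \code{ci_upper} (Wald 95\%), \code{p} (drop-one LRT), \code{chi_squared}
#'   (model LRT vs null), \code{loglik}, \code{linear_predictors} (centered,
#'   one per subject) and the underlying \code{fit}.
#' @export
fit_cox_backward <- function(cohort, covariates, p_enter = 0.001, p_remove = 0.05) {
  if (length(covariates) == 0) stop("`covariates` must be nonempty", call. = FALSE)
  if (sum(cohort$event) < length(covariates)) {
    stop("fewer events than covariates; model (",
         paste(covariates, collapse = ", "), ") is not identifiable",
         call. = FALSE)
  }
  current <- covariates
  fit_set <- function(set) {
    rhs <- if (length(set)) paste(set, collapse = " + ") else "1"
    fit <- tryCatch(
      survival::coxph(stats::as.formula(paste("cox_surv(cohort) ~", rhs)),
                      data = cohort, ties = "efron"),
      error = function(e) stop("Cox fit failed for covariate set (",
                               paste(set, collapse = ", "), "): ",
                               conditionMessage(e), call. = FALSE)
    )
    if (length(set) && anyNA(stats::coef(fit))) {
      stop("Cox fit did not converge (possible separation) for covariate set (",
           paste(set, collapse = ", "), ")", call. = FALSE)
    }
    fit
  }
  fit <- fit_set(current)
  repeat {
    if (length(current) == 0) break
    drop_p <- vapply(current, function(v) {
      reduced <- fit_set(setdiff(current, v))
      ll_red <- if (length(current) == 1) reduced$loglik[1] else reduced$loglik[2]
      stats::pchisq(2 * (fit$loglik[2] - ll_red), df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(drop_p)
    if (drop_p[worst] < p_remove) break
    current <- current[-worst]
    fit <- fit_set(current)
  }
  if (length(current) == 0) {
    warning("backward selection removed every covariate; returning the null model",
            call. = FALSE)
    return(structure(
      list(covariates = character(0), coefficients = numeric(0),
           se = numeric(0), hr = numeric(0), ci_lower = numeric(0),
           ci_upper = numeric(0), p = numeric(0), chi_squared = 0,
           loglik = fit$loglik[1],
           linear_predictors = rep(0, nrow(cohort)), fit = NULL),
      class = "cox_model"))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  drop_p <- vapply(current, function(v) {
    reduced <- fit_set(setdiff(current, v))
    ll_red <- if (length(current) == 1) reduced$loglik[1] else reduced$loglik[2]
    stats::pchisq(2 * (fit$loglik[2] - ll_red), df = 1, lower.tail = FALSE)
  }, numeric(1))
  structure(
    list(covariates = current,
         coefficients = beta,
         se = se,
         hr = exp(beta),
         ci_lower = exp(beta - stats::qnorm(0.975) * se),
         ci_upper = exp(beta + stats::qnorm(0.975) * se),
         p = drop_p,
         chi_squared = 2 * (fit$loglik[2] - fit$loglik[1]),
         loglik = fit$loglik[2],
         linear_predictors = unname(fit$linear.predictors),
         fit = fit),
    class = "cox_model"
  )
}

#' @export
print.cox_model <- function(x, ...) {
  cat("Cox proportional-hazards model (backward-selected)\n")
  if (length(x$covariates) == 0) {
    cat("  (null model: no covariates retained)\n")
    return(invisible(x))
  }
  tab <- data.frame(HR = round(x$hr, 2),
                    CI = sprintf("%.2f to %.2f", x$ci_lower, x$ci_upper),
                    P = signif(x$p, 2),
                    Coefficient = round(x$coefficients, 2),
                    SE = round(x$se, 2))
  rownames(tab) <- x$covariates
  print(tab)
  cat(sprintf("  Model chi-squared: %.1f\n", x$chi_squared))
  invisible(x)
}

#' Harrell's concordance index for censored survival data
#'
#' The fraction of usable subject pairs in which the subject with the higher
#' risk score dies earlier. A pair is usable when the ordering of its
#' survival times is determinable under right censoring: the earlier time is
#' an event (including a tied pair of one event and one censored subject, the
#' event taken as earlier). Tied risk scores count one half; pairs of tied
#' event times are not usable. Implemented as a vectorized enumeration of all
#' ordered pairs, O(n^2) time and memory.
#'
#' @param linear_predictors numeric risk scores (higher = worse prognosis).
#' @param times follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return Concordance in \code{[0, 1]}.
#' @export
harrells_c <- function(linear_predictors, times, events) {
  n <- length(linear_predictors)
  stopifnot(length(times) == n, length(events) == n)
  if (anyNA(linear_predictors) || anyNA(times) || anyNA(events)) {
    stop("inputs to harrells_c must not contain missing values", call. = FALSE)
  }
  ti <- matrix(times, n, n)            # [i, j] = times[i]
  tj <- t(ti)
  ei <- matrix(events == 1, n, n)
  ej <- t(ei)
  # ordered pair (i, j): i is the determinably earlier death
  earlier <- (ti < tj & ei) | (ti == tj & ei & !ej)
  diag(earlier) <- FALSE
  usable <- sum(earlier)
  if (usable == 0) stop("no usable pairs under the censoring pattern", call. = FALSE)
  li <- matrix(linear_predictors, n, n)
  lj <- t(li)
  concordant <- sum(earlier & li > lj)
  tied <- sum(earlier & li == lj)
  (concordant + 0.5 * tied) / usable
}

#' Youden-optimal cutoff on a risk score
#'
#' Scans every observed score value as a candidate cutoff (predicted positive
#' when score >= cutoff) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1 against the outcome labels; the smallest
#' cutoff wins ties. By default the labels are the observed event indicators
#' over follow-up. With \code{horizon} set, labels are instead defined at a
#' fixed horizon: events before the horizon are positive, subjects followed
#' beyond it negative, and subjects censored before it are excluded.
#'
#' @param linear_predictors numeric risk scores.
#' @param events event indicators.
#' @param times follow-up times; required when \code{horizon} is given.
#' @param horizon optional horizon in the time unit of \code{times}.
#' @return A list with \code{cutoff}, \code{J}, \code{sensitivity},
#'   \code{specificity} and \code{n_used}.
#' @export
youden_cutoff <- function(linear_predictors, events, times = NULL, horizon = NULL) {
  lp <- linear_predictors
  lab <- events
  if (!is.null(horizon)) {
    if (is.null(times)) stop("`times` required for a fixed-horizon cutoff", call. = FALSE)
    usable <- events == 1 & times <= horizon | times > horizon
    lp <- lp[usable]
    lab <- as.integer(events[usable] == 1 & times[usable] <= horizon)
  }
  if (length(unique(lab)) < 2) {
    stop("both outcome classes must be present to optimize a cutoff", call. = FALSE)
  }
  cand <- sort(unique(lp))
  pos <- lp[lab == 1]
  neg <- lp[lab == 0]
  sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  J <- sens + spec - 1
  best <- which(J == max(J))[1]  # candidates sorted ascending: smallest tie wins
  list(cutoff = cand[best], J = J[best], sensitivity = sens[best],
       specificity = spec[best], n_used = length(lp))
}

#' Kaplan-Meier comparison of two predicted risk groups
#'
#' Estimates a Kaplan-Meier curve per group, tests the difference with the
#' logrank test, and reports the between-group hazard ratio from a
#' one-covariate Cox model on the group indicator with its Wald 95\% CI.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param predicted_group two-level factor (or coercible); the second level
#'   is the high-risk group whose hazard ratio is reported.
#' @return A list of class \code{"km_comparison"}: \code{curves} (data.frame
#'   of \code{group}, \code{time}, \code{survival}, \code{n_risk}),
#'   \code{logrank_p}, \code{logrank_chisq}, \code{hr}, \code{ci_lower},
#'   \code{ci_upper} and \code{group_sizes}.
#' @export
km_compare <- function(times, events, predicted_group) {
  g <- factor(predicted_group)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("`predicted_group` must contain two nonempty groups", call. = FALSE)
  }
  d <- data.frame(time = times, event = events, group = g)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  ss <- summary(sf, censored = TRUE)
  curves <- data.frame(group = sub("^group=", "", as.character(ss$strata)),
                       time = ss$time, survival = ss$surv, n_risk = ss$n.risk)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = d,
                        ties = "efron")
  beta <- unname(stats::coef(cx))
  se <- sqrt(diag(stats::vcov(cx)))[1]
  structure(
    list(curves = curves,
         logrank_p = logrank_p,
         logrank_chisq = sd$chisq,
         hr = exp(beta),
         ci_lower = exp(beta - stats::qnorm(0.975) * se),
         ci_upper = exp(beta + stats::qnorm(0.975) * se),
         group_sizes = table(g)),
    class = "km_comparison"
  )
}

#' Stratify a cohort at the Youden-optimal cutoff and compare the groups
#'
#' Convenience wrapper: finds the Youden cutoff on the risk scores, splits
#' the cohort into low/high groups and runs \code{\link{km_compare}}.
#'
#' @inheritParams youden_cutoff
#' @param times follow-up times.
#' @return A list of class \code{"stratification_result"}: \code{cutoff},
#'   \code{J}, \code{groups} (factor low/high), and the
#'   \code{\link{km_compare}} fields.
#' @export
stratify_cohort <- function(linear_predictors, times, events, horizon = NULL) {
  yc <- youden_cutoff(linear_predictors, events, times = times, horizon = horizon)
  groups <- factor(ifelse(linear_predictors >= yc$cutoff, "high", "low"),
                   levels = c("low", "high"))
  if (any(table(groups) == 0)) {
    stop("Youden cutoff leaves one risk group empty; cannot stratify", call. = FALSE)
  }
  km <- km_compare(times, events, groups)
  structure(c(list(cutoff = yc$cutoff, J = yc$J, groups = groups), unclass(km)),
            class = "stratification_result")
}

#' Linear predictor of the published four-covariate model
#'
#' Dot product of the published coefficients with the covariate columns
#' (\code{ttv_cm3}, \code{het_A_pct}, \code{ttp_min}, \code{npi}).
#'
#' @param features data.frame (or named list) holding the four covariates.
#' @param coefficients named coefficient vector; default
#'   \code{\link{published_coefficients}}.
#' @return Numeric linear predictor, one per row.
#' @export
apply_published_model <- function(features, coefficients = published_coefficients()) {
  missing <- setdiff(names(coefficients), names(features))
  if (length(missing)) {
    stop("missing covariate(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(features)[names(coefficients)])
  drop(X %*% coefficients)
}
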