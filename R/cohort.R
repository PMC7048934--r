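# Synthetic survival cohorts drawn from a known proportional-hazards model.

#' Published multivariable model coefficients
#'
#' Log hazard ratios of the four covariates retained in the compound
#' NPI + vascularization prognostic model: total enhancing tumor volume
#' (per cm^3), heterogeneity category A percentage (weak wash-in, persistent),
#' time to peak enhancement (per minute) and the Nottingham Prognostic Index
#' (per unit).
#'
#' @return Named numeric vector of coefficients.
#' @export
published_coefficients <- function() {
  c(ttv_cm3 = 0.01, het_A_pct = -0.05, ttp_min = 0.61, npi = 0.70)
}

#' Default covariate distributions for simulated cohorts
#'
#' A plausible cross-section of a primary breast-cancer cohort: a heavy-tailed
#' lognormal enhancing tumor volume (median 3.2 cm^3, mean ~9, SD ~25), a
#' truncated-normal category-A heterogeneity percentage (mean 29\%, SD 14,
#' within 0..100), a right-skewed discrete time-to-peak on 1..7 minutes
#' (mean ~1.5 min, most tumors peaking in the first minute), and a
#' truncated-normal NPI (mean 4.4, SD 1.1, within its 2.2..7.4 range). These
#' are configuration, not estimates.
#'
#' @return Named list of distribution descriptors, one per covariate.
#' @export
default_covariate_model <- function() {
  list(
    ttv_cm3 = list(dist = "lognormal", meanlog = log(3.2), sdlog = 1.45),
    het_A_pct = list(dist = "truncnorm", mean = 29, sd = 14, lower = 0, upper = 100),
    ttp_min = list(dist = "discrete", values = 1:7,
                   prob = c(0.70, 0.20, 0.05, 0.02, 0.01, 0.01, 0.01)),
    npi = list(dist = "truncnorm", mean = 4.4, sd = 1.1, lower = 2.2, upper = 7.4)
  )
}

covariate_model_mean <- function(m) {
  switch(m$dist,
    lognormal = exp(m$meanlog + m$sdlog^2 / 2),
    truncnorm = {
      a <- (m$lower - m$mean) / m$sd
      b <- (m$upper - m$mean) / m$sd
      m$mean + m$sd * (stats::dnorm(a) - stats::dnorm(b)) /
        (stats::pnorm(b) - stats::pnorm(a))
    },
    discrete = sum(m$values * m$prob),
    stop("unknown covariate distribution: ", m$dist, call. = FALSE)
  )
}

draw_covariate <- function(n, m) {
  switch(m$dist,
    lognormal = stats::rlnorm(n, m$meanlog, m$sdlog),
    truncnorm = rtruncnorm(n, m$mean, m$sd, m$lower, m$upper),
    discrete = sample(m$values, n, replace = TRUE, prob = m$prob),
    stop("unknown covariate distribution: ", m$dist, call. = FALSE)
  )
}

#' Specification of a simulated survival cohort
#'
#' Event times follow an exponential baseline hazard scaled by
#' \eqn{\exp(\beta' (x - \mu))}, where \eqn{\mu} are the covariate-model
#' means (centering keeps \code{baseline_hazard} interpretable as the hazard
#' of an average subject). Administrative censoring is uniform on
#' \code{admin_censor_months}. The default baseline hazard of 1.13e-3 per
#' month yields roughly an 11\% event fraction under the default covariate
#' model and the 27-93 month censoring window, the censoring regime the
#' pipeline is designed for.
#'
#' @param n_subjects number of subjects (at least 2).
#' @param coefficients named log-hazard-ratio vector; names must match
#'   \code{covariate_model}. Default \code{\link{published_coefficients}}.
#' @param baseline_hazard exponential event rate per month for an average
#'   subject; positive.
#' @param admin_censor_months censoring window \code{c(min, max)} in months.
#' @param covariate_model list of distribution descriptors (see
#'   \code{\link{default_covariate_model}}).
#' @param seed integer seed.
#' @return A list of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects = 314,
                        coefficients = published_coefficients(),
                        baseline_hazard = 1.13e-3,
                        admin_censor_months = c(27, 93),
                        covariate_model = default_covariate_model(),
                        seed = 1L) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2", call. = FALSE)
  if (any(!is.finite(coefficients))) {
    stop("non-finite coefficient for: ",
         paste(names(coefficients)[!is.finite(coefficients)], collapse = ", "),
         call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("`baseline_hazard` must be positive", call. = FALSE)
  if (length(admin_censor_months) != 2L ||
      admin_censor_months[1] > admin_censor_months[2] ||
      admin_censor_months[1] <= 0) {
    stop("`admin_censor_months` must be a positive (min, max) window", call. = FALSE)
  }
  if (!all(names(coefficients) %in% names(covariate_model))) {
    stop("every coefficient needs a covariate_model entry", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         coefficients = coefficients,
         baseline_hazard = baseline_hazard,
         admin_censor_months = admin_censor_months,
         covariate_model = covariate_model,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a survival cohort from a proportional-hazards model
#'
#' Draws covariates from the configured distributions, computes each
#' subject's linear predictor, draws an exponential event time at hazard
#' \code{baseline_hazard * exp(lp - lp_ref)} (with \code{lp_ref} the linear
#' predictor of the covariate means) and censors uniformly on the
#' administrative window. Identical seeds give identical cohorts.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A list with \code{table}: data.frame of \code{id}, one column per
#'   covariate, \code{time_months}, \code{event}; and \code{truth}:
#'   \code{linear_predictor} (centered), \code{event_time},
#'   \code{censor_time}, and the \code{spec}.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  covs <- names(spec$coefficients)
  with_seed(spec$seed, {
    X <- vapply(covs, function(nm) {
      draw_covariate(spec$n_subjects, spec$covariate_model[[nm]])
    }, numeric(spec$n_subjects))
    X <- matrix(X, nrow = spec$n_subjects, dimnames = list(NULL, covs))
    mu <- vapply(covs, function(nm) covariate_model_mean(spec$covariate_model[[nm]]),
                 numeric(1))
    lp <- drop(X %*% spec$coefficients)
    lp_c <- lp - sum(spec$coefficients * mu)
    rate <- spec$baseline_hazard * exp(lp_c)
    t_event <- stats::rexp(spec$n_subjects, rate)
    t_censor <- stats::runif(spec$n_subjects,
                             spec$admin_censor_months[1],
                             spec$admin_censor_months[2])
    tab <- data.frame(id = seq_len(spec$n_subjects), X,
                      time_months = pmin(t_event, t_censor),
                      event = as.integer(t_event <= t_censor))
    list(table = tab,
         truth = list(linear_predictor = lp_c,
                      event_time = t_event,
                      censor_time = t_censor,
                      spec = spec))
  })
}
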