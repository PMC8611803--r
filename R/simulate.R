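#' Simulation configuration for the registry-style data generator
#'
#' Defines the data-generating mechanism for a three-cause competing-risks
#' cohort modelled on a cord-blood transplant registry: cause 1 is acute
#' graft-versus-host disease (aGvHD), cause 2 graft failure before aGvHD,
#' cause 3 death before aGvHD. Event times are drawn from per-cause
#' log-normal distributions via inverse-transform sampling and rounded up
#' to whole days; follow-up is administratively censored at a fixed horizon.
#'
#' @param n_subjects Number of subjects per dataset.
#' @param n_reps Number of Monte-Carlo replicates (used by the study harness).
#' @param event_probs Probability of causes 1..3; must sum to 1.
#' @param lognormal_mu Per-cause location parameters on the log-day scale.
#' @param lognormal_sigma Per-cause scale parameters on the log-day scale;
#'   all must be positive.
#' @param admin_censor_day Administrative censoring horizon in days.
#' @param aux_prob Bernoulli probability of the binary auxiliary covariate
#'   (double versus single cord-blood unit).
#' @param bounds Half-open interval `(left, right]`, in days, assigned as the
#'   censoring interval of records whose event time is set missing.
#' @return An object of class `sim_config` (a validated list of the above).
#' @examples
#' cfg <- sim_config()
#' cfg$event_probs
#' @export
sim_config <- function(n_subjects = 500L,
                       n_reps = 1000L,
                       event_probs = c(0.65, 0.25, 0.10),
                       lognormal_mu = log(c(26, 43, 77)),
                       lognormal_sigma = log(c(2, 2, 4)),
                       admin_censor_day = 365,
                       aux_prob = 0.45,
                       bounds = c(0, 100)) {
  stopifnot(length(event_probs) == 3L, length(lognormal_mu) == 3L,
            length(lognormal_sigma) == 3L, length(bounds) == 2L)
  if (abs(sum(event_probs) - 1) > 1e-8)
    stop("event_probs must sum to 1", call. = FALSE)
  if (any(event_probs < 0))
    stop("event_probs must be non-negative", call. = FALSE)
  if (any(lognormal_sigma <= 0))
    stop("all lognormal_sigma must be > 0", call. = FALSE)
  if (!(bounds[1] >= 0 && bounds[1] < bounds[2] &&
        bounds[2] <= admin_censor_day))
    stop("bounds must satisfy 0 <= left < right <= admin_censor_day",
         call. = FALSE)
  if (n_subjects < 1L || n_reps < 1L)
    stop("n_subjects and n_reps must be positive", call. = FALSE)
  if (aux_prob < 0 || aux_prob > 1)
    stop("aux_prob must be in [0, 1]", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_reps = as.integer(n_reps),
                 event_probs = as.numeric(event_probs),
                 lognormal_mu = as.numeric(lognormal_mu),
                 lognormal_sigma = as.numeric(lognormal_sigma),
                 admin_censor_day = as.numeric(admin_censor_day),
                 aux_prob = as.numeric(aux_prob),
                 bounds = as.numeric(bounds)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Competing-risks simulation configuration\n")
  cat(sprintf("  subjects per dataset : %d   replicates: %d\n",
              x$n_subjects, x$n_reps))
  cat(sprintf("  cause probabilities  : %s\n",
              paste(format(x$event_probs), collapse = ", ")))
  cat(sprintf("  log-normal mu        : %s\n",
              paste(format(round(x$lognormal_mu, 4)), collapse = ", ")))
  cat(sprintf("  log-normal sigma     : %s\n",
              paste(format(round(x$lognormal_sigma, 4)), collapse = ", ")))
  cat(sprintf("  censoring horizon    : day %g\n", x$admin_censor_day))
  cat(sprintf("  aux covariate P(=1)  : %g\n", x$aux_prob))
  cat(sprintf("  missing-time bounds  : (%g, %g]\n",
              x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Draw event types from the cause distribution
#'
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Integer vector of cause codes in `{1, 2, 3}`.
#' @export
draw_event_type <- function(n, config = sim_config()) {
  sample.int(3L, n, replace = TRUE, prob = config$event_probs)
}

#' Map uniform draws to event days by inverse-transform sampling
#'
#' Returns the `u`-quantile of the cause-specific log-normal distribution,
#' rounded up to the next whole day:
#' `ceil(exp(mu_cause + sigma_cause * qnorm(u)))`.
#'
#' @param cause Integer cause codes (vectorised, recycled against `u`).
#' @param u Uniform(0,1) draws; values of exactly 0 or 1 are rejected.
#' @param config A [sim_config()].
#' @return Positive integer days.
#' @export
inverse_transform_time <- function(cause, u, config = sim_config()) {
  if (any(u <= 0 | u >= 1))
    stop("u must lie strictly inside (0, 1)", call. = FALSE)
  mu <- config$lognormal_mu[cause]
  sg <- config$lognormal_sigma[cause]
  # round at 1e-9 first so exact quantiles (e.g. exp(log 26)) are not
  # pushed up a day by floating-point noise
  ceiling(round(exp(mu + sg * stats::qnorm(u)), 9))
}

#' Generate one complete competing-risks dataset
#'
#' Each subject receives a cause via [draw_event_type()] and a day via
#' [inverse_transform_time()]; times beyond the administrative horizon are
#' replaced by a censored record (`event = 0`) at the horizon. The auxiliary
#' covariate is drawn i.i.d. Bernoulli and is independent of everything else.
#'
#' @param config A [sim_config()].
#' @return A `crd_data` data frame with columns `id`, `time`, `event`
#'   (0 = censored, 1 = aGvHD, 2 = graft failure, 3 = death), `aux`,
#'   `time_missing`, `interval_left`, `interval_right`, `true_time`.
#'   No missingness is applied; see [apply_mdm()].
#' @examples
#' set.seed(1)
#' d <- generate_dataset(sim_config(n_subjects = 20))
#' table(d$event)
#' @export
generate_dataset <- function(config = sim_config()) {
  n <- config$n_subjects
  cause <- draw_event_type(n, config)
  u <- stats::runif(n)
  tm <- inverse_transform_time(cause, u, config)
  event <- cause
  cens <- tm > config$admin_censor_day
  tm[cens] <- config$admin_censor_day
  event[cens] <- 0L
  aux <- stats::rbinom(n, 1L, config$aux_prob)
  out <- data.frame(id = seq_len(n),
                    time = as.numeric(tm),
                    event = as.integer(event),
                    aux = as.integer(aux),
                    time_missing = FALSE,
                    interval_left = NA_real_,
                    interval_right = NA_real_,
                    true_time = as.numeric(tm))
  class(out) <- c("crd_data", "data.frame")
  attr(out, "config") <- config
  out
}

#' Missing-data mechanism specification
#'
#' @param mechanism `"MCAR"`, `"MAR"` or `"MNAR"`.
#' @param fraction Missingness fraction, strictly inside (0, 1).
#' @param mnar_direction For MNAR: flag the `"smallest"` (default) or
#'   `"largest"` cause-1 times. The latter is the sensitivity variant that
#'   reverses the direction of the not-at-random selection.
#' @return An object of class `mdm_spec`.
#' @export
mdm_spec <- function(mechanism = c("MCAR", "MAR", "MNAR"),
                     fraction = 0.3,
                     mnar_direction = c("smallest", "largest")) {
  mechanism <- match.arg(mechanism)
  mnar_direction <- match.arg(mnar_direction)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(mechanism = mechanism, fraction = fraction,
                 mnar_direction = mnar_direction),
            class = "mdm_spec")
}

#' Apply a missing-data mechanism to a complete dataset
#'
#' Flags event times as missing and attaches the censoring interval from the
#' generating configuration. Mechanisms:
#' \describe{
#'   \item{MCAR}{every record, regardless of event type, is flagged
#'     independently with probability `fraction`;}
#'   \item{MAR}{records with `event == 1` (aGvHD) are flagged independently
#'     with probability `fraction`; no other record is ever flagged
#'     (missingness depends on the event type only);}
#'   \item{MNAR}{the `floor(fraction * n1)` smallest (or largest) of the `n1`
#'     observed aGvHD times are flagged, deterministically given the data;
#'     ties are broken by subject id.}
#' }
#' Flagged records have `time` set to `NA` and keep the generated value in
#' `true_time`, which downstream estimators and imputers never read.
#'
#' @param dataset A `crd_data` dataset without existing missingness.
#' @param spec An [mdm_spec()].
#' @return The dataset with `time_missing`, `interval_left`, `interval_right`
#'   populated and `time` blanked for flagged rows.
#' @export
apply_mdm <- function(dataset, spec) {
  stopifnot(inherits(spec, "mdm_spec"))
  if (any(dataset$time_missing))
    stop("dataset already contains missing times", call. = FALSE)
  config <- attr(dataset, "config")
  if (is.null(config)) config <- sim_config()
  n <- nrow(dataset)
  flag <- logical(n)
  if (spec$mechanism == "MCAR") {
    flag <- stats::runif(n) < spec$fraction
  } else if (spec$mechanism == "MAR") {
    is1 <- dataset$event == 1L
    flag[is1] <- stats::runif(sum(is1)) < spec$fraction
  } else {
    idx1 <- which(dataset$event == 1L)
    k <- floor(spec$fraction * length(idx1))
    if (k < 1) {
      warning("MNAR: fraction * count < 1, no records flagged")
    } else {
      sgn <- if (spec$mnar_direction == "largest") -1 else 1
      o <- order(sgn * dataset$time[idx1], dataset$id[idx1])
      flag[idx1[o[seq_len(k)]]] <- TRUE
    }
  }
  dataset$time_missing <- flag
  dataset$interval_left[flag] <- config$bounds[1]
  dataset$interval_right[flag] <- config$bounds[2]
  dataset$time[flag] <- NA_real_
  attr(dataset, "mdm") <- spec
  dataset
}

#' Analytic true values of the estimands under the generating mechanism
#'
#' The marginal cause-1 cumulative incidence implied by the generator is the
#' closed-form mixture `CIF_1(t) = p_1 * pnorm((log t - mu_1) / sigma_1)`.
#' The true median is the time at which this reaches 0.5: either the
#' smallest integer day (matching the ceiling rounding of generated times,
#' the default) or the continuous root of the mixture CDF.
#'
#' @param config A [sim_config()].
#' @param horizon Day at which the true cumulative incidence is evaluated.
#' @param median_convention `"ceiling"` (smallest integer day with
#'   `CIF_1 >= 0.5`) or `"continuous"` (exact root of `CIF_1(t) = 0.5`).
#' @return List with `cif` (proportion at `horizon`) and `median` (days;
#'   `NA` when the cause-1 probability never reaches 0.5).
#' @examples
#' true_estimands()           # cif ~ 0.6331, median 44
#' @export
true_estimands <- function(config = sim_config(), horizon = 100,
                           median_convention = c("ceiling", "continuous")) {
  median_convention <- match.arg(median_convention)
  if (horizon > config$admin_censor_day)
    stop("horizon must not exceed the censoring day", call. = FALSE)
  p1 <- config$event_probs[1]
  mu1 <- config$lognormal_mu[1]
  s1 <- config$lognormal_sigma[1]
  cif <- p1 * stats::pnorm((log(horizon) - mu1) / s1)
  if (p1 < 0.5) {
    med <- NA_real_
  } else {
    root <- exp(mu1 + s1 * stats::qnorm(0.5 / p1))
    med <- if (median_convention == "continuous") root else ceiling(root)
  }
  list(cif = cif, median = med)
}

#' @export
print.crd_data <- function(x, ...) {
  cat(sprintf("Competing-risks dataset: %d subjects\n", nrow(x)))
  tab <- table(factor(x$event, levels = 0:3,
                      labels = c("censored", "aGvHD", "graft failure",
                                 "death")))
  cat("  events:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  nm <- sum(x$time_missing)
  if (nm > 0)
    cat(sprintf("  missing times: %d, bounded in (%g, %g]\n", nm,
                x$interval_left[x$time_missing][1],
                x$interval_right[x$time_missing][1]))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
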