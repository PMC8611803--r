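#' Aalen-Johansen estimator of a cause-specific cumulative incidence
#'
#' Non-parametric product-limit estimator for competing-risks data. At each
#' distinct event time \eqn{t_j} with \eqn{n_j} subjects at risk, \eqn{d_j}
#' events of any cause and \eqn{d_{kj}} events of the cause of interest,
#' \deqn{\hat F_k(t) = \sum_{t_j \le t} \hat S(t_{j-1}) \, d_{kj} / n_j,}
#' where \eqn{\hat S} is the all-cause Kaplan-Meier estimate of remaining
#' event-free. All events at a tied time are aggregated before the risk set
#' is updated, and subjects censored at \eqn{t_j} leave the risk set after
#' the events at \eqn{t_j}.
#'
#' Pointwise standard errors use the Greenwood-style (Marubini-Valsecchi)
#' variance for the cumulative incidence,
#' \deqn{\widehat{Var}\{\hat F_k(t)\} =
#'   \sum_{t_j \le t} [\hat F_k(t)-\hat F_k(t_j)]^2
#'       \frac{d_j}{n_j(n_j-d_j)}
#'   + \sum_{t_j \le t} \hat S(t_{j-1})^2 \frac{n_j-d_{kj}}{n_j}
#'       \frac{d_{kj}}{n_j^2}
#'   - 2 \sum_{t_j \le t} [\hat F_k(t)-\hat F_k(t_j)]
#'       \hat S(t_{j-1}) \frac{d_{kj}}{n_j^2},}
#' the estimator used by standard multistate software. With a single cause
#' and no censoring it collapses to the binomial Greenwood variance of
#' \eqn{1 - \hat S}.
#'
#' @param data A `crd_data` data frame (or any data frame with `time` and
#'   `event` columns; `event == 0` is censoring). Records with missing times
#'   are not allowed: filter with [complete_case_filter()] or impute first.
#' @param cause Cause code of interest (default 1, aGvHD).
#' @return An object of class `aj_cif`: list with `time` (sorted distinct
#'   event times of any cause), `est`, `se` (both evaluated at those times),
#'   `surv` (all-cause Kaplan-Meier just after each time), `n_risk`,
#'   `n_event` (cause-specific), `n_event_all`, and `n` (sample size).
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 2, 0, 1))
#' f <- cuminc_aj(d, cause = 1)
#' cif_at(f, 3.5)   # 0.25
#' @export
cuminc_aj <- function(data, cause = 1L) {
  time <- data$time
  event <- data$event
  if (length(time) == 0L) stop("empty dataset", call. = FALSE)
  if (anyNA(time))
    stop("missing event times: filter or impute before estimation",
         call. = FALSE)
  o <- order(time)
  time <- time[o]
  event <- as.integer(event[o])
  n <- length(time)

  ut <- unique(time)
  grp <- findInterval(time, ut)      # time is sorted, so this is the run id
  nt <- length(ut)
  cnt <- tabulate(grp, nt)                       # leaving risk set at ut
  d_all <- tabulate(grp[event != 0L], nt)        # events of any cause
  d_k <- tabulate(grp[event == cause], nt)       # events of this cause
  n_risk <- n - c(0, cumsum(cnt))[seq_len(nt)]

  keep <- d_all > 0L                             # jump grid: event times only
  ut <- ut[keep]; d_all <- d_all[keep]; d_k <- d_k[keep]
  n_risk <- n_risk[keep]
  nj <- length(ut)
  if (nj == 0L) {
    out <- list(time = numeric(0), est = numeric(0), se = numeric(0),
                surv = numeric(0), n_risk = integer(0),
                n_event = integer(0), n_event_all = integer(0),
                n = n, cause = cause)
    class(out) <- "aj_cif"
    return(out)
  }

  surv <- cumprod(1 - d_all / n_risk)            # S(t_j)
  s_prev <- c(1, surv[-nj])                      # S(t_{j-1})
  est <- cumsum(s_prev * d_k / n_risk)           # F_k(t_j)

  # variance via cumulative-sum expansion of the three-term formula
  a <- d_all / (n_risk * (n_risk - d_all))
  dead_end <- n_risk == d_all
  if (any(dead_end)) {
    a[dead_end] <- 0    # [F(t)-F(t_j)] = 0 beyond total failure anyway
    if (any(which(dead_end) < nj))
      warning("risk set exhausted before the last event time; ",
              "SE carried forward")
  }
  b <- s_prev^2 * ((n_risk - d_k) / n_risk) * d_k / n_risk^2
  cc <- s_prev * d_k / n_risk^2
  A <- cumsum(a);  AF <- cumsum(a * est);  AF2 <- cumsum(a * est^2)
  B <- cumsum(b);  C <- cumsum(cc);        CF <- cumsum(cc * est)
  v <- est^2 * A - 2 * est * AF + AF2 + B - 2 * (est * C - CF)
  v[v < 0] <- 0                                   # guard rounding noise
  out <- list(time = ut, est = est, se = sqrt(v), surv = surv,
              n_risk = as.integer(n_risk), n_event = as.integer(d_k),
              n_event_all = as.integer(d_all), n = n, cause = cause)
  class(out) <- "aj_cif"
  out
}

#' @export
print.aj_cif <- function(x, ...) {
  cat(sprintf("Aalen-Johansen cumulative incidence, cause %d (n = %d)\n",
              x$cause, x$n))
  if (length(x$time) == 0L) {
    cat("  no events observed; estimate identically 0\n")
    return(invisible(x))
  }
  cat(sprintf("  %d jump times in [%g, %g]; final estimate %.4f (SE %.4f)\n",
              length(x$time), min(x$time), max(x$time),
              x$est[length(x$est)], x$se[length(x$se)]))
  invisible(x)
}

#' @export
summary.aj_cif <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$time
  vals <- t(vapply(times, function(t) cif_at(object, t), numeric(2)))
  out <- data.frame(time = times, estimate = vals[, 1], se = vals[, 2])
  class(out) <- c("summary.aj_cif", "data.frame")
  out
}

#' @export
plot.aj_cif <- function(x, conf = TRUE, xlab = "days",
                        ylab = "cumulative incidence", ...) {
  if (length(x$time) == 0L) {
    graphics::plot(0, 0, type = "n", xlab = xlab, ylab = ylab,
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    return(invisible(x))
  }
  tt <- c(0, x$time); ee <- c(0, x$est)
  graphics::plot(tt, ee, type = "s", xlab = xlab, ylab = ylab,
                 ylim = c(0, min(1, max(x$est + 2 * x$se))), ...)
  if (conf) {
    graphics::lines(tt, c(0, pmax(0, x$est - 1.96 * x$se)), type = "s",
                    lty = 2)
    graphics::lines(tt, c(0, pmin(1, x$est + 1.96 * x$se)), type = "s",
                    lty = 2)
  }
  invisible(x)
}

#' Evaluate a cumulative incidence estimate at arbitrary times
#'
#' Right-continuous step-function lookup: the value at the last jump at or
#' before `t`, and `(0, 0)` before the first jump. A jump exactly at `t` is
#' included unless `include_at = FALSE`.
#'
#' @param cif An [cuminc_aj()] fit.
#' @param t Non-negative time (scalar).
#' @param include_at Include a jump exactly at `t` (default `TRUE`).
#' @return Named numeric vector `c(est, se)`.
#' @export
cif_at <- function(cif, t, include_at = TRUE) {
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  i <- if (include_at) findInterval(t, cif$time)
       else findInterval(t, cif$time, left.open = TRUE)
  if (i == 0L) c(est = 0, se = 0)
  else c(est = cif$est[i], se = cif$se[i])
}

#' Median event time from a cumulative incidence estimate
#'
#' The smallest jump time at which the estimated cumulative incidence
#' reaches 0.5; `NA` when it never does (e.g. when fewer than half of
#' subjects experience the cause, as happens for complete-case analyses
#' with many missing cause-1 times).
#'
#' @param x An [cuminc_aj()] fit.
#' @param na.rm Unused, kept for generic compatibility.
#' @param ... Unused.
#' @return Median in days, or `NA_real_`.
#' @export
median.aj_cif <- function(x, na.rm = FALSE, ...) {
  i <- which(x$est >= 0.5)
  if (length(i) == 0L) NA_real_ else x$time[i[1]]
}

#' Delta-method standard error of the median event time
#'
#' The SE of the median is `SE(F(t50)) / f(t50)` where the density at the
#' median is a local gradient of the cumulative incidence:
#' `f = (F(u50) - F(l50)) / (u50 - l50)` with anchors
#' `u50 = min{t_i : F(t_i) >= 0.5 + eps}` and
#' `l50 = max{t_i : F(t_i) <= 0.5 - eps}` over the observed jump times.
#'
#' @param cif An [cuminc_aj()] fit.
#' @param epsilon Half-width of the gradient window on the probability
#'   scale (default 0.01).
#' @return Object of class `cif_median`: list with `median`, `se`,
#'   `density`, `epsilon`, `lower_anchor`, `upper_anchor`. `se` is `NA`
#'   (with a warning) when an anchor does not exist.
#' @export
median_estimate <- function(cif, epsilon = 0.01) {
  med <- median.aj_cif(cif)
  out <- list(median = med, se = NA_real_, density = NA_real_,
              epsilon = epsilon, lower_anchor = NA_real_,
              upper_anchor = NA_real_)
  class(out) <- "cif_median"
  if (is.na(med)) return(out)
  iu <- which(cif$est >= 0.5 + epsilon)
  il <- which(cif$est <= 0.5 - epsilon)
  if (length(iu) == 0L || length(il) == 0L) {
    warning("median SE undefined: no jump time beyond 0.5 +/- epsilon")
    return(out)
  }
  u50 <- cif$time[iu[1]]
  l50 <- cif$time[il[length(il)]]
  if (u50 <= l50) {
    warning("median SE undefined: degenerate gradient window")
    return(out)
  }
  Fu <- cif$est[iu[1]]
  Fl <- cif$est[il[length(il)]]
  dens <- (Fu - Fl) / (u50 - l50)
  se_f <- cif_at(cif, med)[["se"]]
  out$density <- dens
  out$se <- se_f / dens
  out$lower_anchor <- l50
  out$upper_anchor <- u50
  out
}

#' @export
print.cif_median <- function(x, ...) {
  if (is.na(x$median)) {
    cat("Median event time: not estimable (cumulative incidence < 0.5)\n")
  } else {
    cat(sprintf("Median event time: %g days (SE %.3f, local density %.5f/day,",
                x$median, x$se, x$density))
    cat(sprintf(" anchors [%g, %g], epsilon %g)\n",
                x$lower_anchor, x$upper_anchor, x$epsilon))
  }
  invisible(x)
}

#' Complete-case filter
#'
#' Drops every record whose event time is flagged missing; censored and
#' competing-event records are retained.
#'
#' @param dataset A `crd_data` data frame.
#' @return The filtered dataset.
#' @export
complete_case_filter <- function(dataset) {
  out <- dataset[!dataset$time_missing, , drop = FALSE]
  rownames(out) <- NULL
  out
}
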