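#' Combine per-imputation estimates by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation estimates;
#' its variance is the within-imputation variance `W = mean(se^2)` plus the
#' between-imputation variance `B = var(estimates)` inflated for finite
#' `m`: `T = W + (1 + 1/m) B`. No small-`m` degrees-of-freedom adjustment
#' is applied (the package reports standard errors, not intervals).
#'
#' Imputations with an undefined estimate (e.g. a median the cumulative
#' incidence never reaches) are dropped and counted. The pooled SE is
#' computed over imputations with both estimate and SE defined; it is `NA`
#' when fewer than two remain.
#'
#' @param estimates Per-imputation point estimates (may contain `NA`).
#' @param ses Per-imputation model-based standard errors.
#' @return Object of class `mi_pooled`: list with `estimate`, `se`, `m`
#'   (imputations used for the estimate), `within_var`, `between_var`,
#'   `n_undefined`.
#' @examples
#' pool_rubin(c(0.5, 0.6), c(0.1, 0.1))   # estimate 0.55, se 0.13229
#' @export
pool_rubin <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  ok <- !is.na(estimates)
  n_undef <- sum(!ok)
  if (sum(ok) < 2L) {
    out <- list(estimate = NA_real_, se = NA_real_, m = sum(ok),
                within_var = NA_real_, between_var = NA_real_,
                n_undefined = n_undef)
    class(out) <- "mi_pooled"
    return(out)
  }
  est <- mean(estimates[ok])
  both <- ok & !is.na(ses)
  if (sum(both) >= 2L) {
    m <- sum(both)
    w <- mean(ses[both]^2)
    b <- stats::var(estimates[both])
    se <- sqrt(w + (1 + 1 / m) * b)
  } else {
    w <- NA_real_; b <- NA_real_; se <- NA_real_
  }
  out <- list(estimate = est, se = se, m = sum(ok),
              within_var = w, between_var = b, n_undefined = n_undef)
  class(out) <- "mi_pooled"
  out
}

#' @export
print.mi_pooled <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over %d imputation(s)", x$m))
  if (x$n_undefined > 0L)
    cat(sprintf(" (%d undefined, dropped)", x$n_undefined))
  cat(sprintf(":\n  estimate %.5f, SE %.5f (within %.3g, between %.3g)\n",
              x$estimate, x$se, x$within_var, x$between_var))
  invisible(x)
}
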