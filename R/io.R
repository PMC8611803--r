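#' Write a competing-risks dataset to CSV
#'
#' The analysis view blanks the `time` field of flagged records and omits
#' the oracle column, so downstream consumers cannot see the generated
#' truth; the oracle view keeps `true_time` for harness use.
#'
#' @param dataset A `crd_data` data frame.
#' @param path Output file.
#' @param view `"analysis"` or `"oracle"`.
#' @return `path`, invisibly.
#' @export
write_crd <- function(dataset, path, view = c("analysis", "oracle")) {
  view <- match.arg(view)
  d <- as.data.frame(dataset)
  d$time_missing <- as.integer(d$time_missing)
  if (view == "analysis") d$true_time <- NULL
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a competing-risks dataset from CSV
#'
#' Accepts the dialect written by [write_crd()]; a `true_time` column is
#' optional. Validates the record invariants and reports offending line
#' numbers.
#'
#' @param path CSV file.
#' @return A `crd_data` data frame.
#' @export
read_crd <- function(path) {
  d <- utils::read.csv(path)
  need <- c("id", "time", "event", "aux", "time_missing",
            "interval_left", "interval_right")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d$time_missing <- d$time_missing != 0
  if (!"true_time" %in% names(d)) d$true_time <- d$time
  bad <- which(!d$event %in% 0:3)
  if (length(bad))
    stop("invalid event code on data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  ok_bounds <- !is.na(d$interval_left) & !is.na(d$interval_right) &
    d$interval_left < d$interval_right
  bad <- which(d$time_missing & !ok_bounds)
  if (length(bad))
    stop("flagged record without valid bounds on data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!d$time_missing & (is.na(d$time) | d$time < 1))
  if (length(bad))
    stop("observed time missing or < 1 on data line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  d <- d[, c(need, "true_time")]
  class(d) <- c("crd_data", "data.frame")
  d
}

#' Read a simulation scenario from a YAML or JSON config file
#'
#' Top-level keys mirror the arguments of [sim_config()]; an optional
#' `missingness` block mirrors [mdm_spec()] and an optional `study` block
#' mirrors [study_design()].
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return List with `config`, and `mdm` / `design` when present.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(lst, fn) {
    args <- lst[intersect(names(lst), names(formals(fn)))]
    do.call(fn, args)
  }
  cfg_fields <- raw[setdiff(names(raw), c("missingness", "study"))]
  out <- list(config = take(cfg_fields, sim_config))
  if (!is.null(raw$missingness)) out$mdm <- take(raw$missingness, mdm_spec)
  if (!is.null(raw$study)) out$design <- take(raw$study, study_design)
  out
}

#' Write study results or a cumulative incidence estimate to CSV
#'
#' @param x An `mi_study` results frame or an `aj_cif` fit.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "aj_cif")) {
    x <- data.frame(time = x$time, cause = x$cause, estimate = x$est,
                    se = x$se, n_risk = x$n_risk, n_event = x$n_event)
  }
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
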