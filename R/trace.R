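#' Construct a patient position trace
#'
#' A position trace is a data frame of sensor readings sampled (nominally)
#' every \code{sample_interval_s} seconds, with columns:
#' \describe{
#'   \item{t_s}{seconds from trace start; non-negative, strictly increasing,
#'     multiples of the sampling interval}
#'   \item{angle_deg}{signed transverse roll angle, positive towards the
#'     patient's right}
#'   \item{posture}{\code{"in_bed"} or \code{"upright"}}
#' }
#' The patient id and the absolute wall-clock start time travel as attributes;
#' absolute times are needed for hour-of-day metrics.
#'
#' @param t_s Numeric vector of sample times in seconds.
#' @param angle_deg Numeric vector of roll angles.
#' @param posture Character vector (recycled if length 1).
#' @param patient_id Single id string.
#' @param start_time \code{POSIXct} wall-clock time of \code{t_s = 0}.
#' @param sample_interval_s Sampling interval used for validation.
#' @return A \code{patient_trace} data frame.
#' @export
patient_trace <- function(t_s, angle_deg, posture = "in_bed",
                          patient_id = "P1",
                          start_time = as.POSIXct("2013-05-01 00:00:00", tz = "UTC"),
                          sample_interval_s = 10) {
  if (length(t_s) == 0) stop("patient_trace: empty trace")
  if (length(posture) == 1) posture <- rep(posture, length(t_s))
  tr <- data.frame(t_s = as.numeric(t_s), angle_deg = as.numeric(angle_deg),
                   posture = as.character(posture))
  attr(tr, "patient_id") <- as.character(patient_id)
  attr(tr, "start_time") <- as.POSIXct(start_time, tz = "UTC")
  attr(tr, "sample_interval_s") <- sample_interval_s
  class(tr) <- c("patient_trace", "data.frame")
  validate_trace(tr)
  tr
}

#' Validate a position trace
#'
#' Checks ordering, sampling-grid alignment and value ranges; stops with an
#' informative message naming the first offending row.
#'
#' @param trace A \code{patient_trace} (or plain data frame with the same
#'   columns).
#' @return The trace, invisibly.
#' @export
validate_trace <- function(trace) {
  need <- c("t_s", "angle_deg", "posture")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop("trace is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(trace) == 0) stop("trace has no samples")
  dt <- attr(trace, "sample_interval_s")
  if (is.null(dt)) dt <- 10
  if (any(!is.finite(trace$t_s)) || any(trace$t_s < 0))
    stop("trace t_s must be finite and non-negative")
  d <- diff(trace$t_s)
  if (any(d == 0)) {
    i <- which(d == 0)[1]
    stop(sprintf("duplicate timestamp at row %d (t_s = %g)", i + 1, trace$t_s[i + 1]))
  }
  if (any(d < 0)) {
    i <- which(d < 0)[1]
    stop(sprintf("timestamps out of order at row %d (t_s = %g after %g)",
                 i + 1, trace$t_s[i + 1], trace$t_s[i]))
  }
  off <- trace$t_s %% dt
  if (any(off != 0)) {
    i <- which(off != 0)[1]
    stop(sprintf("t_s not aligned to the %gs sampling grid at row %d", dt, i))
  }
  if (any(!is.finite(trace$angle_deg)))
    stop("trace angle_deg must be finite")
  if (any(!trace$posture %in% c("in_bed", "upright")))
    stop("trace posture values must be 'in_bed' or 'upright'")
  invisible(trace)
}

#' @export
print.patient_trace <- function(x, ...) {
  cat(sprintf("<patient_trace> %s: %d samples, %.1f h monitored, start %s\n",
              attr(x, "patient_id"), nrow(x),
              (max(x$t_s) - min(x$t_s)) / 3600,
              format(attr(x, "start_time"), "%Y-%m-%d %H:%M:%S %Z")))
  NextMethod()
}

#' Construct an exemption-interval table
#'
#' Documented periods (patient refusal, off-unit, clinical contraindication)
#' during which a missed turn must not penalise compliance.
#'
#' @param start_s,end_s Numeric vectors, interval bounds in trace-relative
#'   seconds, \code{start_s < end_s}, non-overlapping.
#' @param reason Character vector in
#'   \code{c("refused", "off_unit", "clinical")}.
#' @return A data frame with columns \code{start_s}, \code{end_s},
#'   \code{reason}.
#' @export
exemption_intervals <- function(start_s = numeric(), end_s = numeric(),
                                reason = character()) {
  if (length(reason) == 0 && length(start_s) > 0)
    reason <- rep("clinical", length(start_s))
  ex <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   reason = as.character(reason))
  validate_exemptions(ex)
  ex
}

validate_exemptions <- function(ex) {
  if (is.null(ex) || nrow(ex) == 0) return(invisible(ex))
  if (!all(c("start_s", "end_s") %in% names(ex)))
    stop("exemptions need columns start_s, end_s")
  if (any(ex$end_s <= ex$start_s))
    stop("exemption intervals must have start_s < end_s")
  o <- order(ex$start_s)
  exo <- ex[o, ]
  if (nrow(exo) > 1 && any(exo$start_s[-1] < exo$end_s[-nrow(exo)]))
    stop("exemption intervals overlap")
  if ("reason" %in% names(ex) &&
      !all(ex$reason %in% c("refused", "off_unit", "clinical")))
    stop("exemption reason must be one of refused, off_unit, clinical")
  invisible(ex)
}
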