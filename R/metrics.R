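# The three compliance statistics: per-patient / pooled compliance,
# 100-hour block turn-protocol adherence, and hour-of-day compliance.
#
# Exempt time is compliant-equivalent by default: it stays in the monitored
# denominator but never counts as non-compliant (a documented missed turn has
# no negative impact). Set exempt = "exclude" to drop exempt time from the
# denominator instead.

timeline_durations <- function(timeline, exempt = c("include", "exclude")) {
  exempt <- match.arg(exempt)
  tt <- state_times(timeline)
  num <- tt[["COMPLIANT"]] + if (exempt == "include") tt[["EXEMPT"]] else 0
  den <- tt[["COMPLIANT"]] + tt[["NONCOMPLIANT"]] +
    if (exempt == "include") tt[["EXEMPT"]] else 0
  c(num = num, den = den)
}

#' Per-patient turn-protocol compliance
#'
#' Total time the patient was considered compliant divided by total monitored
#' time.
#'
#' @param timeline A [compliance_timeline()].
#' @param exempt How documented exemption time enters the fraction:
#'   \code{"include"} (default; counts as compliant-equivalent) or
#'   \code{"exclude"} (dropped from the denominator).
#' @return Fraction in \[0, 1\].
#' @export
patient_compliance <- function(timeline, exempt = c("include", "exclude")) {
  if (is.null(timeline) || nrow(timeline) == 0)
    stop("patient_compliance: empty timeline")
  d <- timeline_durations(timeline, exempt)
  if (d[["den"]] <= 0) stop("patient_compliance: zero monitored time")
  unname(d[["num"]] / d[["den"]])
}

#' Pooled (phase-level) turn-protocol compliance
#'
#' Sum of compliant time across patients divided by total monitored time:
#' a monitored-time-weighted pooling, not the mean of per-patient fractions.
#'
#' @param timelines List of [compliance_timeline()] objects.
#' @inheritParams patient_compliance
#' @return Fraction in \[0, 1\].
#' @export
phase_compliance <- function(timelines, exempt = c("include", "exclude")) {
  if (length(timelines) == 0) stop("phase_compliance: no timelines")
  d <- vapply(timelines, timeline_durations, numeric(2), exempt = exempt)
  den <- sum(d["den", ])
  if (den <= 0) stop("phase_compliance: zero total monitored time")
  sum(d["num", ]) / den
}

# Patient-hours: wall-clock hours in which a patient was monitored for at
# least min_coverage_s, with a flag for "zero non-compliant time".
patient_hours <- function(timelines, min_coverage_s = 1800) {
  rows <- lapply(timelines, function(tl) {
    t0 <- as.numeric(attr(tl, "start_time"))
    if (length(t0) == 0 || is.na(t0))
      stop("timeline lacks an absolute start_time; hour-based metrics need one")
    a <- t0 + tl$start_s
    b <- t0 + tl$end_s
    h0 <- floor(min(a) / 3600)
    h1 <- floor((max(b) - 1e-9) / 3600)
    hours <- seq(h0, h1) * 3600
    cov <- vapply(hours, function(h)
      sum(pmax(0, pmin(b, h + 3600) - pmax(a, h))), numeric(1))
    bad <- tl$state == "NONCOMPLIANT"
    ncv <- vapply(hours, function(h)
      sum(pmax(0, pmin(b[bad], h + 3600) - pmax(a[bad], h))), numeric(1))
    data.frame(patient_id = attr(tl, "patient_id") %||% "?",
               hour_start = hours, covered_s = cov, noncompliant_s = ncv,
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, rows)
  ph <- ph[ph$covered_s >= min_coverage_s, , drop = FALSE]
  ph <- ph[order(ph$hour_start, ph$patient_id), , drop = FALSE]
  ph$fully_compliant <- ph$noncompliant_s == 0
  ph
}

#' Turn-protocol adherence per 100-hour monitoring block
#'
#' Patient-hours (wall-clock hours with at least 30 min of monitoring) are
#' ordered chronologically (ties broken by patient id) and chunked into
#' consecutive blocks of \code{block_h} hours; each block's adherence is the
#' fraction of its hours with 100% turn-protocol compliance (zero
#' non-compliant time; exempt time does not break an hour). A trailing
#' partial block is dropped.
#'
#' @param timelines List of [compliance_timeline()] objects with absolute
#'   start times.
#' @param block_h Block size in patient-hours (default 100).
#' @return Numeric vector of per-block adherence fractions.
#' @export
block_adherence <- function(timelines, block_h = 100) {
  ph <- patient_hours(timelines)
  n_blocks <- floor(nrow(ph) / block_h)
  if (n_blocks < 1)
    stop(sprintf("need at least %d patient-hours; have %d", block_h, nrow(ph)))
  idx <- seq_len(n_blocks * block_h)
  blk <- rep(seq_len(n_blocks), each = block_h)
  as.numeric(tapply(ph$fully_compliant[idx], blk, mean))
}

#' Average hourly turn-protocol compliance over the 24-hour day
#'
#' For each hour-of-day bin, the compliant time accumulated in that bin
#' (pooled across patients and days) divided by the monitored time in the
#' bin. Bins with no monitored time are \code{NA}.
#'
#' @param timelines List of [compliance_timeline()] objects with absolute
#'   start times.
#' @inheritParams patient_compliance
#' @return Numeric vector of 24 fractions (names \code{"00"}..\code{"23"}),
#'   \code{NA} where unmonitored.
#' @export
hourly_compliance <- function(timelines, exempt = c("include", "exclude")) {
  exempt <- match.arg(exempt)
  num <- den <- numeric(24)
  for (tl in timelines) {
    t0 <- as.numeric(attr(tl, "start_time"))
    if (length(t0) == 0 || is.na(t0))
      stop("timeline lacks an absolute start_time; hour-based metrics need one")
    a <- t0 + tl$start_s
    b <- t0 + tl$end_s
    st <- tl$state
    for (i in seq_along(a)) {
      if (exempt == "exclude" && st[i] == "EXEMPT") next
      lo <- a[i]
      while (lo < b[i]) {
        hi <- min(b[i], (floor(lo / 3600) + 1) * 3600)
        bin <- (floor(lo / 3600) %% 24) + 1
        den[bin] <- den[bin] + (hi - lo)
        if (st[i] != "NONCOMPLIANT") num[bin] <- num[bin] + (hi - lo)
        lo <- hi
      }
    }
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  names(out) <- sprintf("%02d", 0:23)
  out
}

#' Summarise one study phase
#'
#' Collects the three compliance statistics plus cohort descriptors into a
#' phase summary.
#'
#' @param timelines Named list of [compliance_timeline()] objects.
#' @param records Demographics data frame from [simulate_cohort()] (or the
#'   equivalent columns for real data).
#' @param phase Phase label.
#' @param block_h Block size for [block_adherence()].
#' @inheritParams patient_compliance
#' @return An object of class \code{phase_summary}.
#' @export
phase_summary <- function(timelines, records = NULL, phase = "baseline",
                          block_h = 100, exempt = c("include", "exclude")) {
  exempt <- match.arg(exempt)
  per <- vapply(timelines, patient_compliance, numeric(1), exempt = exempt)
  mon_h <- vapply(timelines, function(tl)
    sum(tl$end_s - tl$start_s), numeric(1)) / 3600
  blocks <- tryCatch(block_adherence(timelines, block_h),
                     error = function(e) numeric(0))
  out <- list(phase = phase,
              n_patients = length(timelines),
              monitored_h = sum(mon_h),
              pooled_compliance = phase_compliance(timelines, exempt = exempt),
              per_patient_compliance = unname(per),
              patient_ids = names(timelines),
              patient_monitored_h = unname(mon_h),
              block_adherence = blocks,
              hourly_compliance = hourly_compliance(timelines, exempt = exempt),
              records = records)
  class(out) <- "phase_summary"
  out
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("<phase_summary> %s: %d patients, %.0f h monitored\n",
              x$phase, x$n_patients, x$monitored_h))
  cat(sprintf("  pooled compliance : %.1f%%\n", 100 * x$pooled_compliance))
  cat(sprintf("  per-patient range : %.1f%% - %.1f%%\n",
              100 * min(x$per_patient_compliance),
              100 * max(x$per_patient_compliance)))
  if (length(x$block_adherence))
    cat(sprintf("  block adherence   : mean %.1f%% over %d blocks of 100 h\n",
                100 * mean(x$block_adherence), length(x$block_adherence)))
  invisible(x)
}
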