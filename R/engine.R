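# Turn-detection and compliance engine.
#
# Time semantics: every sample covers the half-open interval from its own
# timestamp to the next sample's timestamp (the final sample covers one
# nominal sampling interval). A sampling gap longer than max_gap_min splits
# the trace into independent monitored blocks; all clocks restart at a block
# boundary and the gap itself is unmonitored (excluded from numerator and
# denominator of every metric).
#
# Clock semantics: one sustained-time clock per body region (LEFT/BACK/RIGHT).
# The clock of the occupied region accrues; a vacated region's clock is zeroed
# once the region has been continuously offloaded for decompression_min
# (otherwise it resumes on re-entry, so brief rocking cannot reset the turn
# period). Upright posture zeroes all three clocks. Compliance is evaluated on
# the discrete sampling grid: a reading is NONCOMPLIANT when the sustained
# time on the current region, inclusive of that reading, has reached
# turn_period + grace.

#' Segment a position trace into sustained-region intervals
#'
#' Classifies every sample, then merges consecutive samples in the same region
#' and debounces: a region change only registers if the new region persists
#' for at least \code{debounce_min}; shorter excursions are absorbed into the
#' surrounding region. Gaps longer than \code{max_gap_min} split the trace
#' into independent monitored blocks.
#'
#' @param trace A [patient_trace()].
#' @param config An [engine_config()].
#' @return Data frame with columns \code{start_s}, \code{end_s},
#'   \code{region}, \code{block}; intervals are contiguous within a block.
#' @export
segment_regions <- function(trace, config = engine_config()) {
  validate_trace(trace)
  dt <- config$sample_interval_s
  gap_s <- config$max_gap_min * 60
  n <- nrow(trace)
  t <- trace$t_s
  cover <- c(diff(t), dt)
  gap <- cover > gap_s
  cover[gap] <- dt
  block <- cumsum(c(1, as.integer(gap[-n])))
  region <- classify_region(trace$angle_deg, trace$posture,
                            config$angle_threshold_deg)
  ends <- t + cover

  out <- vector("list", max(block))
  for (b in seq_len(max(block))) {
    idx <- which(block == b)
    r <- rle(region[idx])
    k <- length(r$lengths)
    last <- cumsum(r$lengths)
    first <- c(1, last[-k] + 1)
    runs <- data.frame(start_s = t[idx][first],
                       end_s = ends[idx][last],
                       region = r$values)
    runs <- debounce_runs(runs, config$debounce_min * 60)
    runs$block <- b
    out[[b]] <- runs
  }
  do.call(rbind, out)
}

# Absorb runs shorter than debounce_s into their neighbours (into the
# preceding run; a short leading run is absorbed into the following one).
# A block consisting of a single run is kept regardless of its length.
debounce_runs <- function(runs, debounce_s) {
  repeat {
    if (nrow(runs) <= 1) return(runs)
    dur <- runs$end_s - runs$start_s
    short <- which(dur < debounce_s)
    if (length(short) == 0) return(runs)
    i <- short[1]
    runs$region[i] <- if (i == 1) runs$region[2] else runs$region[i - 1]
    # re-merge adjacent equal regions
    keep <- c(TRUE, runs$region[-1] != runs$region[-nrow(runs)])
    grp <- cumsum(keep)
    runs <- data.frame(start_s = tapply(runs$start_s, grp, min),
                       end_s = tapply(runs$end_s, grp, max),
                       region = runs$region[keep],
                       row.names = NULL)
  }
}

# Core sweep over region intervals: emits turn events and per-interval
# compliance/display states (before exemption overlay). Internal.
engine_sweep <- function(segs, config) {
  dt <- config$sample_interval_s
  limit_s <- (config$turn_period_min + config$grace_min) * 60
  green_s <- config$green_window_min * 60
  period_s <- config$turn_period_min * 60
  decomp_s <- config$decompression_min * 60

  ev <- list(t_change = numeric(), from_region = character(),
             to_region = character(), qualifying = logical(),
             t_qualified = numeric())
  st <- list(start_s = numeric(), end_s = numeric(), state = character(),
             display = character(), block = integer())
  push_state <- function(a, b, state, display, blk) {
    st$start_s[[length(st$start_s) + 1]] <<- a
    st$end_s[[length(st$end_s) + 1]] <<- b
    st$state[[length(st$state) + 1]] <<- state
    st$display[[length(st$display) + 1]] <<- display
    st$block[[length(st$block) + 1]] <<- blk
  }

  for (b in unique(segs$block)) {
    sb <- segs[segs$block == b, , drop = FALSE]
    m <- nrow(sb)
    block_end <- sb$end_s[m]
    sus <- c(LEFT = 0, BACK = 0, RIGHT = 0)
    vac <- c(LEFT = NA_real_, BACK = NA_real_, RIGHT = NA_real_)
    prev <- NA_character_

    for (i in seq_len(m)) {
      s <- sb$start_s[i]; e <- sb$end_s[i]; reg <- sb$region[i]

      if (!is.na(prev) && prev != reg &&
          prev != "UPRIGHT" && reg != "UPRIGHT") {
        reent <- sb$start_s[seq_len(m) > i & sb$region == prev]
        offload <- if (length(reent)) reent[1] - s else block_end - s
        qual <- offload >= decomp_s
        ev$t_change[[length(ev$t_change) + 1]] <- s
        ev$from_region[[length(ev$from_region) + 1]] <- prev
        ev$to_region[[length(ev$to_region) + 1]] <- reg
        ev$qualifying[[length(ev$qualifying) + 1]] <- qual
        ev$t_qualified[[length(ev$t_qualified) + 1]] <-
          if (qual) s + decomp_s else NA_real_
      }

      if (reg == "UPRIGHT") {
        sus[] <- 0
        vac[] <- NA_real_
        push_state(s, e, "COMPLIANT", "GREEN", b)
      } else {
        if (!is.na(vac[[reg]]) && s - vac[[reg]] >= decomp_s) sus[[reg]] <- 0
        vac[[reg]] <- NA_real_
        s0 <- sus[[reg]]
        K <- (e - s) / dt
        # first grid step whose end-of-step sustained time crosses each rule
        brk <- function(k) if (k > K) e else s + (max(k, 1) - 1) * dt
        y_at <- brk(ceiling((green_s - s0) / dt))          # sus_end >= green
        r_at <- brk(floor((period_s - s0) / dt) + 1)       # sus_end >  period
        nc_at <- brk(ceiling((limit_s - s0) / dt))         # sus_end >= limit
        cp <- sort(unique(c(s, y_at, r_at, nc_at, e)))
        for (j in seq_len(length(cp) - 1)) {
          a <- cp[j]
          state <- if (a >= nc_at) "NONCOMPLIANT" else "COMPLIANT"
          display <- if (a >= r_at) "RED" else if (a >= y_at) "YELLOW" else "GREEN"
          push_state(a, cp[j + 1], state, display, b)
        }
        sus[[reg]] <- s0 + (e - s)
        vac[[reg]] <- e
      }
      prev <- reg
    }
  }

  events <- data.frame(t_change = ev$t_change, from_region = ev$from_region,
                       to_region = ev$to_region, qualifying = ev$qualifying,
                       t_qualified = ev$t_qualified,
                       stringsAsFactors = FALSE)
  states <- data.frame(start_s = st$start_s, end_s = st$end_s,
                       state = st$state, display = st$display,
                       block = st$block, stringsAsFactors = FALSE)
  states <- merge_equal_runs(states)
  list(events = events, states = states)
}

# Merge adjacent intervals that agree in every label (within a block).
merge_equal_runs <- function(states) {
  if (nrow(states) <= 1) return(states)
  same <- with(states,
               c(FALSE, state[-1] == state[-nrow(states)] &
                   display[-1] == display[-nrow(states)] &
                   block[-1] == block[-nrow(states)] &
                   start_s[-1] == end_s[-nrow(states)]))
  grp <- cumsum(!same)
  data.frame(start_s = as.numeric(tapply(states$start_s, grp, min)),
             end_s = as.numeric(tapply(states$end_s, grp, max)),
             state = states$state[!same],
             display = states$display[!same],
             block = states$block[!same],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect turn events in a segmented trace
#'
#' Every change between the bed regions LEFT/BACK/RIGHT emits a turn event
#' (the sensor cannot distinguish self-turns from caregiver-assisted turns).
#' An event is \emph{qualifying} when the vacated region stays continuously
#' offloaded for at least the decompression time; it is then fully
#' decompressed at \code{t_qualified = t_change + decompression}. If the
#' patient returns to the vacated region earlier, the event is non-qualifying
#' and that region's sustained-time clock resumes, accumulating across the
#' interruption. An event whose decompression window is cut short by the end
#' of monitoring is conservatively marked non-qualifying.
#'
#' @param region_intervals Output of [segment_regions()].
#' @param config An [engine_config()].
#' @return Data frame with columns \code{t_change}, \code{from_region},
#'   \code{to_region}, \code{qualifying}, \code{t_qualified} (NA when
#'   non-qualifying).
#' @export
detect_turns <- function(region_intervals, config = engine_config()) {
  stopifnot(is.data.frame(region_intervals),
            all(c("start_s", "end_s", "region") %in% names(region_intervals)))
  if (is.null(region_intervals$block)) region_intervals$block <- 1L
  engine_sweep(region_intervals, config)$events
}

#' Compute the compliance timeline of a position trace
#'
#' Runs the full engine: segmentation and debouncing, per-region sustained
#' time with decompression accounting, the grace-period compliance rule, the
#' bedside display rule, and the exemption overlay. The result partitions the
#' monitored span into contiguous intervals labelled with a compliance state
#' (\code{COMPLIANT}, \code{NONCOMPLIANT}, \code{EXEMPT}) and a display state
#' (\code{GREEN}, \code{YELLOW}, \code{RED}; \code{NONE} while exempt).
#'
#' Non-compliant time first accrues during the reading in which the sustained
#' time on one side reaches \code{turn_period + grace} (135 min under the
#' default protocol); exemption intervals override any state to \code{EXEMPT}
#' so that a documented missed turn cannot penalise compliance; upright time
#' is compliant and resets all region clocks.
#'
#' @param trace A [patient_trace()].
#' @param exemptions Optional [exemption_intervals()] data frame
#'   (trace-relative seconds).
#' @param config An [engine_config()].
#' @return A \code{compliance_timeline}: data frame with columns
#'   \code{start_s}, \code{end_s}, \code{state}, \code{display}, \code{block},
#'   carrying the patient id, absolute start time and turn events as
#'   attributes.
#' @examples
#' tr <- patient_trace(t_s = seq(0, 200 * 60 - 10, by = 10), angle_deg = 0)
#' tl <- compliance_timeline(tr)
#' state_times(tl) / 60  # minutes per state
#' @export
compliance_timeline <- function(trace, exemptions = NULL,
                                config = engine_config()) {
  segs <- segment_regions(trace, config)
  sweep <- engine_sweep(segs, config)
  states <- sweep$states
  if (!is.null(exemptions) && nrow(exemptions) > 0) {
    validate_exemptions(exemptions)
    span <- c(min(states$start_s), max(states$end_s))
    if (any(exemptions$start_s < span[1]) || any(exemptions$end_s > span[2]))
      stop("exemption intervals fall outside the monitored span")
    states <- overlay_exemptions(states, exemptions)
  }
  attr(states, "patient_id") <- attr(trace, "patient_id")
  attr(states, "start_time") <- attr(trace, "start_time")
  attr(states, "events") <- sweep$events
  attr(states, "config") <- config
  class(states) <- c("compliance_timeline", "data.frame")
  states
}

# Split state intervals at exemption bounds and relabel the covered pieces.
overlay_exemptions <- function(states, ex) {
  ex <- ex[order(ex$start_s), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(states))) {
    a <- states$start_s[i]; b <- states$end_s[i]
    cuts <- sort(unique(c(a, b,
                          pmin(pmax(ex$start_s, a), b),
                          pmin(pmax(ex$end_s, a), b))))
    for (j in seq_len(length(cuts) - 1)) {
      lo <- cuts[j]; hi <- cuts[j + 1]
      exempt <- any(ex$start_s <= lo & ex$end_s >= hi)
      out[[length(out) + 1]] <- data.frame(
        start_s = lo, end_s = hi,
        state = if (exempt) "EXEMPT" else states$state[i],
        display = if (exempt) "NONE" else states$display[i],
        block = states$block[i], stringsAsFactors = FALSE)
    }
  }
  merge_equal_runs(do.call(rbind, out))
}

#' Total time per compliance state
#'
#' @param timeline A [compliance_timeline()].
#' @return Named numeric vector of seconds for \code{COMPLIANT},
#'   \code{NONCOMPLIANT} and \code{EXEMPT}.
#' @export
state_times <- function(timeline) {
  dur <- timeline$end_s - timeline$start_s
  out <- c(COMPLIANT = 0, NONCOMPLIANT = 0, EXEMPT = 0)
  agg <- tapply(dur, timeline$state, sum)
  out[names(agg)] <- agg
  out
}

#' @export
print.compliance_timeline <- function(x, ...) {
  tt <- state_times(x)
  cat(sprintf("<compliance_timeline> %s: %.1f h monitored (%.1f%% compliant, %.1f%% non-compliant, %.1f%% exempt)\n",
              attr(x, "patient_id") %||% "?",
              sum(tt) / 3600, 100 * tt[1] / sum(tt), 100 * tt[2] / sum(tt),
              100 * tt[3] / sum(tt)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
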