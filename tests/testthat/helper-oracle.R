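# Brute-force per-sample reference simulator: advances the trace one sampling
# interval at a time, updating one sustained-time clock and one offload timer
# per body region, and labels every step. Written independently of the
# interval engine so the two can cross-check each other.

oracle_steps <- function(trace, exemptions = NULL, config = engine_config()) {
  dt <- config$sample_interval_s
  gap_s <- config$max_gap_min * 60
  deb_s <- config$debounce_min * 60
  limit_s <- (config$turn_period_min + config$grace_min) * 60
  green_s <- config$green_window_min * 60
  period_s <- config$turn_period_min * 60
  decomp_s <- config$decompression_min * 60

  n <- nrow(trace)
  cover <- c(diff(trace$t_s), dt)
  gap <- cover > gap_s
  cover[gap] <- dt
  block <- cumsum(c(1, as.integer(gap[-n])))
  region <- classify_region(trace$angle_deg, trace$posture,
                            config$angle_threshold_deg)

  # expand each sample into dt-sized steps
  reps <- cover / dt
  step_t <- unlist(lapply(seq_len(n), function(i)
    trace$t_s[i] + dt * (seq_len(reps[i]) - 1)))
  step_region <- rep(region, reps)
  step_block <- rep(block, reps)

  # independent debounce: repeatedly recolour runs shorter than deb_s
  for (b in unique(step_block)) {
    idx <- which(step_block == b)
    r <- step_region[idx]
    repeat {
      runs <- rle(r)
      if (length(runs$lengths) <= 1) break
      short <- which(runs$lengths * dt < deb_s)
      if (!length(short)) break
      i <- short[1]
      repl <- if (i == 1) runs$values[2] else runs$values[i - 1]
      lo <- sum(runs$lengths[seq_len(i - 1)]) + 1
      r[lo:(lo + runs$lengths[i] - 1)] <- repl
    }
    step_region[idx] <- r
  }

  m <- length(step_t)
  state <- character(m)
  display <- character(m)
  regions <- c("LEFT", "BACK", "RIGHT")
  prev_block <- -1L
  sus <- off <- NULL
  for (k in seq_len(m)) {
    if (step_block[k] != prev_block) {
      sus <- c(LEFT = 0, BACK = 0, RIGHT = 0)
      off <- c(LEFT = 0, BACK = 0, RIGHT = 0)
      prev_block <- step_block[k]
    }
    r <- step_region[k]
    if (r == "UPRIGHT") {
      sus[] <- 0
      off <- off + dt
      sus[off >= decomp_s] <- 0
      state[k] <- "COMPLIANT"
      display[k] <- "GREEN"
    } else {
      for (q in regions) {
        if (q == r) next
        off[q] <- off[q] + dt
        if (off[q] >= decomp_s) sus[q] <- 0
      }
      off[r] <- 0
      sus[r] <- sus[r] + dt
      state[k] <- if (sus[r] >= limit_s) "NONCOMPLIANT" else "COMPLIANT"
      display[k] <- if (sus[r] > period_s) "RED"
                    else if (sus[r] >= green_s) "YELLOW" else "GREEN"
    }
  }

  if (!is.null(exemptions) && nrow(exemptions) > 0) {
    for (i in seq_len(nrow(exemptions))) {
      hit <- step_t >= exemptions$start_s[i] &
        (step_t + dt) <= exemptions$end_s[i]
      state[hit] <- "EXEMPT"
      display[hit] <- "NONE"
    }
  }
  data.frame(t = step_t, state = state, display = display,
             block = step_block, stringsAsFactors = FALSE)
}

# Look up the engine timeline's state/display at each step start.
timeline_at <- function(timeline, t) {
  i <- findInterval(t, timeline$start_s)
  ok <- i >= 1 & t < timeline$end_s[pmax(i, 1)]
  if (!all(ok)) stop("timeline lookup outside monitored span")
  data.frame(state = timeline$state[i], display = timeline$display[i],
             stringsAsFactors = FALSE)
}

# Random in-bed/upright trace with angles that linger near the classification
# boundary, plus optional dt-aligned exemptions.
random_trace <- function(seed, hours = 24, dt = 10, p_upright = 0.1,
                         n_exempt = 0) {
  set.seed(seed)
  total_s <- hours * 3600
  t_s <- seq(0, total_s - dt, by = dt)
  # piecewise-constant latent angle with occasional very short excursions
  segs <- list(); at <- 0
  while (at < total_s) {
    dur <- if (runif(1) < 0.25) sample(1:5, 1) * dt else
      ceiling(rexp(1, 1 / (40 * 60)) / dt) * dt
    dur <- max(dur, dt)
    segs[[length(segs) + 1]] <- c(at, min(at + dur, total_s),
                                  runif(1, -60, 60))
    at <- at + dur
  }
  sm <- do.call(rbind, segs)
  idx <- findInterval(t_s, sm[, 1])
  angle <- sm[idx, 3] + rnorm(length(t_s), 0, runif(1, 0, 4))
  posture <- rep("in_bed", length(t_s))
  if (runif(1) < p_upright) {
    u0 <- sample(t_s, 1)
    posture[t_s >= u0 & t_s < u0 + 3600] <- "upright"
  }
  ex <- exemption_intervals()
  if (n_exempt > 0) {
    starts <- sort(sample(seq(0, total_s - 1800, by = dt), n_exempt))
    ends <- pmin(starts + sample(seq(600, 5400, by = dt), n_exempt,
                                 replace = TRUE), total_s)
    keep <- c(TRUE, starts[-1] >= ends[-n_exempt])
    ex <- exemption_intervals(starts[keep], ends[keep])
  }
  list(trace = patient_trace(t_s, angle, posture, patient_id = "R1",
                             sample_interval_s = dt),
       exemptions = ex)
}

expect_engine_matches_oracle <- function(seed, hours = 24, n_exempt = 0,
                                         config = engine_config()) {
  rt <- random_trace(seed, hours = hours, n_exempt = n_exempt,
                     dt = config$sample_interval_s)
  tl <- compliance_timeline(rt$trace, rt$exemptions, config)
  or <- oracle_steps(rt$trace, rt$exemptions, config)
  got <- timeline_at(tl, or$t)
  expect_identical(got$state, or$state)
  expect_identical(got$display, or$display)
  invisible(list(timeline = tl, oracle = or, input = rt))
}
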