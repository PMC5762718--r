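# Seeded simulator for wearable position-monitoring cohorts.
#
# The generator emulates the data-generating process the compliance analysis
# assumes: 10-s roll-angle sampling, a latent body-region sequence driven by
# scheduled caregiver turns (each independently missed with a configurable
# probability) and Poisson self-turns, sink-back angle drift after caregiver
# turns, contiguous daytime upright periods, documented exemption intervals,
# and Braden/age/sex demographics.
#
# Randomness is drawn in a fixed order whose stream lengths do not depend on
# miss_probability, so raising the miss probability flips miss indicators
# without perturbing the rest of the trace (common random numbers). This is
# what makes pooled compliance behave monotonically in miss_probability at a
# fixed seed, and what the regime calibration relies on.

#' Simulation configuration for a monitored cohort
#'
#' Defaults describe a general adult medical unit on a 2-hour turning
#' protocol: mean stay about 59 h (stays exponential, truncated at a 12-h
#' minimum), caregiver-assisted turns scheduled every 120 min, a modest
#' self-turn rate, 3 degrees of sensor noise, occasional sink-back after
#' caregiver turns, about one documented exemption per 100 monitored hours,
#' and 15% of the stay spent upright during daytime.
#'
#' @param n_patients Number of patients.
#' @param mean_stay_h Mean monitored stay in hours (exponential, truncated
#'   to a 12-h minimum).
#' @param sample_interval_s Sensor sampling interval in seconds.
#' @param self_turn_rate_per_h Poisson rate of spontaneous self-turns.
#' @param caregiver_period_min Scheduled caregiver turn interval in minutes.
#' @param miss_probability Probability each scheduled caregiver turn is
#'   missed.
#' @param angle_noise_sd_deg Gaussian sensor noise SD in degrees.
#' @param sink_back_prob Probability a caregiver turn to a side is followed by
#'   sink-back drift.
#' @param sink_back_halflife_min Half-life of the sink-back angle decay in
#'   minutes.
#' @param exemption_rate_per_100h Documented exemptions per 100 monitored
#'   hours.
#' @param upright_fraction Fraction of each full day spent upright/out of bed
#'   (contiguous daytime block), in \[0, 1).
#' @param demographics Named list: \code{age_mean}, \code{age_sd},
#'   \code{female_prob}, \code{braden_mean}, \code{braden_sd},
#'   \code{isolation_prob}.
#' @param phase Phase label attached to the generated records
#'   (\code{"baseline"} or \code{"post"}).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients = 75,
                              mean_stay_h = 59,
                              sample_interval_s = 10,
                              self_turn_rate_per_h = 0.2,
                              caregiver_period_min = 120,
                              miss_probability = 0.5,
                              angle_noise_sd_deg = 3,
                              sink_back_prob = 0.2,
                              sink_back_halflife_min = 20,
                              exemption_rate_per_100h = 1,
                              upright_fraction = 0.15,
                              demographics = list(
                                age_mean = 58, age_sd = 18,
                                female_prob = 0.47,
                                braden_mean = 20.8, braden_sd = 2.2,
                                isolation_prob = 5 / 75),
                              phase = "baseline",
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              mean_stay_h = as.numeric(mean_stay_h),
              sample_interval_s = as.numeric(sample_interval_s),
              self_turn_rate_per_h = as.numeric(self_turn_rate_per_h),
              caregiver_period_min = as.numeric(caregiver_period_min),
              miss_probability = as.numeric(miss_probability),
              angle_noise_sd_deg = as.numeric(angle_noise_sd_deg),
              sink_back_prob = as.numeric(sink_back_prob),
              sink_back_halflife_min = as.numeric(sink_back_halflife_min),
              exemption_rate_per_100h = as.numeric(exemption_rate_per_100h),
              upright_fraction = as.numeric(upright_fraction),
              demographics = demographics,
              phase = match.arg(phase, c("baseline", "post")),
              seed = as.integer(seed))
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (cfg$mean_stay_h <= 0) stop("mean_stay_h must be > 0")
  if (cfg$sample_interval_s <= 0 || 60 %% cfg$sample_interval_s != 0)
    stop("sample_interval_s must divide 60 s evenly")
  if (cfg$self_turn_rate_per_h < 0) stop("self_turn_rate_per_h must be >= 0")
  if (cfg$caregiver_period_min <= 0) stop("caregiver_period_min must be > 0")
  for (p in c("miss_probability", "sink_back_prob"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  if (cfg$angle_noise_sd_deg < 0) stop("angle_noise_sd_deg must be >= 0")
  if (cfg$sink_back_halflife_min <= 0)
    stop("sink_back_halflife_min must be > 0")
  if (cfg$exemption_rate_per_100h < 0)
    stop("exemption_rate_per_100h must be >= 0")
  if (cfg$upright_fraction < 0 || cfg$upright_fraction >= 1)
    stop("upright_fraction must lie in [0, 1)")
  need <- c("age_mean", "age_sd", "female_prob", "braden_mean", "braden_sd",
            "isolation_prob")
  if (!all(need %in% names(cfg$demographics)))
    stop("demographics must provide: ", paste(need, collapse = ", "))
  class(cfg) <- "simulation_config"
  cfg
}

REGION_ANGLE <- c(LEFT = -45, BACK = 0, RIGHT = 45)

#' Simulate one monitored patient
#'
#' Generates the latent region sequence (scheduled caregiver turns cycling
#' left -> back -> right -> back, each missed independently with
#' \code{miss_probability}; Poisson self-turns to a uniformly chosen other
#' region), emits noisy roll angles at the sampling interval (side-lying at
#' +/-45 degrees, back at 0), applies sink-back decay after affected
#' caregiver turns, inserts daytime upright blocks, and draws exemption
#' intervals and demographics.
#'
#' @param config A [simulation_config()].
#' @param patient_seed Integer seed for this patient's randomness.
#' @param patient_id Id string for the generated trace/record.
#' @return List with elements \code{trace} (a [patient_trace()]),
#'   \code{exemptions} (an [exemption_intervals()] table) and \code{record}
#'   (one-row demographics data frame).
#' @export
simulate_patient <- function(config, patient_seed = config$seed,
                             patient_id = "P1") {
  stopifnot(inherits(config, "simulation_config"))
  dt <- config$sample_interval_s
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(patient_seed)

  # --- fixed draw order; stream lengths independent of miss_probability ---
  stay_h <- max(12, stats::rexp(1, rate = 1 / config$mean_stay_h))
  stay_s <- floor(stay_h * 3600 / dt) * dt
  if (stay_s <= 0) stop("simulate_patient: non-positive stay")
  start_day_s <- floor(stats::runif(1, 0, 86400) / dt) * dt
  start_time <- as.POSIXct("2013-05-01 00:00:00", tz = "UTC") + start_day_s

  n_sched <- floor(stay_s / (config$caregiver_period_min * 60))
  sched_t <- seq_len(n_sched) * config$caregiver_period_min * 60
  n_self <- stats::rpois(1, config$self_turn_rate_per_h * stay_s / 3600)
  self_t <- sort(floor(stats::runif(n_self, 0, stay_s) / dt) * dt)
  self_u <- stats::runif(max(n_self, 1))[seq_len(n_self)]
  miss_u <- stats::runif(max(n_sched, 1))[seq_len(n_sched)]
  sink_u <- stats::runif(max(n_sched, 1))[seq_len(n_sched)]

  # upright daytime blocks (one per full day present)
  n_days <- ceiling((start_day_s + stay_s) / 86400)
  up_len <- config$upright_fraction * 86400
  up_start_u <- stats::runif(n_days)
  # exemptions
  n_ex <- stats::rpois(1, config$exemption_rate_per_100h * stay_s / 360000)
  ex_start_u <- stats::runif(max(n_ex, 1))[seq_len(n_ex)]
  ex_dur <- stats::runif(max(n_ex, 1), 30 * 60, 120 * 60)[seq_len(n_ex)]
  # demographics
  dg <- config$demographics
  age <- round(min(97, max(18, stats::rnorm(1, dg$age_mean, dg$age_sd))))
  sex <- if (stats::runif(1) < dg$female_prob) "F" else "M"
  braden <- round(min(23, max(11, stats::rnorm(1, dg$braden_mean, dg$braden_sd))))
  isolation <- stats::runif(1) < dg$isolation_prob
  n_samp <- stay_s / dt
  noise <- if (config$angle_noise_sd_deg > 0)
    stats::rnorm(n_samp, 0, config$angle_noise_sd_deg) else numeric(n_samp)

  # --- latent region path ---
  ev_t <- c(sched_t, self_t)
  ev_kind <- c(rep("sched", n_sched), rep("self", n_self))
  ev_idx <- c(seq_len(n_sched), seq_len(n_self))
  o <- order(ev_t, ev_kind)  # at ties, "sched" sorts before "self"
  ev_t <- ev_t[o]; ev_kind <- ev_kind[o]; ev_idx <- ev_idx[o]

  cycle <- c("LEFT", "BACK", "RIGHT", "BACK")
  cyc_pos <- 0L
  region <- "BACK"
  seg_start <- 0
  seg_region <- character()
  seg_from <- numeric()
  add_seg <- function(until) {
    if (until > seg_start) {
      seg_region[[length(seg_region) + 1]] <<- region
      seg_from[[length(seg_from) + 1]] <<- seg_start
      seg_start <<- until
    }
  }
  for (k in seq_along(ev_t)) {
    t_ev <- ev_t[k]
    if (t_ev >= stay_s) break
    if (ev_kind[k] == "sched") {
      if (miss_u[ev_idx[k]] < config$miss_probability) next  # missed turn
      target <- region
      while (target == region) {
        cyc_pos <- cyc_pos %% 4L + 1L
        target <- cycle[cyc_pos]
      }
      add_seg(t_ev)
      region <- target
    } else {
      others <- setdiff(c("LEFT", "BACK", "RIGHT"), region)
      target <- others[1 + (self_u[ev_idx[k]] >= 0.5)]
      add_seg(t_ev)
      region <- target
    }
  }
  add_seg(stay_s)

  # re-derive sink flags per segment: a segment is sink-affected if it was
  # opened by a performed caregiver turn to a side that drew sink-back
  seg_df <- data.frame(start_s = seg_from,
                       end_s = c(seg_from[-1], stay_s),
                       region = seg_region, stringsAsFactors = FALSE)
  seg_df$sink <- FALSE
  done_sched <- which(miss_u >= config$miss_probability)
  for (k in done_sched) {
    t_ev <- sched_t[k]
    if (t_ev >= stay_s) next
    i <- which(seg_df$start_s == t_ev)
    if (length(i) == 1 && seg_df$region[i] %in% c("LEFT", "RIGHT") &&
        sink_u[k] < config$sink_back_prob)
      seg_df$sink[i] <- TRUE
  }

  # --- emit samples ---
  t_s <- seq(0, stay_s - dt, by = dt)
  seg_of <- findInterval(t_s, seg_df$start_s)
  base_angle <- REGION_ANGLE[seg_df$region[seg_of]]
  elapsed <- t_s - seg_df$start_s[seg_of]
  decay <- seg_df$sink[seg_of]
  hl_s <- config$sink_back_halflife_min * 60
  base_angle[decay] <- base_angle[decay] * 2^(-elapsed[decay] / hl_s)
  angle <- as.numeric(base_angle) + noise

  posture <- rep("in_bed", length(t_s))
  for (d in seq_len(n_days)) {
    if (up_len <= 0) break
    day0 <- (d - 1) * 86400 - start_day_s  # trace-relative start of day d
    win0 <- day0 + 8 * 3600
    L <- min(up_len, 12 * 3600)
    u0 <- win0 + up_start_u[d] * (12 * 3600 - L)
    u0 <- floor(u0 / dt) * dt
    posture[t_s >= u0 & t_s < u0 + L] <- "upright"
  }

  trace <- patient_trace(t_s, angle, posture, patient_id = patient_id,
                         start_time = start_time, sample_interval_s = dt)

  # --- exemptions: place without overlap, clipped to the stay ---
  ex <- exemption_intervals()
  if (n_ex > 0) {
    starts <- sort(floor(ex_start_u * stay_s / dt) * dt)
    keep_s <- numeric(); keep_e <- numeric()
    last_end <- -Inf
    for (i in seq_len(n_ex)) {
      a <- max(starts[i], last_end)
      b <- min(a + ex_dur[i], stay_s)
      if (b > a) {
        keep_s <- c(keep_s, a); keep_e <- c(keep_e, b)
        last_end <- b
      }
    }
    if (length(keep_s))
      ex <- exemption_intervals(keep_s, keep_e,
                                sample(c("refused", "off_unit", "clinical"),
                                       length(keep_s), replace = TRUE))
  }

  record <- data.frame(patient_id = patient_id, phase = config$phase,
                       age = age, sex = sex, braden = braden,
                       isolation = isolation, monitored_h = stay_s / 3600,
                       stringsAsFactors = FALSE)
  list(trace = trace, exemptions = ex, record = record)
}

#' Simulate a monitored cohort
#'
#' Derives one deterministic seed per patient from \code{config$seed} and
#' calls [simulate_patient()] for each.
#'
#' @param config A [simulation_config()].
#' @return List with \code{traces}, \code{exemptions} (named lists keyed by
#'   patient id) and \code{records} (one data frame).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_patients < 1) stop("n_patients must be >= 1")
  ids <- sprintf("%s-%03d", toupper(substr(config$phase, 1, 1)),
                 seq_len(config$n_patients))
  seeds <- (config$seed + 777771L * seq_len(config$n_patients)) %% 2147483629L
  out <- lapply(seq_len(config$n_patients), function(i)
    simulate_patient(config, patient_seed = seeds[i], patient_id = ids[i]))
  traces <- lapply(out, `[[`, "trace")
  exemptions <- lapply(out, `[[`, "exemptions")
  names(traces) <- names(exemptions) <- ids
  records <- do.call(rbind, lapply(out, `[[`, "record"))
  list(traces = traces, exemptions = exemptions, records = records)
}

#' Score a simulated cohort with the compliance engine
#'
#' Convenience wrapper: runs [compliance_timeline()] over every trace of a
#' cohort.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param engine An [engine_config()].
#' @return Named list of [compliance_timeline()] objects.
#' @export
score_cohort <- function(cohort, engine = engine_config()) {
  mapply(function(tr, ex) compliance_timeline(tr, ex, engine),
         cohort$traces, cohort$exemptions, SIMPLIFY = FALSE)
}

#' Calibrate baseline/post regimes to target pooled compliances
#'
#' Finds, by bisection on \code{miss_probability} over seeded calibration
#' cohorts, two simulation configurations whose pooled engine compliance
#' approximates the requested targets (e.g. a 64% baseline and a 98%
#' post-intervention regime). Both phases share all parameters except the
#' miss probability and demographics.
#'
#' @param target_low,target_high Pooled compliance targets in (0, 1],
#'   \code{target_low < target_high}.
#' @param base_config Template [simulation_config()]; its miss probability is
#'   ignored.
#' @param n_calib Patients per calibration cohort.
#' @param engine An [engine_config()].
#' @param tol Bisection stops once pooled compliance is within \code{tol} of
#'   the target (or the bracket is exhausted).
#' @param post_demographics Demographics list for the post regime.
#' @return List with elements \code{baseline} and \code{post}
#'   (simulation_configs) plus \code{achieved}, the calibration-cohort pooled
#'   compliances.
#' @export
make_phase_regimes <- function(target_low, target_high,
                               base_config = simulation_config(),
                               n_calib = 24,
                               engine = engine_config(),
                               tol = 0.01,
                               post_demographics = list(
                                 age_mean = 63, age_sd = 18,
                                 female_prob = 0.56,
                                 braden_mean = 19.9, braden_sd = 2.2,
                                 isolation_prob = 5 / 63)) {
  if (!(target_low > 0 && target_low < target_high && target_high <= 1))
    stop("targets must satisfy 0 < target_low < target_high <= 1")
  eval_m <- function(m) {
    cfg <- base_config
    cfg$miss_probability <- m
    cfg$n_patients <- as.integer(n_calib)
    tls <- score_cohort(simulate_cohort(cfg), engine)
    phase_compliance(tls)
  }
  calibrate <- function(target) {
    lo <- 0; hi <- 1
    c_lo <- eval_m(0); c_hi <- eval_m(1)   # compliance decreasing in m
    if (target > c_lo + 0.05 || target < c_hi - 0.05)
      stop(sprintf(
        "target %.3f unattainable: pooled compliance spans [%.3f, %.3f]",
        target, c_hi, c_lo))
    if (target >= c_lo) return(list(m = 0, achieved = c_lo))
    if (target <= c_hi) return(list(m = 1, achieved = c_hi))
    for (i in 1:20) {
      mid <- (lo + hi) / 2
      cm <- eval_m(mid)
      if (abs(cm - target) <= tol) return(list(m = mid, achieved = cm))
      if (cm > target) lo <- mid else hi <- mid
      if (hi - lo < 1e-3) break
    }
    mid <- (lo + hi) / 2
    list(m = mid, achieved = eval_m(mid))
  }
  low <- calibrate(target_low)
  high <- calibrate(target_high)
  baseline <- base_config
  baseline$miss_probability <- low$m
  baseline$phase <- "baseline"
  post <- base_config
  post$miss_probability <- high$m
  post$phase <- "post"
  post$demographics <- post_demographics
  post$seed <- base_config$seed + 1L
  list(baseline = baseline, post = post,
       achieved = c(baseline = low$achieved, post = high$achieved))
}
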