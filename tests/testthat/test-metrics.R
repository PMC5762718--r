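# Compliance metrics on constructed timelines (hand arithmetic) and on
# simulated cohorts (algebraic invariants).

make_tl <- function(states, durations_min,
                    start_time = as.POSIXct("2013-05-01 00:00:00", tz = "UTC"),
                    patient_id = "T1") {
  ends <- cumsum(durations_min) * 60
  tl <- data.frame(start_s = c(0, ends[-length(ends)]), end_s = ends,
                   state = states,
                   display = ifelse(states == "NONCOMPLIANT", "RED",
                                    ifelse(states == "EXEMPT", "NONE", "GREEN")),
                   block = 1L, stringsAsFactors = FALSE)
  attr(tl, "patient_id") <- patient_id
  attr(tl, "start_time") <- start_time
  class(tl) <- c("compliance_timeline", "data.frame")
  tl
}

test_that("per-patient compliance is compliant over monitored time", {
  expect_equal(patient_compliance(make_tl("COMPLIANT", 120)), 1.0)
  # 135 compliant + 65 non-compliant minutes: 135/200
  tl <- make_tl(c("COMPLIANT", "NONCOMPLIANT"), c(135, 65))
  expect_equal(patient_compliance(tl), 0.675)
  # 100 h with 36 h non-compliant: the 64% construction
  tl <- make_tl(c("COMPLIANT", "NONCOMPLIANT"), c(64, 36) * 60)
  expect_equal(patient_compliance(tl), 0.64)
})

test_that("exempt time is compliant-equivalent by default, removable by option", {
  tl <- make_tl(c("COMPLIANT", "EXEMPT", "NONCOMPLIANT"), c(60, 60, 60))
  expect_equal(patient_compliance(tl), 2 / 3)
  expect_equal(patient_compliance(tl, exempt = "exclude"), 1 / 2)
})

test_that("phase compliance pools by time, not by patient", {
  a <- make_tl(c("COMPLIANT", "NONCOMPLIANT"), c(50, 50) * 60, patient_id = "A")
  b <- make_tl("COMPLIANT", 100 * 60, patient_id = "B")
  expect_equal(phase_compliance(list(a, b)), 150 / 200)
  # unequal monitored time separates pooling from the mean of fractions
  c2 <- make_tl("COMPLIANT", 10 * 60, patient_id = "C")
  expect_equal(phase_compliance(list(a, c2)), 60 / 110)
  expect_false(isTRUE(all.equal(phase_compliance(list(a, c2)),
                                mean(c(0.5, 1)))))
  expect_equal(phase_compliance(list(b, c2)), 1.0)
})

test_that("phase compliance equals the time-weighted mean of patient fractions", {
  cfg <- simulation_config(n_patients = 6, seed = 31, mean_stay_h = 24)
  tls <- score_cohort(simulate_cohort(cfg))
  per <- vapply(tls, patient_compliance, numeric(1))
  w <- vapply(tls, function(tl) sum(tl$end_s - tl$start_s), numeric(1))
  expect_equal(phase_compliance(tls), sum(per * w) / sum(w))
})

test_that("block adherence counts fully compliant hours per 100-h block", {
  # 100 fully compliant hours
  tl <- make_tl("COMPLIANT", 100 * 60)
  expect_equal(block_adherence(list(tl)), 1.0)
  # 64 clean hours, 36 hours each carrying non-compliance
  states <- rep(c("COMPLIANT", "NONCOMPLIANT"), 36)
  durs <- rep(c(30, 30), 36)
  tl <- make_tl(c(rep("COMPLIANT", 1), states, rep("COMPLIANT", 1)),
                c(32 * 60, durs, 32 * 60))
  expect_equal(block_adherence(list(tl)), 0.64)
  # 250 hours -> 2 blocks, trailing 50 dropped
  tl <- make_tl("COMPLIANT", 250 * 60)
  expect_length(block_adherence(list(tl)), 2L)
  expect_error(block_adherence(list(make_tl("COMPLIANT", 50 * 60))),
               "patient-hours")
})

test_that("hour attribution needs 30 min of monitoring within the hour", {
  # starts 20 min past the hour: first partial hour (40 min) still counts,
  # a 25-min tail does not
  t0 <- as.POSIXct("2013-05-01 10:20:00", tz = "UTC")
  tl <- make_tl("COMPLIANT", 100 * 60 + 5, start_time = t0)
  ph <- turnwatch:::patient_hours(list(tl))
  expect_equal(nrow(ph), 100L)  # 40-min head hour + 99 full hours; 25-min tail dropped
})

test_that("hourly compliance pools by hour of day and marks empty bins NA", {
  t0 <- as.POSIXct("2013-05-01 00:00:00", tz = "UTC")
  # fully compliant two-day stay: every bin 1.0
  tl <- make_tl("COMPLIANT", 48 * 60, start_time = t0)
  expect_equal(unname(hourly_compliance(list(tl))), rep(1, 24))
  # non-compliance only 02:00-04:00 each day
  states <- rep(c("COMPLIANT", "NONCOMPLIANT", "COMPLIANT"), 2)
  durs <- rep(c(2 * 60, 2 * 60, 20 * 60), 2)
  tl <- make_tl(states, durs, start_time = t0)
  hc <- hourly_compliance(list(tl))
  expect_equal(unname(hc[c("02", "03")]), c(0, 0))
  expect_equal(unname(hc[setdiff(names(hc), c("02", "03"))]), rep(1, 22))
  # monitored 10:00-11:00 only: 23 NA bins
  tl <- make_tl("COMPLIANT", 60,
                start_time = as.POSIXct("2013-05-01 10:00:00", tz = "UTC"))
  hc <- hourly_compliance(list(tl))
  expect_equal(sum(is.na(hc)), 23L)
  expect_equal(unname(hc[["10"]]), 1)
})

test_that("hourly compliance bins average back to the pooled compliance", {
  cfg <- simulation_config(n_patients = 5, seed = 77, mean_stay_h = 30)
  tls <- score_cohort(simulate_cohort(cfg))
  hc <- hourly_compliance(tls)
  # recompute bin weights (monitored seconds per bin) the slow way
  den <- numeric(24)
  for (tl in tls) {
    t0 <- as.numeric(attr(tl, "start_time"))
    for (i in seq_len(nrow(tl))) {
      lo <- t0 + tl$start_s[i]; b <- t0 + tl$end_s[i]
      while (lo < b) {
        hi <- min(b, (floor(lo / 3600) + 1) * 3600)
        bin <- (floor(lo / 3600) %% 24) + 1
        den[bin] <- den[bin] + (hi - lo)
        lo <- hi
      }
    }
  }
  expect_equal(sum(hc * den, na.rm = TRUE) / sum(den), phase_compliance(tls))
  expect_true(all(hc >= 0 & hc <= 1, na.rm = TRUE))
})

test_that("metrics are invariant to splitting timeline intervals", {
  tl <- make_tl(c("COMPLIANT", "NONCOMPLIANT", "EXEMPT"), c(300, 90, 210))
  split_tl <- make_tl(c("COMPLIANT", "COMPLIANT", "NONCOMPLIANT",
                        "NONCOMPLIANT", "EXEMPT", "EXEMPT"),
                      c(100, 200, 45, 45, 110, 100))
  expect_equal(patient_compliance(tl), patient_compliance(split_tl))
  expect_equal(block_adherence(list(tl), 10), block_adherence(list(split_tl), 10))
  expect_equal(hourly_compliance(list(tl)), hourly_compliance(list(split_tl)))
})

test_that("phase_summary assembles counts, hours and all three metrics", {
  cfg <- simulation_config(n_patients = 4, seed = 8, mean_stay_h = 30)
  coh <- simulate_cohort(cfg)
  s <- phase_summary(score_cohort(coh), coh$records, phase = "baseline")
  expect_equal(s$n_patients, 4L)
  expect_length(s$per_patient_compliance, 4L)
  expect_length(s$hourly_compliance, 24L)
  expect_equal(s$monitored_h, sum(s$patient_monitored_h))
  expect_true(all(s$per_patient_compliance >= 0 &
                    s$per_patient_compliance <= 1))
})
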