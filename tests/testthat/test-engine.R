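# Region classification, segmentation, turn detection, timeline rules.

min_trace <- function(minutes_angle, dt = 10, posture = "in_bed") {
  # minutes_angle: matrix-like list of c(minutes, angle)
  ang <- unlist(lapply(minutes_angle, function(x) rep(x[2], x[1] * 60 / dt)))
  patient_trace(seq(0, length(ang) * dt - dt, by = dt), ang,
                posture = posture, sample_interval_s = dt)
}

test_that("region classifier maps the +/-20 degree band inclusively to back", {
  expect_identical(classify_region(25), "RIGHT")
  expect_identical(classify_region(21), "RIGHT")
  expect_identical(classify_region(20), "BACK")
  expect_identical(classify_region(0), "BACK")
  expect_identical(classify_region(-20), "BACK")
  expect_identical(classify_region(-21), "LEFT")
  expect_identical(classify_region(45, posture = "upright"), "UPRIGHT")
  expect_error(classify_region(NaN), "finite")
  expect_error(classify_region(0, posture = "sitting"), "posture")
})

test_that("segmentation merges runs and absorbs sub-debounce excursions", {
  # constant back for 1 h: one interval of 3600 s
  tr <- min_trace(list(c(60, 0)))
  segs <- segment_regions(tr)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$end_s - segs$start_s, 3600)
  expect_identical(segs$region, "BACK")

  # single 10-s excursion to the left is absorbed
  ang <- c(rep(0, 180), -30, rep(0, 180))
  tr <- patient_trace(seq(0, length(ang) * 10 - 10, 10), ang)
  segs <- segment_regions(tr)
  expect_equal(nrow(segs), 1L)
  expect_identical(segs$region, "BACK")

  # a 30/30 min split registers the change at 1800 s
  tr <- min_trace(list(c(30, 0), c(30, -45)))
  segs <- segment_regions(tr)
  expect_equal(segs$start_s, c(0, 1800))
  expect_identical(segs$region, c("BACK", "LEFT"))
})

test_that("turn qualification requires the 15-min decompression of the vacated region", {
  # back 60 min -> left 15 min: qualifying, decompressed at +900 s
  tr <- min_trace(list(c(60, 0), c(15, -45)))
  ev <- detect_turns(segment_regions(tr))
  expect_equal(nrow(ev), 1L)
  expect_true(ev$qualifying)
  expect_equal(ev$t_qualified, ev$t_change + 900)

  # back 60 -> left 10 -> back: non-qualifying, back clock resumes at 60 min
  tr <- min_trace(list(c(60, 0), c(10, -45), c(80, 0)))
  ev <- detect_turns(segment_regions(tr))
  expect_false(ev$qualifying[1])
  tl <- compliance_timeline(tr)
  # back sustained resumes at 60 min, so 135 min is hit 75 min after return
  nc <- tl[tl$state == "NONCOMPLIANT", ]
  expect_equal(nrow(nc), 1L)
  expect_equal(nc$start_s, (60 + 10 + 75) * 60 - 10)

  # single region: no events
  tr <- min_trace(list(c(90, 0)))
  expect_equal(nrow(detect_turns(segment_regions(tr))), 0L)
})

test_that("non-compliance begins once 135 min accumulate on one side", {
  tl <- compliance_timeline(min_trace(list(c(134, 0))))
  expect_equal(unname(state_times(tl)[["NONCOMPLIANT"]]), 0)

  tl <- compliance_timeline(min_trace(list(c(200, 0))))
  tt <- state_times(tl)
  # flagged from the reading in which minute 135 is reached
  expect_equal(unname(tt[["NONCOMPLIANT"]]), (200 - 135) * 60 + 10)
  expect_equal(sum(tt), 200 * 60)
  expect_equal(patient_compliance(tl), (135 * 60 - 10) / (200 * 60))
  # within one sampling interval of the idealized 135/200
  expect_lt(abs(patient_compliance(tl) - 135 / 200), 10 / (200 * 60) + 1e-12)
})

test_that("exemptions override non-compliant time and display", {
  tr <- min_trace(list(c(200, 0)))
  ex <- exemption_intervals(120 * 60, 200 * 60, "refused")
  tl <- compliance_timeline(tr, ex)
  tt <- state_times(tl)
  expect_equal(unname(tt[["NONCOMPLIANT"]]), 0)
  expect_equal(unname(tt[["EXEMPT"]]), 80 * 60)
  expect_true(all(tl$display[tl$state == "EXEMPT"] == "NONE"))
  expect_error(
    compliance_timeline(tr, exemption_intervals(c(0, 1800), c(3600, 5400))),
    "overlap")
  expect_error(compliance_timeline(tr, exemption_intervals(0, 300 * 60)),
               "span")
})

test_that("display turns red before the compliance metric penalises", {
  expect_identical(display_state(104), "GREEN")
  expect_identical(display_state(105), "YELLOW")
  expect_identical(display_state(110), "YELLOW")
  expect_identical(display_state(120), "YELLOW")
  expect_identical(display_state(121), "RED")
  expect_error(display_state(-1), "non-negative")

  # at 125 min sustained the display is red but the state still compliant
  tl <- compliance_timeline(min_trace(list(c(125, 0))))
  last <- tl[nrow(tl), ]
  expect_identical(last$display, "RED")
  expect_identical(last$state, "COMPLIANT")
})

test_that("upright time is compliant and resets all region clocks", {
  # back 130 min, upright 10 min, back 130 min: never non-compliant
  ang <- c(rep(0, 130 * 6), rep(0, 10 * 6), rep(0, 130 * 6))
  post <- c(rep("in_bed", 130 * 6), rep("upright", 10 * 6),
            rep("in_bed", 130 * 6))
  tr <- patient_trace(seq(0, length(ang) * 10 - 10, 10), ang, post)
  tl <- compliance_timeline(tr)
  expect_equal(unname(state_times(tl)[["NONCOMPLIANT"]]), 0)
})

test_that("sampling gaps beyond 5 min split monitoring and restart clocks", {
  t1 <- seq(0, 100 * 60 - 10, 10)
  t2 <- seq(130 * 60, 230 * 60 - 10, 10)  # 30-min dropout
  tr <- patient_trace(c(t1, t2), 0)
  tl <- compliance_timeline(tr)
  tt <- state_times(tl)
  expect_equal(sum(tt), 200 * 60)            # gap excluded from monitored time
  expect_equal(unname(tt[["NONCOMPLIANT"]]), 0)  # each block only 100 min
  expect_equal(length(unique(tl$block)), 2L)
})

test_that("interval engine matches the per-sample oracle on random traces", {
  for (seed in 1:40)
    expect_engine_matches_oracle(seed, hours = 12,
                                 n_exempt = seed %% 3)
})

test_that("monitored time is conserved across states", {
  for (seed in 1:10) {
    rt <- random_trace(seed + 100, hours = 12, n_exempt = 2)
    tl <- compliance_timeline(rt$trace, rt$exemptions)
    expect_equal(sum(state_times(tl)),
                 max(rt$trace$t_s) + 10 - min(rt$trace$t_s))
  }
})

test_that("display is red whenever the state is non-compliant", {
  for (seed in 41:55) {
    rt <- random_trace(seed, hours = 18)
    tl <- compliance_timeline(rt$trace, rt$exemptions)
    nc <- tl$state == "NONCOMPLIANT"
    expect_true(all(tl$display[nc] == "RED"))
  }
})

test_that("removing a qualifying turn never increases compliant time", {
  # with the turn: back 120 -> left 20 -> back 120; without: back 260
  with_turn <- min_trace(list(c(120, 0), c(20, -45), c(120, 0)))
  without <- min_trace(list(c(260, 0)))
  ct <- function(tr) state_times(compliance_timeline(tr))[["COMPLIANT"]]
  expect_gt(ct(with_turn), ct(without))
})

test_that("noiseless region traces classify exactly under sub-threshold noise", {
  set.seed(1)
  ang <- rep(c(0, -45, 45), each = 600) + rnorm(1800, 0, 3)
  tr <- patient_trace(seq(0, 1800 * 10 - 10, 10), ang)
  segs <- segment_regions(tr)
  expect_identical(segs$region, c("BACK", "LEFT", "RIGHT"))
})
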