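#' Engine configuration for the turn-detection and compliance rules
#'
#' Bundles the clinical protocol parameters the compliance engine applies to a
#' position trace. Defaults reproduce a standard 2-hour adult turning protocol
#' monitored at 10-second resolution:
#' \itemize{
#'   \item \code{turn_period_min}: maximum time allowed on one side before a
#'     turn is due (120 min).
#'   \item \code{grace_min}: extra minutes added to the turn period in
#'     compliance *calculations only* (15 min), so non-compliant time first
#'     accrues once 135 min are accumulated on a side. The bedside display
#'     never applies the grace period.
#'   \item \code{decompression_min}: continuous offload a vacated body region
#'     needs before the position change counts as a qualifying turn (15 min).
#'   \item \code{angle_threshold_deg}: roll-angle threshold separating back
#'     from side-lying (20 degrees; the +/-20 boundary itself counts as back).
#'   \item \code{green_window_min}: sustained time below which the display is
#'     green, i.e. "turned within the past hour and 45 min" (105 min). Between
#'     \code{green_window_min} and \code{turn_period_min} the display is the
#'     yellow warning; beyond the turn period it is red (overdue).
#'   \item \code{sample_interval_s}: nominal sensor sampling interval (10 s).
#'   \item \code{debounce_min}: minimum persistence for a region change to
#'     register; shorter excursions are absorbed (1 min).
#'   \item \code{max_gap_min}: sampling gaps longer than this are treated as
#'     unmonitored time and split the trace into independent blocks (5 min);
#'     all sustained-time clocks restart at a block boundary.
#' }
#'
#' @param turn_period_min Turn period in minutes.
#' @param grace_min Grace period in minutes (compliance metric only).
#' @param decompression_min Required continuous offload in minutes.
#' @param angle_threshold_deg Turn-angle threshold in degrees.
#' @param green_window_min Green display window in minutes; defaults to
#'   \code{turn_period_min - 15}, keeping a 15-minute warning window.
#' @param sample_interval_s Sampling interval in seconds; must divide 60.
#' @param debounce_min Debounce persistence in minutes.
#' @param max_gap_min Maximum tolerated sampling gap in minutes.
#' @return An object of class \code{engine_config} (a named list).
#' @examples
#' cfg <- engine_config()
#' cfg$turn_period_min + cfg$grace_min  # non-compliance onset, minutes
#' @export
engine_config <- function(turn_period_min = 120,
                          grace_min = 15,
                          decompression_min = 15,
                          angle_threshold_deg = 20,
                          green_window_min = turn_period_min - 15,
                          sample_interval_s = 10,
                          debounce_min = 1,
                          max_gap_min = 5) {
  cfg <- list(
    turn_period_min = as.numeric(turn_period_min),
    grace_min = as.numeric(grace_min),
    decompression_min = as.numeric(decompression_min),
    angle_threshold_deg = as.numeric(angle_threshold_deg),
    green_window_min = as.numeric(green_window_min),
    sample_interval_s = as.numeric(sample_interval_s),
    debounce_min = as.numeric(debounce_min),
    max_gap_min = as.numeric(max_gap_min)
  )
  if (!all(vapply(cfg, function(x) length(x) == 1 && is.finite(x), logical(1))))
    stop("engine_config: all parameters must be single finite numbers")
  if (cfg$turn_period_min <= 0) stop("turn_period_min must be > 0")
  if (cfg$grace_min < 0) stop("grace_min must be >= 0")
  if (cfg$decompression_min <= 0) stop("decompression_min must be > 0")
  if (cfg$angle_threshold_deg <= 0) stop("angle_threshold_deg must be > 0")
  if (cfg$green_window_min <= 0 || cfg$green_window_min >= cfg$turn_period_min)
    stop("green_window_min must satisfy 0 < green_window_min < turn_period_min")
  if (cfg$sample_interval_s <= 0 || 60 %% cfg$sample_interval_s != 0)
    stop("sample_interval_s must be positive and divide 60 s evenly")
  if (cfg$debounce_min < 0) stop("debounce_min must be >= 0")
  if (cfg$max_gap_min <= 0) stop("max_gap_min must be > 0")
  class(cfg) <- "engine_config"
  cfg
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  cat(sprintf("  turn period     : %g min (+%g min grace => non-compliance at %g min)\n",
              x$turn_period_min, x$grace_min, x$turn_period_min + x$grace_min))
  cat(sprintf("  decompression   : %g min\n", x$decompression_min))
  cat(sprintf("  angle threshold : +/-%g deg\n", x$angle_threshold_deg))
  cat(sprintf("  display         : green < %g min, yellow %g-%g min, red > %g min\n",
              x$green_window_min, x$green_window_min, x$turn_period_min,
              x$turn_period_min))
  cat(sprintf("  sampling        : %g s, debounce %g min, max gap %g min\n",
              x$sample_interval_s, x$debounce_min, x$max_gap_min))
  invisible(x)
}

#' Classify a roll angle into a body-region
#'
#' Maps a signed transverse-plane roll angle (positive = patient's right) and a
#' posture flag to one of the regions \code{LEFT}, \code{BACK}, \code{RIGHT},
#' \code{UPRIGHT}. Angles strictly greater than \code{+threshold_deg} are
#' right side-lying, strictly less than \code{-threshold_deg} left side-lying,
#' and the closed band \code{[-threshold_deg, +threshold_deg]} is back
#' (boundary angles count as back). Upright posture overrides the angle.
#'
#' @param angle_deg Numeric vector of roll angles in degrees.
#' @param posture Character vector, \code{"in_bed"} or \code{"upright"}
#'   (recycled if length 1).
#' @param threshold_deg Turn-angle threshold in degrees (default 20).
#' @return Character vector of regions.
#' @examples
#' classify_region(c(-45, 0, 20, 25), "in_bed")
#' @export
classify_region <- function(angle_deg, posture = "in_bed", threshold_deg = 20) {
  if (!is.numeric(angle_deg) || any(!is.finite(angle_deg)))
    stop("classify_region: angle_deg must be finite numeric")
  if (length(posture) == 1) posture <- rep(posture, length(angle_deg))
  if (length(posture) != length(angle_deg))
    stop("classify_region: posture must have length 1 or length(angle_deg)")
  bad <- !posture %in% c("in_bed", "upright")
  if (any(bad)) stop("classify_region: posture must be 'in_bed' or 'upright'")
  out <- rep("BACK", length(angle_deg))
  out[angle_deg > threshold_deg] <- "RIGHT"
  out[angle_deg < -threshold_deg] <- "LEFT"
  out[posture == "upright"] <- "UPRIGHT"
  out
}

#' Bedside display state for a sustained time
#'
#' Pure display rule used at the nurses' station: green while the patient was
#' turned within the green window, yellow while compliant but due for a turn
#' within 15 minutes, red once the turn period is exceeded. The grace period is
#' deliberately *not* applied here; it affects only the compliance metric, so
#' the display turns red (at >120 min) before non-compliant time starts to
#' accrue (at 135 min).
#'
#' @param sustained_min Non-negative numeric vector: minutes accumulated on the
#'   current side since the last qualifying turn.
#' @param config An [engine_config()].
#' @return Character vector in \code{c("GREEN", "YELLOW", "RED")}.
#' @examples
#' display_state(c(0, 104, 105, 120, 121))
#' @export
display_state <- function(sustained_min, config = engine_config()) {
  if (!is.numeric(sustained_min) || any(!is.finite(sustained_min)) ||
      any(sustained_min < 0))
    stop("display_state: sustained_min must be non-negative and finite")
  out <- rep("YELLOW", length(sustained_min))
  out[sustained_min < config$green_window_min] <- "GREEN"
  out[sustained_min > config$turn_period_min] <- "RED"
  out
}
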