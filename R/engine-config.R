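#' Engine configuration
#'
#' All numeric rules of the geofence-triggered support (GTS) engine live
#' here.  Defaults encode the behaviour of the deployed intervention:
#' geofences around locations where smoking is reported more than once, a
#' 5-minute dwell before any trigger decision, re-decisions every 3 hours of
#' continued presence, an 08:00-21:30 local delivery window, a 28-day
#' abstinence challenge followed by two maintenance months in which message
#' frequency halves each month, and a hard stop 3 months after the quit
#' date.
#'
#' @param fence_radius_m geofence radius in meters.  The deployed radius is
#'   not public; 100 m is a typical urban geofence scale.
#' @param min_reports_for_fence smoking reports at a location before a
#'   geofence is created ("reported more than once" = 2).
#' @param min_dwell_minutes continuous minutes inside a fence before the
#'   first trigger decision.
#' @param redecision_interval_hours hours between successive decisions while
#'   remaining in a fence; also the per-fence message cooldown.
#' @param active_window local clock window (minutes past midnight,
#'   `c(start, end)`) in which messages may fire.
#' @param stage2_duration_days length of the abstinence challenge.
#' @param stage3_duration_months maintenance months after the challenge.
#' @param monthly_decay_factor per-month multiplier on maintenance trigger
#'   probability (0.5 = halves every month).
#' @param support_stop_months months post-quit after which GTS stops.
#' @param trigger_threshold minimum smoking-report tally in the current
#'   time-of-day bin for a fence to fire.
#' @param relapse_episodes_per_day_gt relapse requires strictly more than
#'   this many reported episodes per day...
#' @param relapse_consecutive_days ...on this many consecutive days.
#' @param month_length_days days per "month" for stage arithmetic.
#' @param tz IANA timezone governing the local clock rules for this user.
#' @return an object of class `engine_config`.
#' @examples
#' cfg <- engine_config()
#' cfg$fence_radius_m
#' @export
engine_config <- function(fence_radius_m = 100,
                          min_reports_for_fence = 2L,
                          min_dwell_minutes = 5,
                          redecision_interval_hours = 3,
                          active_window = c(8 * 60, 21 * 60 + 30),
                          stage2_duration_days = 28,
                          stage3_duration_months = 2,
                          monthly_decay_factor = 0.5,
                          support_stop_months = 3,
                          trigger_threshold = 2L,
                          relapse_episodes_per_day_gt = 1L,
                          relapse_consecutive_days = 2L,
                          month_length_days = 30,
                          tz = "UTC") {
  cfg <- list(
    fence_radius_m = fence_radius_m,
    min_reports_for_fence = as.integer(min_reports_for_fence),
    min_dwell_minutes = min_dwell_minutes,
    redecision_interval_hours = redecision_interval_hours,
    active_window = active_window,
    stage2_duration_days = stage2_duration_days,
    stage3_duration_months = stage3_duration_months,
    monthly_decay_factor = monthly_decay_factor,
    support_stop_months = support_stop_months,
    trigger_threshold = as.integer(trigger_threshold),
    relapse_episodes_per_day_gt = as.integer(relapse_episodes_per_day_gt),
    relapse_consecutive_days = as.integer(relapse_consecutive_days),
    month_length_days = month_length_days,
    tz = tz
  )
  validate_engine_config(cfg)
  structure(cfg, class = "engine_config")
}

validate_engine_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      fence_radius_m > 0, min_reports_for_fence >= 1,
      min_dwell_minutes > 0, redecision_interval_hours > 0,
      stage2_duration_days > 0, stage3_duration_months > 0,
      support_stop_months > 0, month_length_days > 0,
      trigger_threshold >= 1, relapse_consecutive_days >= 1,
      monthly_decay_factor > 0, monthly_decay_factor <= 1,
      length(active_window) == 2, active_window[1] < active_window[2],
      active_window[1] >= 0, active_window[2] < 1440
    )
  })
  invisible(cfg)
}

#' @export
print.engine_config <- function(x, ...) {
  cat("<engine_config>\n")
  cat(sprintf("  fence radius %gm; fence at >=%d reports; dwell >=%g min\n",
              x$fence_radius_m, x$min_reports_for_fence, x$min_dwell_minutes))
  cat(sprintf("  re-decide every %gh; window %02d:%02d-%02d:%02d local (%s)\n",
              x$redecision_interval_hours,
              x$active_window[1] %/% 60, x$active_window[1] %% 60,
              x$active_window[2] %/% 60, x$active_window[2] %% 60, x$tz))
  cat(sprintf("  stage 2 %g days; maintenance decay %g/month; stop at %g months\n",
              x$stage2_duration_days, x$monthly_decay_factor,
              x$support_stop_months))
  invisible(x)
}
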