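# The geofence-triggered support (GTS) engine.
#
# Life cycle of a user:
#   training    -- before the quit date, smoking reports teach the engine
#                  where smoking happens; >=2 reports within the fence
#                  radius of each other create a geofence.
#   committed   -- the 28-day abstinence challenge: location fixes are
#                  monitored, and >=5 minutes of continuous dwell inside a
#                  fence prompts a trigger decision (then again every 3 h).
#   maintenance -- two further months with trigger probability halving each
#                  month.
#   stopped     -- 3 months post-quit, support ends (unless the quit
#                  attempt is restarted).

SITUATIONS <- c("home", "work", "working_from_home", "socializing", "other")
STAGES <- c("training", "committed", "maintenance", "stopped")
DECISION_REASONS <- c("outside_window", "below_threshold", "cooldown",
                      "decayed_out", "stopped", "fired")
N_BINS <- 8L

#' Construct a location fix event
#'
#' @param time `POSIXct` timestamp.
#' @param lat,lon position in decimal degrees.
#' @param accuracy_m reported positional accuracy (meters, `>= 0`).  The
#'   engine treats fixes as exact; accuracy is carried for simulation noise
#'   models only.
#' @return a `location_fix` event.
#' @export
location_fix <- function(time, lat, lon, accuracy_m = 10) {
  stopifnot(inherits(time, "POSIXct"), length(time) == 1,
            is.finite(lat), lat >= -90, lat <= 90,
            is.finite(lon), lon >= -180, lon < 180,
            accuracy_m >= 0)
  structure(list(kind = "fix", time = time, lat = lat, lon = lon,
                 accuracy_m = accuracy_m),
            class = c("location_fix", "jitai_event"))
}

#' Construct a smoking report event
#'
#' A self-reported smoking episode with its situational context (urge
#' strength, stress, mood, situation, presence of other smokers).  Location
#' may be absent if no fix was available when the report was made.
#'
#' @param time `POSIXct` timestamp.
#' @param lat,lon report location (decimal degrees) or `NA` if unavailable.
#' @param urge_strength ordinal 0-5.
#' @param stress,mood ordinal 0-5.
#' @param situation one of `"home"`, `"work"`, `"working_from_home"`,
#'   `"socializing"`, `"other"`.
#' @param others_present were other smokers present?
#' @return a `smoking_report` event.
#' @export
smoking_report <- function(time, lat = NA_real_, lon = NA_real_,
                           urge_strength = 3L, stress = 2L, mood = 2L,
                           situation = "other", others_present = FALSE) {
  stopifnot(inherits(time, "POSIXct"), length(time) == 1)
  if (!situation %in% SITUATIONS) {
    stop_jitai("invalid situation '%s'", situation, class = "jitai_validation")
  }
  for (v in list(urge = urge_strength, stress = stress, mood = mood)) {
    if (!is.finite(v) || v < 0 || v > 5) {
      stop_jitai("ordinal context fields must lie in 0..5",
                 class = "jitai_validation")
    }
  }
  structure(list(kind = "report", time = time, lat = lat, lon = lon,
                 urge_strength = as.integer(urge_strength),
                 stress = as.integer(stress), mood = as.integer(mood),
                 situation = situation,
                 others_present = isTRUE(others_present),
                 is_lapse = FALSE),
            class = c("smoking_report", "jitai_event"))
}

#' Construct a quit-date reset command
#'
#' @param time `POSIXct` timestamp of the command.
#' @param quit_date new quit `Date`.
#' @return a `quit_reset` event.
#' @export
quit_reset <- function(time, quit_date) {
  stopifnot(inherits(time, "POSIXct"), inherits(quit_date, "Date"))
  structure(list(kind = "reset", time = time, quit_date = quit_date),
            class = c("quit_reset", "jitai_event"))
}

#' Create a fresh engine state
#'
#' @param config an [engine_config()].
#' @param quit_date the user's quit `Date`, or `NULL` if not yet set.
#' @param seed integer seed for the deterministic maintenance-decay stream.
#' @return an object of class `engine_state`.
#' @export
engine_new <- function(config = engine_config(), quit_date = NULL,
                       seed = 1L) {
  structure(list(
    stage = "training",
    quit_date = quit_date,
    fences = list(),
    candidates = list(),
    dwell = list(),          # per fence id: entry, next_k
    fix_intervals = numeric(0),
    last_fix_time = NULL,
    last_event_time = NULL,
    daily_episode_counts = integer(0),  # named by date string
    messages_sent = data.frame(time = as.POSIXct(character(0), tz = "UTC"),
                               fence_id = character(0),
                               message_id = character(0),
                               stringsAsFactors = FALSE),
    rng_seed = as.integer(seed)
  ), class = "engine_state")
}

#' @export
print.engine_state <- function(x, ...) {
  cat(sprintf("<engine_state> stage=%s quit_date=%s fences=%d candidates=%d messages=%d\n",
              x$stage,
              if (is.null(x$quit_date)) "unset" else format(x$quit_date),
              length(x$fences), length(x$candidates),
              nrow(x$messages_sent)))
  invisible(x)
}

new_fence <- function(id, lat, lon, config, created_at, source,
                      bins = integer(N_BINS), situations = NULL,
                      context = NULL, born = created_at) {
  if (is.null(situations)) {
    situations <- stats::setNames(integer(length(SITUATIONS)), SITUATIONS)
  }
  if (is.null(context)) {
    context <- c(strong_urge = 0L, stress = 0L, low_mood = 0L,
                 others_present = 0L)
  }
  list(id = id, lat = lat, lon = lon, radius_m = config$fence_radius_m,
       tally = bins, created_at = created_at, born = born, source = source,
       situations = situations, context = context)
}

check_ordering <- function(state, time) {
  if (!is.null(state$last_event_time) && time < state$last_event_time) {
    stop_jitai("out-of-order event at %s (last processed %s)",
               format(time), format(state$last_event_time),
               class = "jitai_ordering")
  }
}

report_context_increments <- function(report) {
  c(strong_urge = as.integer(report$urge_strength >= 4),
    stress = as.integer(report$stress >= 4),
    low_mood = as.integer(report$mood <= 1),
    others_present = as.integer(report$others_present))
}

#' Ingest a smoking report
#'
#' Assigns the report to the nearest existing geofence or candidate cluster
#' within the fence radius (ties broken by earliest creation), else opens a
#' new candidate.  A candidate reaching `min_reports_for_fence` reports is
#' promoted to a geofence centred on its first report.  Post-quit reports
#' are flagged as lapses and counted towards relapse detection, and lapse
#' locations grow fences exactly as training reports do.
#'
#' @param state an `engine_state`.
#' @param report a [smoking_report()].
#' @param config an [engine_config()].
#' @return the updated `engine_state`.
#' @export
ingest_smoking_report <- function(state, report, config = engine_config()) {
  stopifnot(inherits(state, "engine_state"), inherits(report, "smoking_report"))
  check_ordering(state, report$time)
  state$last_event_time <- report$time
  state <- advance_stage(state, report$time, config)

  post_quit <- !is.null(state$quit_date) &&
    local_date(report$time, config$tz) >= state$quit_date
  if (post_quit) {
    report$is_lapse <- TRUE
    d <- as.character(local_date(report$time, config$tz))
    state$daily_episode_counts[d] <-
      (if (d %in% names(state$daily_episode_counts))
         state$daily_episode_counts[[d]] else 0L) + 1L
  }

  if (is.na(report$lat) || is.na(report$lon)) return(state)

  bin <- time_bin(report$time, config)
  ctx <- report_context_increments(report)

  # nearest cluster (fence or candidate) within radius wins; exact ties go
  # to the earliest-born cluster (fences carry their founding report time)
  n_f <- length(state$fences)
  all_clusters <- c(state$fences, state$candidates)
  if (length(all_clusters) > 0) {
    d <- vapply(all_clusters, function(cl)
      haversine_m(cl$lat, cl$lon, report$lat, report$lon), numeric(1))
    born <- vapply(all_clusters, function(cl)
      as.numeric(cl$born %||% cl$first_at), numeric(1))
    ok <- which(d <= config$fence_radius_m)
    if (length(ok) > 0) {
      i <- ok[order(d[ok], born[ok])][1]
      if (i <= n_f) {
        f <- state$fences[[i]]
        f$tally[bin] <- f$tally[bin] + 1L
        f$situations[report$situation] <- f$situations[report$situation] + 1L
        f$context <- f$context + ctx
        state$fences[[i]] <- f
      } else {
        j <- i - n_f
        cl <- state$candidates[[j]]
        cl$count <- cl$count + 1L
        cl$bins[bin] <- cl$bins[bin] + 1L
        cl$situations[report$situation] <-
          cl$situations[report$situation] + 1L
        cl$context <- cl$context + ctx
        if (cl$count >= config$min_reports_for_fence) {
          id <- sprintf("f%03d", length(state$fences) + 1L)
          state$fences[[length(state$fences) + 1L]] <-
            new_fence(id, cl$lat, cl$lon, config,
                      created_at = report$time,
                      source = if (report$is_lapse) "lapse" else "pre_quit",
                      bins = cl$bins, situations = cl$situations,
                      context = cl$context, born = cl$first_at)
          state$candidates[[j]] <- NULL
        } else {
          state$candidates[[j]] <- cl
        }
      }
      return(state)
    }
  }

  cl <- list(lat = report$lat, lon = report$lon, count = 1L,
             bins = integer(N_BINS), first_at = report$time,
             situations = stats::setNames(integer(length(SITUATIONS)),
                                          SITUATIONS),
             context = c(strong_urge = 0L, stress = 0L, low_mood = 0L,
                         others_present = 0L))
  cl$bins[bin] <- 1L
  cl$situations[report$situation] <- 1L
  cl$context <- ctx
  state$candidates[[length(state$candidates) + 1L]] <- cl
  # immediate promotion when a single report suffices
  if (config$min_reports_for_fence <= 1L) {
    id <- sprintf("f%03d", length(state$fences) + 1L)
    state$fences[[length(state$fences) + 1L]] <-
      new_fence(id, cl$lat, cl$lon, config, created_at = report$time,
                source = if (report$is_lapse) "lapse" else "pre_quit",
                bins = cl$bins, situations = cl$situations,
                context = cl$context)
    state$candidates[[length(state$candidates)]] <- NULL
  }
  state
}

#' Ingest a location fix
#'
#' Updates per-fence dwell tracking and evaluates trigger decisions.  A
#' decision is due when continuous dwell inside a fence first reaches
#' `min_dwell_minutes`, and again at every `redecision_interval_hours`
#' boundary of continued presence.  Decisions are evaluated at the first
#' fix at or after each due time; leaving the fence, or a fix gap larger
#' than twice the median fix interval, resets dwell.
#'
#' Dwell is tracked in every stage, but decisions can only fire while the
#' quit attempt is active (committed or maintenance stage, post quit date);
#' otherwise dwell-qualified evaluations are reported with reason
#' `"stopped"`.
#'
#' @param state an `engine_state`.
#' @param fix a [location_fix()].
#' @param config an [engine_config()].
#' @return `list(state = <engine_state>, decisions = <list of decisions>)`;
#'   `decisions` is empty when no evaluation was due.
#' @export
ingest_location_fix <- function(state, fix, config = engine_config()) {
  stopifnot(inherits(state, "engine_state"), inherits(fix, "location_fix"))
  check_ordering(state, fix$time)
  state <- advance_stage(state, fix$time, config)

  gap_reset <- FALSE
  if (!is.null(state$last_fix_time)) {
    gap <- as.numeric(difftime(fix$time, state$last_fix_time, units = "secs"))
    if (length(state$fix_intervals) >= 3 &&
        gap > 2 * stats::median(state$fix_intervals)) {
      gap_reset <- TRUE
    }
    state$fix_intervals <- utils::tail(c(state$fix_intervals, gap), 50)
  }
  state$last_fix_time <- fix$time
  state$last_event_time <- fix$time

  decisions <- list()
  dwell_secs <- config$min_dwell_minutes * 60
  redecide_secs <- config$redecision_interval_hours * 3600

  for (f in state$fences) {
    inside <- haversine_m(f$lat, f$lon, fix$lat, fix$lon) <= f$radius_m
    trk <- state$dwell[[f$id]]
    if (!inside) {
      state$dwell[[f$id]] <- NULL
      next
    }
    if (is.null(trk) || gap_reset) {
      trk <- list(entry = fix$time, next_k = 0L)
      state$dwell[[f$id]] <- trk
      next
    }
    # evaluate every due boundary that this fix confirms was dwelt through
    repeat {
      due <- trk$entry + dwell_secs + trk$next_k * redecide_secs
      if (fix$time < due) break
      active <- state$stage %in% c("committed", "maintenance") &&
        !is.null(state$quit_date) &&
        local_date(due, config$tz) >= state$quit_date
      if (active) {
        dec <- decide_trigger(state, f, due, config)
        if (dec$fired) {
          msg_id <- sprintf("m%03d", nrow(state$messages_sent) + 1L)
          state$messages_sent <- rbind(
            state$messages_sent,
            data.frame(time = due, fence_id = f$id, message_id = msg_id,
                       stringsAsFactors = FALSE))
        }
      } else {
        dec <- trigger_decision(FALSE, "stopped", f$id, due)
      }
      decisions[[length(decisions) + 1L]] <- dec
      trk$next_k <- trk$next_k + 1L
    }
    state$dwell[[f$id]] <- trk
  }
  list(state = state, decisions = decisions)
}

trigger_decision <- function(fired, reason, fence_id, time) {
  stopifnot(reason %in% DECISION_REASONS, fired == (reason == "fired"))
  structure(list(fired = fired, reason = reason, fence_id = fence_id,
                 time = time),
            class = "trigger_decision")
}

#' Decide whether a geofence fires a support message
#'
#' Pure rule evaluation for a dwell-qualified moment inside `fence`:
#' support must not have stopped (3 months post-quit), the local clock must
#' lie inside the active window, the fence's smoking-report tally in the
#' current 3-hour time-of-day bin must reach `trigger_threshold`, no
#' message may have fired for this fence within the re-decision interval,
#' and in the maintenance stage a decay gate passes with probability
#' `monthly_decay_factor^m` (m = 1 in the first maintenance month, 2 in the
#' second, ...).  The decay draw is a counter-based deterministic stream
#' keyed by the engine seed, the evaluation minute, and the number of
#' messages sent, so replays are exactly reproducible.
#'
#' @param state an `engine_state`.
#' @param fence a fence element of `state$fences`.
#' @param time evaluation time (`POSIXct`).
#' @param config an [engine_config()].
#' @return a `trigger_decision` with fields `fired`, `reason`, `fence_id`,
#'   `time`.
#' @export
decide_trigger <- function(state, fence, time, config = engine_config()) {
  stopifnot(inherits(state, "engine_state"))
  month_secs <- config$month_length_days * 86400
  quit_time <- as.POSIXct(paste(state$quit_date, "00:00:00"),
                          tz = config$tz)
  stop_at <- quit_time + config$support_stop_months * month_secs
  if (state$stage == "stopped" || time >= stop_at) {
    return(trigger_decision(FALSE, "stopped", fence$id, time))
  }
  if (!in_active_window(time, config)) {
    return(trigger_decision(FALSE, "outside_window", fence$id, time))
  }
  bin <- time_bin(time, config)
  if (fence$tally[bin] < config$trigger_threshold) {
    return(trigger_decision(FALSE, "below_threshold", fence$id, time))
  }
  sent <- state$messages_sent
  recent <- sent$fence_id == fence$id &
    as.numeric(difftime(time, sent$time, units = "hours")) <
      config$redecision_interval_hours &
    sent$time <= time
  if (any(recent)) {
    return(trigger_decision(FALSE, "cooldown", fence$id, time))
  }
  stage2_end <- quit_time + config$stage2_duration_days * 86400
  if (time >= stage2_end) {
    m <- floor(as.numeric(difftime(time, stage2_end, units = "secs")) /
                 month_secs) + 1
    p <- config$monthly_decay_factor^m
    counter <- floor(as.numeric(time) / 60) %% 1e6 +
      7919 * nrow(state$messages_sent)
    if (counter_unif(state$rng_seed, counter) >= p) {
      return(trigger_decision(FALSE, "decayed_out", fence$id, time))
    }
  }
  trigger_decision(TRUE, "fired", fence$id, time)
}

#' Detect relapse from daily reported episode counts
#'
#' Relapse is declared when strictly more than
#' `relapse_episodes_per_day_gt` smoking episodes were reported on each of
#' `relapse_consecutive_days` consecutive days ending at `date` (defaults:
#' more than one episode per day over two consecutive days).
#'
#' @param state an `engine_state` with a quit date set.
#' @param date the `Date` ending the window.
#' @param config an [engine_config()].
#' @return `TRUE` or `FALSE`.
#' @export
detect_relapse <- function(state, date, config = engine_config()) {
  stopifnot(inherits(state, "engine_state"), inherits(date, "Date"))
  if (is.null(state$quit_date)) {
    stop_jitai("relapse detection requires a quit date",
               class = "jitai_validation")
  }
  days <- date - seq_len(config$relapse_consecutive_days) + 1
  counts <- vapply(as.character(days), function(d)
    if (d %in% names(state$daily_episode_counts))
      state$daily_episode_counts[[d]] else 0L, integer(1))
  all(counts > config$relapse_episodes_per_day_gt)
}

#' Restart a quit attempt
#'
#' Sets a new quit date, restarting the abstinence challenge and with it
#' the maintenance-decay and support-stop clocks.  Learned geofences, their
#' tallies, and the message history are retained.
#'
#' @param state an `engine_state`.
#' @param new_quit_date the new quit `Date`.
#' @param config an [engine_config()].
#' @return the updated `engine_state`.
#' @export
reset_quit_attempt <- function(state, new_quit_date,
                               config = engine_config()) {
  stopifnot(inherits(state, "engine_state"), inherits(new_quit_date, "Date"))
  if (!is.null(state$last_event_time) &&
      new_quit_date < local_date(state$last_event_time, config$tz)) {
    stop_jitai("new quit date %s precedes the last processed event",
               format(new_quit_date), class = "jitai_validation")
  }
  state$quit_date <- new_quit_date
  state$stage <- "committed"
  state$daily_episode_counts <- integer(0)
  if (!is.null(state$last_event_time)) {
    state <- advance_stage(state, state$last_event_time, config)
  }
  state
}

#' Advance the engine stage clock
#'
#' Stage is a pure function of `now` and the quit date: training before the
#' quit date, committed for the 28-day challenge, maintenance until
#' `support_stop_months` (in `month_length_days`-day months), stopped
#' after.
#'
#' @param state an `engine_state`.
#' @param now current time (`POSIXct`).
#' @param config an [engine_config()].
#' @return the updated `engine_state`.
#' @export
advance_stage <- function(state, now, config = engine_config()) {
  stopifnot(inherits(state, "engine_state"))
  if (is.null(state$quit_date)) {
    state$stage <- "training"
    return(state)
  }
  days <- as.numeric(local_date(now, config$tz) - state$quit_date)
  state$stage <-
    if (days < 0) "training"
    else if (days < config$stage2_duration_days) "committed"
    else if (days < config$support_stop_months * config$month_length_days)
      "maintenance"
    else "stopped"
  state
}

#' Replay an ordered event log through the engine
#'
#' Folds [ingest_smoking_report()], [ingest_location_fix()] and
#' [reset_quit_attempt()] over a time-ordered stream of events.  The result
#' is a pure function of `(events, config, quit_date, seed)`.
#'
#' @param events list of events built with [location_fix()],
#'   [smoking_report()] and [quit_reset()], in non-decreasing time order.
#' @param config an [engine_config()].
#' @param quit_date initial quit `Date` (may also be set by a reset event).
#' @param seed integer decay-stream seed.
#' @return `list(state = final engine_state, decisions = data.frame(time,
#'   fence_id, reason, fired))`.
#' @export
replay_event_log <- function(events, config = engine_config(),
                             quit_date = NULL, seed = 1L) {
  state <- engine_new(config, quit_date = quit_date, seed = seed)
  times <- as.POSIXct(character(0), tz = "UTC")
  fence_ids <- character(0); reasons <- character(0); fired <- logical(0)
  last <- NULL
  for (i in seq_along(events)) {
    ev <- events[[i]]
    if (!inherits(ev, "jitai_event")) {
      stop_jitai("record %d is not a recognised event", i,
                 class = "jitai_validation")
    }
    if (!is.null(last) && ev$time < last) {
      stop_jitai("record %d at %s is out of order (previous %s)",
                 i, format(ev$time), format(last), class = "jitai_ordering")
    }
    last <- ev$time
    if (inherits(ev, "smoking_report")) {
      state <- ingest_smoking_report(state, ev, config)
    } else if (inherits(ev, "location_fix")) {
      out <- ingest_location_fix(state, ev, config)
      state <- out$state
      for (dec in out$decisions) {
        times <- c(times, dec$time)
        fence_ids <- c(fence_ids, dec$fence_id)
        reasons <- c(reasons, dec$reason)
        fired <- c(fired, dec$fired)
      }
    } else if (inherits(ev, "quit_reset")) {
      state$last_event_time <- ev$time
      state <- reset_quit_attempt(state, ev$quit_date, config)
    }
  }
  list(state = state,
       decisions = data.frame(time = times, fence_id = fence_ids,
                              reason = reasons, fired = fired,
                              stringsAsFactors = FALSE))
}
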