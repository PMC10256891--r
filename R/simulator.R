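# Agent-based simulator of a two-arm app-vs-usual-care cessation trial.
#
# The behavioural model is deliberately minimal but sufficient for the
# engine's output to matter: smokers move between a small set of labelled
# places on a weekly template, report smoking episodes at place-dependent
# rates before their quit date, and after quitting face a per-cue-exposure
# lapse hazard that a recently fired support message multiplies by
# `message_effect_multiplier` (rho).  Lapses can escalate to relapse.
# Observation is then degraded through the trial's missingness structure:
# app installation, heavy-tailed engagement, follow-up response,
# abstinence misreporting, and arm-differential saliva-kit return.

#' Default place set
#'
#' Four labelled places around a small urban area with per-place smoking
#' rates (episodes/hour while present) and context profiles feeding the
#' situational fields of smoking reports.
#'
#' @return a `data.frame`, one row per place.
#' @export
default_places <- function() {
  data.frame(
    label = c("home", "work", "social", "other"),
    situation = c("home", "work", "socializing", "other"),
    lat = c(52.6300, 52.6410, 52.6255, 52.6370),
    lon = c(1.2970, 1.3090, 1.2920, 1.2840),
    rate = c(0.9, 0.7, 1.4, 0.5),        # pre-quit episodes/hour present
    p_others = c(0.15, 0.35, 0.85, 0.25),
    mean_urge = c(2.6, 3.0, 3.4, 2.8),
    mean_stress = c(2.0, 3.2, 1.8, 2.4),
    mean_mood = c(3.0, 2.4, 3.6, 2.8),
    stringsAsFactors = FALSE
  )
}

#' Default weekly movement template
#'
#' A 7 x 24 matrix of place labels (rows Monday..Sunday, columns hour of
#' day): nights and evenings at home, weekday working hours at work, an
#' errand hour morning and evening, and social blocks on Friday/Saturday
#' evenings and weekend afternoons.
#'
#' @return a character matrix `[7, 24]`.
#' @export
default_schedule <- function() {
  sched <- matrix("home", nrow = 7, ncol = 24,
                  dimnames = list(c("Mon", "Tue", "Wed", "Thu", "Fri",
                                    "Sat", "Sun"), NULL))
  for (d in 1:5) {
    sched[d, 9] <- "other"              # hour index 9 = 08:00-08:59
    sched[d, 10:17] <- "work"
    sched[d, 18] <- "other"
  }
  sched[5, 20:23] <- "social"           # Friday evening
  sched[6, 11:13] <- "other"            # Saturday errands
  sched[6, 14:18] <- "social"
  sched[6, 20:23] <- "social"
  sched[7, 12:14] <- "other"            # Sunday
  sched[7, 15:17] <- "social"
  sched
}

#' Draw a smoker profile
#'
#' Baseline smoking rate is Normal(15.4, 7.1) cigarettes/day (clamped to
#' [3, 60]), matching the trial population's baseline mean; heavy smoking
#' is >= 16/day and low socioeconomic status has prevalence 0.29, the two
#' randomization stratifiers.  The default lapse hazard (0.004 per cue
#' exposure) and relapse-given-lapse probability (0.5) put the usual-care
#' arm's true 6-month prolonged-abstinence rate near 14%, the level the
#' self-reported usual-care outcome suggests.
#'
#' @param seed integer.
#' @param baseline_lapse_hazard per-cue-exposure lapse probability.
#' @param message_effect_multiplier rho in (0, 1]: multiplier on the lapse
#'   hazard for exposures covered by a recent support message.
#' @param relapse_given_lapse probability a lapse escalates to relapse.
#' @param low_ses_prob prevalence of low socioeconomic status.
#' @return a list of class `smoker_profile`.
#' @export
smoker_profile <- function(seed = 1L,
                           baseline_lapse_hazard = 0.004,
                           message_effect_multiplier = 0.5,
                           relapse_given_lapse = 0.5,
                           low_ses_prob = 0.29) {
  stopifnot(baseline_lapse_hazard >= 0, baseline_lapse_hazard <= 1,
            message_effect_multiplier > 0, message_effect_multiplier <= 1,
            relapse_given_lapse >= 0, relapse_given_lapse <= 1)
  set.seed(seed)
  cpd <- round(min(60, max(3, stats::rnorm(1, 15.4, 7.1))))
  structure(list(
    cigarettes_per_day = cpd,
    heavy_smoker = cpd >= 16,
    low_ses = stats::runif(1) < low_ses_prob,
    schedule = default_schedule(),
    baseline_lapse_hazard = baseline_lapse_hazard,
    message_effect_multiplier = message_effect_multiplier,
    relapse_given_lapse = relapse_given_lapse
  ), class = "smoker_profile")
}

#' App engagement and measurement model
#'
#' Defaults encode the feasibility evidence the simulator emulates: 75%
#' install the app, everyone who installs sets a quit date, engagement
#' duration is heavy-tailed with median 10 days, 6-month/6-week follow-up
#' response is 77%/71%, and saliva kits come back from 52% (app arm) vs
#' 19% (usual care) of self-reported abstainers.
#'
#' @param install_prob probability an app-arm participant installs.
#' @param set_quit_date_given_install probability of setting a quit date.
#' @param engagement_meanlog,engagement_sdlog log-normal engagement-days
#'   parameters (median `exp(meanlog)` = 10 by default).
#' @param followup_prob_6m,followup_prob_6w follow-up response rates.
#' @param saliva_return_prob_by_arm named vector, `app` and `usual_care`.
#' @param misreport_prob probability a smoker self-reports abstinence.
#' @param withdraw_prob probability of withdrawal.
#' @param nrt_prob probability of non-tobacco nicotine substitution use.
#' @return a list of class `engagement_model`.
#' @export
engagement_model <- function(install_prob = 0.75,
                             set_quit_date_given_install = 1.0,
                             engagement_meanlog = log(10),
                             engagement_sdlog = 1.8,
                             followup_prob_6m = 0.77,
                             followup_prob_6w = 0.71,
                             saliva_return_prob_by_arm =
                               c(app = 0.52, usual_care = 0.19),
                             misreport_prob = 0.05,
                             withdraw_prob = 0.03,
                             nrt_prob = 0.3) {
  probs <- c(install_prob, set_quit_date_given_install, followup_prob_6m,
             followup_prob_6w, saliva_return_prob_by_arm, misreport_prob,
             withdraw_prob, nrt_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            all(c("app", "usual_care") %in%
                  names(saliva_return_prob_by_arm)))
  structure(list(install_prob = install_prob,
                 set_quit_date_given_install = set_quit_date_given_install,
                 engagement_meanlog = engagement_meanlog,
                 engagement_sdlog = engagement_sdlog,
                 followup_prob_6m = followup_prob_6m,
                 followup_prob_6w = followup_prob_6w,
                 saliva_return_prob_by_arm = saliva_return_prob_by_arm,
                 misreport_prob = misreport_prob,
                 withdraw_prob = withdraw_prob,
                 nrt_prob = nrt_prob),
            class = "engagement_model")
}

#' Simulation parameter bundle
#'
#' @param engine an [engine_config()].
#' @param engagement an [engagement_model()].
#' @param places a place table ([default_places()]).
#' @param train_days pre-quit training days.
#' @param horizon_days post-quit follow-up horizon (6 months = 180 days).
#' @param reporting_adherence fraction of smoking episodes reported.
#' @param coverage_prob expected fraction of engaged-period cue exposures
#'   covered by a fired message (used only by the fast, engine-free path).
#' @param block_sizes permuted-block sizes for stratified allocation.
#' @param start_date enrollment `Date` (a Monday keeps the weekly template
#'   aligned across participants).
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(engine = engine_config(),
                       engagement = engagement_model(),
                       places = default_places(),
                       train_days = 7,
                       horizon_days = 180,
                       reporting_adherence = 0.9,
                       coverage_prob = 0.5,
                       block_sizes = c(2, 4),
                       start_date = as.Date("2021-01-04")) {
  structure(list(engine = engine, engagement = engagement, places = places,
                 train_days = train_days, horizon_days = horizon_days,
                 reporting_adherence = reporting_adherence,
                 coverage_prob = coverage_prob, block_sizes = block_sizes,
                 start_date = start_date),
            class = "sim_params")
}

place_at <- function(schedule, day_index, hour) {
  # day_index counts from 1 at the start date (assumed Monday)
  schedule[(day_index - 1) %% 7 + 1, hour + 1]
}

#' Simulate a movement fix stream
#'
#' Emits one location fix per `fix_interval_s` seconds at the scheduled
#' place's centre plus isotropic Gaussian noise with sd `accuracy_m`.
#'
#' @param profile a [smoker_profile()].
#' @param places place table.
#' @param horizon_days days to simulate.
#' @param seed integer.
#' @param start_time `POSIXct` stream start.
#' @param fix_interval_s seconds between fixes.
#' @param accuracy_m positional noise sd in meters.
#' @return a list of [location_fix()] events in time order.
#' @export
simulate_movement <- function(profile, places = default_places(),
                              horizon_days = 7, seed = 1L,
                              start_time = as.POSIXct("2021-01-04 00:00:00",
                                                      tz = "UTC"),
                              fix_interval_s = 300, accuracy_m = 10) {
  stopifnot(horizon_days >= 1)
  set.seed(seed)
  n <- floor(horizon_days * 86400 / fix_interval_s)
  offs <- (seq_len(n) - 1) * fix_interval_s
  day_idx <- offs %/% 86400 + 1
  hour <- (offs %% 86400) %/% 3600
  labels <- mapply(function(d, h) place_at(profile$schedule, d, h),
                   day_idx, hour)
  pi_ <- match(labels, places$label)
  # ~111,320 m per degree latitude; longitude scaled by cos(lat)
  lat <- places$lat[pi_] + stats::rnorm(n, 0, accuracy_m / 111320)
  lon <- places$lon[pi_] +
    stats::rnorm(n, 0, accuracy_m / (111320 * cos(places$lat[pi_] * pi / 180)))
  lapply(seq_len(n), function(i)
    location_fix(start_time + offs[i], lat[i], lon[i], accuracy_m))
}

draw_context <- function(place_row) {
  clamp <- function(x) as.integer(min(5, max(0, round(x))))
  list(urge = clamp(stats::rnorm(1, place_row$mean_urge, 1)),
       stress = clamp(stats::rnorm(1, place_row$mean_stress, 1)),
       mood = clamp(stats::rnorm(1, place_row$mean_mood, 1)),
       others = stats::runif(1) < place_row$p_others)
}

#' Simulate pre-quit smoking reports
#'
#' Daily report counts are Poisson with mean
#' `cigarettes_per_day * reporting_adherence`; report times fall in waking
#' hours, locations and situational context follow the place occupied at
#' that moment.
#'
#' @param profile a [smoker_profile()].
#' @param places place table.
#' @param train_days days of training.
#' @param seed integer.
#' @param reporting_adherence fraction of episodes reported.
#' @param start_time `POSIXct` start of training.
#' @param accuracy_m positional noise sd.
#' @return a list of [smoking_report()] events in time order.
#' @export
simulate_pre_quit <- function(profile, places = default_places(),
                              train_days = 7, seed = 1L,
                              reporting_adherence = 0.9,
                              start_time = as.POSIXct("2021-01-04 00:00:00",
                                                      tz = "UTC"),
                              accuracy_m = 10) {
  stopifnot(train_days >= 1)
  set.seed(seed)
  if (reporting_adherence <= 0) return(list())
  reports <- list()
  for (d in seq_len(train_days)) {
    k <- stats::rpois(1, profile$cigarettes_per_day * reporting_adherence)
    if (k == 0) next
    secs <- sort(stats::runif(k, 7 * 3600, 23 * 3600))
    for (s in secs) {
      hour <- floor(s / 3600)
      label <- place_at(profile$schedule, d, hour)
      row <- places[places$label == label, ]
      ctx <- draw_context(row)
      t <- start_time + (d - 1) * 86400 + s
      reports[[length(reports) + 1L]] <- smoking_report(
        t,
        lat = row$lat + stats::rnorm(1, 0, accuracy_m / 111320),
        lon = row$lon + stats::rnorm(1, 0, accuracy_m / 111320),
        urge_strength = ctx$urge, stress = ctx$stress, mood = ctx$mood,
        situation = row$situation, others_present = ctx$others)
    }
  }
  reports
}

# Entry sequence into places for one template day: (hour, label) whenever
# the scheduled place changes.
day_entries <- function(schedule, day_index) {
  labels <- vapply(0:23, function(h) place_at(schedule, day_index, h),
                   character(1))
  change <- c(TRUE, labels[-1] != labels[-24])
  data.frame(hour = (0:23)[change], label = labels[change],
             stringsAsFactors = FALSE)
}

#' Simulate the post-quit lapse process
#'
#' Each entry into a place is a cue exposure.  A lapse occurs with
#' probability `baseline_lapse_hazard`, multiplied by
#' `message_effect_multiplier` when a support message fired for the dwelt
#' geofence within the re-decision interval before the exposure moment
#' (coverage).  With an engine supplied, exposures during the engaged
#' window are fed to it as location fixes (entry plus a fix after the
#' dwell minimum) and lapses are reported back as lapse smoking reports.
#' A lapse escalates to relapse with probability `relapse_given_lapse`,
#' after which the participant smokes daily.
#'
#' @param profile a [smoker_profile()].
#' @param places place table.
#' @param engine `NULL`, or `list(state =, config =)` for an app user.
#' @param horizon_days days post-quit.
#' @param seed integer.
#' @param quit_time `POSIXct` midnight of the quit date.
#' @param engaged_days days after the quit date during which the user
#'   still engages with the app (0 = never).
#' @param start_day_index template day index of the quit date.
#' @return a list: `n_lapses`, `relapse_day` (`NA` if none),
#'   `smoked_days` (logical by day), `exposures`, `covered_exposures`,
#'   `messages_fired`, and the final `engine` state (or `NULL`).
#' @export
simulate_post_quit <- function(profile, places = default_places(),
                               engine = NULL, horizon_days = 180,
                               seed = 1L,
                               quit_time = as.POSIXct("2021-01-11 00:00:00",
                                                      tz = "UTC"),
                               engaged_days = 0,
                               start_day_index = 8) {
  set.seed(seed)
  h <- profile$baseline_lapse_hazard
  rho <- profile$message_effect_multiplier
  n_lapses <- 0L
  relapse_day <- NA_integer_
  smoked <- logical(horizon_days)
  exposures <- 0L; covered <- 0L; fired <- 0L
  lapses_covered <- 0L; lapses_uncovered <- 0L
  cfg <- if (!is.null(engine)) engine$config else NULL
  state <- if (!is.null(engine)) engine$state else NULL

  for (d in seq_len(horizon_days)) {
    entries <- day_entries(profile$schedule, start_day_index + d - 1)
    for (i in seq_len(nrow(entries))) {
      exposures <- exposures + 1L
      is_covered <- FALSE
      t_entry <- quit_time + (d - 1) * 86400 + entries$hour[i] * 3600
      use_engine <- !is.null(state) && d <= engaged_days
      if (use_engine) {
        row <- places[places$label == entries$label[i], ]
        dwell_fix <- t_entry + cfg$min_dwell_minutes * 60
        out <- ingest_location_fix(state, location_fix(t_entry, row$lat,
                                                       row$lon), cfg)
        state <- out$state
        out <- ingest_location_fix(state, location_fix(dwell_fix, row$lat,
                                                       row$lon), cfg)
        state <- out$state
        for (dec in out$decisions) {
          if (dec$fired) {
            fired <- fired + 1L
            is_covered <- TRUE
          }
        }
        # leaving the place before the next entry resets dwell
        far <- location_fix(dwell_fix + 60, row$lat + 0.05, row$lon)
        state <- ingest_location_fix(state, far, cfg)$state
      }
      if (is_covered) covered <- covered + 1L
      p_lapse <- h * (if (is_covered) rho else 1)
      if (stats::runif(1) < p_lapse) {
        n_lapses <- n_lapses + 1L
        if (is_covered) lapses_covered <- lapses_covered + 1L
        else lapses_uncovered <- lapses_uncovered + 1L
        smoked[d] <- TRUE
        if (use_engine) {
          row <- places[places$label == entries$label[i], ]
          state <- ingest_smoking_report(
            state,
            smoking_report(t_entry + cfg$min_dwell_minutes * 60 + 120,
                           lat = row$lat, lon = row$lon,
                           situation = row$situation),
            cfg)
        }
        if (stats::runif(1) < profile$relapse_given_lapse) {
          relapse_day <- d
          smoked[d:horizon_days] <- TRUE
          break
        }
      }
    }
    if (!is.na(relapse_day)) break
  }
  list(n_lapses = n_lapses, relapse_day = relapse_day,
       smoked_days = smoked, exposures = exposures,
       covered_exposures = covered, messages_fired = fired,
       lapses_covered = lapses_covered,
       lapses_uncovered = lapses_uncovered,
       engine = if (is.null(state)) NULL else list(state = state,
                                                   config = cfg))
}

true_outcomes <- function(post, horizon_days, criteria = russell_criteria()) {
  smoked <- post$smoked_days
  last7 <- smoked[max(1, horizon_days - 6):horizon_days]
  wk6 <- smoked[max(1, min(36, horizon_days)):min(42, horizon_days)]
  list(
    prolonged_6m = is.na(post$relapse_day) &&
      post$n_lapses <= criteria$max_cigarettes_since_quit && !any(last7),
    pp7_6m = !any(last7),
    pp7_6w = !any(wk6),
    lapsed_2wk = any(smoked[1:14])
  )
}

#' Simulate the observation of one participant
#'
#' Applies the trial's missingness structure to ground truth: follow-up
#' response, withdrawal, abstinence misreporting, arm-differential saliva
#' return among self-reported 7-day abstainers, and assay values (cotinine
#' below 10 ng/ml only for genuine recent abstainers).
#'
#' @param truth list with `prolonged_6m`, `pp7_6m`, `pp7_6w` logicals.
#' @param arm `"app"` or `"usual_care"`.
#' @param engagement an [engagement_model()].
#' @param seed integer.
#' @return a one-row `data.frame` of observed fields.
#' @export
simulate_measurement <- function(truth, arm,
                                 engagement = engagement_model(),
                                 seed = 1L) {
  set.seed(seed)
  e <- engagement
  withdrawn <- stats::runif(1) < e$withdraw_prob
  responded_6m <- !withdrawn && stats::runif(1) < e$followup_prob_6m
  responded_6w <- !withdrawn && stats::runif(1) < e$followup_prob_6w
  misreport <- stats::runif(1) < e$misreport_prob
  sr <- function(true_value) {
    if (!responded_6m) return(NA)
    true_value || misreport
  }
  self_prolonged <- sr(truth$prolonged_6m)
  self_pp7 <- sr(truth$pp7_6m)
  self_pp7_6w <- if (!responded_6w) NA else truth$pp7_6w || misreport
  cot <- NA_real_; anab <- NA_real_
  nrt <- stats::runif(1) < e$nrt_prob
  if (isTRUE(self_pp7)) {
    if (stats::runif(1) < e$saliva_return_prob_by_arm[[arm]]) {
      if (truth$pp7_6m) {
        cot <- stats::runif(1, 0, 5)
        anab <- stats::runif(1, 0, 0.1)
      } else {                      # misreported: assays expose smoking
        cot <- stats::runif(1, 50, 300)
        anab <- stats::runif(1, 0.5, 5)
      }
    }
  }
  data.frame(withdrawn = withdrawn, responded_6m = responded_6m,
             responded_6w = responded_6w,
             self_report_prolonged = self_prolonged,
             self_report_7day_6m = self_pp7,
             self_report_7day_6w = self_pp7_6w,
             cotinine = cot, anabasine = anab, nrt_use = nrt,
             stringsAsFactors = FALSE)
}

#' Stratified permuted-block allocation
#'
#' Two-arm 1:1 allocation within strata using randomly chosen block sizes,
#' mirroring allocation stratified by smoking rate and socioeconomic
#' status.
#'
#' @param strata character vector of stratum labels, one per participant
#'   in enrollment order.
#' @param block_sizes candidate block sizes (arms per block = size).
#' @param seed integer.
#' @return character vector `"app"`/`"usual_care"`.
#' @export
allocate_stratified <- function(strata, block_sizes = c(2, 4), seed = 1L) {
  stopifnot(all(block_sizes %% 2 == 0))
  set.seed(seed)
  arms <- character(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    seq_arms <- character(0)
    while (length(seq_arms) < length(idx)) {
      b <- sample(block_sizes, 1)
      seq_arms <- c(seq_arms, sample(rep(c("app", "usual_care"), b / 2)))
    }
    arms[idx] <- seq_arms[seq_along(idx)]
  }
  arms
}

#' Simulate a full trial
#'
#' Generates participants with stratified blocked allocation and runs the
#' per-participant pipeline: training reports and the decision engine
#' in-loop for engaged app-arm installers (when `engine_detail = TRUE`),
#' the post-quit lapse/relapse process, and the measurement model.  With
#' `engine_detail = FALSE` a vectorised engine-free approximation is used
#' in which coverage of engaged-period exposures is Bernoulli with
#' `params$coverage_prob` -- orders of magnitude faster, intended for
#' repeated-trial calibration studies.
#'
#' @param n_app,n_usual target arm sizes (their sum is enrolled; realized
#'   arm sizes come from the blocked allocation).
#' @param params a [sim_params()].
#' @param seed integer master seed.
#' @param engine_detail run the decision engine per participant?
#' @return an object of class `trial_dataset`: `participants` data.frame,
#'   `seed`, `params`, and (with engine detail) per-participant `engines`.
#' @export
simulate_trial <- function(n_app = 104, n_usual = 105,
                           params = sim_params(), seed = 1L,
                           engine_detail = TRUE) {
  stopifnot(n_app >= 1, n_usual >= 1)
  n <- n_app + n_usual
  e <- params$engagement
  set.seed(seed)
  profile_seeds <- sample.int(2^30, n)
  stage_seeds <- matrix(sample.int(2^30, 4 * n), ncol = 4)

  profiles <- lapply(profile_seeds, smoker_profile)
  heavy <- vapply(profiles, `[[`, logical(1), "heavy_smoker")
  low_ses <- vapply(profiles, `[[`, logical(1), "low_ses")
  strata <- paste0(ifelse(heavy, "heavy", "light"), "/",
                   ifelse(low_ses, "lowSES", "otherSES"))
  arms <- allocate_stratified(strata, params$block_sizes,
                              seed = stage_seeds[1, 1])

  quit_date <- params$start_date + params$train_days
  quit_time <- as.POSIXct(paste(quit_date, "00:00:00"),
                          tz = params$engine$tz)
  horizon <- params$horizon_days

  rows <- vector("list", n)
  engines <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(stage_seeds[i, 1])
    prof <- profiles[[i]]
    arm <- arms[i]
    installed <- FALSE; set_qd <- FALSE; engagement_days <- 0
    if (arm == "app") {
      installed <- stats::runif(1) < e$install_prob
      if (installed) {
        set_qd <- stats::runif(1) < e$set_quit_date_given_install
        engagement_days <- stats::rlnorm(1, e$engagement_meanlog,
                                         e$engagement_sdlog)
      }
    }
    use_engine <- engine_detail && arm == "app" && installed && set_qd
    engine <- NULL
    if (use_engine) {
      state <- engine_new(params$engine, quit_date = quit_date,
                          seed = stage_seeds[i, 2] %% 100000L)
      train <- min(params$train_days, ceiling(engagement_days))
      reports <- simulate_pre_quit(prof, params$places, train,
                                   seed = stage_seeds[i, 2],
                                   reporting_adherence =
                                     params$reporting_adherence,
                                   start_time = as.POSIXct(
                                     paste(params$start_date, "00:00:00"),
                                     tz = params$engine$tz))
      for (r in reports) state <- ingest_smoking_report(state, r,
                                                        params$engine)
      engine <- list(state = state, config = params$engine)
    }
    engaged_post <- max(0, engagement_days - params$train_days)
    if (engine_detail) {
      post <- simulate_post_quit(prof, params$places, engine,
                                 horizon_days = horizon,
                                 seed = stage_seeds[i, 3],
                                 quit_time = quit_time,
                                 engaged_days = if (use_engine)
                                   engaged_post else 0,
                                 start_day_index = params$train_days + 1)
      engines[i] <- list(post$engine)
    } else {
      post <- fast_post_quit(prof, horizon, stage_seeds[i, 3],
                             covered_prob = if (arm == "app" && installed &&
                                                set_qd)
                               params$coverage_prob *
                                 min(1, engaged_post / horizon) else 0)
    }
    truth <- true_outcomes(post, horizon)
    obs <- simulate_measurement(truth, arm, e, seed = stage_seeds[i, 4])
    rows[[i]] <- cbind(
      data.frame(id = sprintf("p%04d", i), arm = arm,
                 heavy_smoker = prof$heavy_smoker, low_ses = prof$low_ses,
                 cigarettes_per_day = prof$cigarettes_per_day,
                 installed = installed, set_quit_date = set_qd,
                 engagement_days = engagement_days,
                 true_prolonged_6m = truth$prolonged_6m,
                 true_pp7_6m = truth$pp7_6m, true_pp7_6w = truth$pp7_6w,
                 lapsed_2wk = truth$lapsed_2wk,
                 n_lapses = post$n_lapses,
                 messages_fired = post$messages_fired %||% 0L,
                 stringsAsFactors = FALSE),
      obs)
  }
  structure(list(participants = do.call(rbind, rows),
                 seed = as.integer(seed), params = params,
                 engines = if (engine_detail) engines else NULL),
            class = "trial_dataset")
}

# Vectorless engine-free post-quit process for one participant: exposure
# count from the movement template, Bernoulli coverage, binomial lapses.
fast_post_quit <- function(profile, horizon_days, seed, covered_prob) {
  set.seed(seed)
  h <- profile$baseline_lapse_hazard
  rho <- profile$message_effect_multiplier
  entries_per_day <- mean(vapply(1:7, function(d)
    nrow(day_entries(profile$schedule, d)), numeric(1)))
  exposures <- stats::rpois(1, entries_per_day * horizon_days)
  cov_n <- stats::rbinom(1, exposures, covered_prob)
  n_lapses <- stats::rbinom(1, exposures - cov_n, h) +
    stats::rbinom(1, cov_n, h * rho)
  relapsed <- stats::runif(1) < 1 - (1 - profile$relapse_given_lapse)^n_lapses
  smoked <- logical(horizon_days)
  if (n_lapses > 0) {
    lapse_days <- sample.int(horizon_days, min(n_lapses, horizon_days),
                             replace = FALSE)
    smoked[lapse_days] <- TRUE
  }
  if (relapsed) {
    d0 <- if (any(smoked)) min(which(smoked)) else 1L
    smoked[d0:horizon_days] <- TRUE
  }
  list(n_lapses = n_lapses,
       relapse_day = if (relapsed)
         (if (any(smoked)) min(which(smoked)) else 1L) else NA_integer_,
       smoked_days = smoked, exposures = exposures,
       covered_exposures = cov_n, messages_fired = 0L, engine = NULL)
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<trial_dataset> %d participants (%d app / %d usual care), seed %d\n",
              nrow(p), sum(p$arm == "app"), sum(p$arm == "usual_care"),
              x$seed))
  invisible(x)
}
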