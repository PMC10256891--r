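# Line-delimited event logs, key-value run configuration, and tabular
# exports.  Logs are UTF-8 JSON lines, one record per line, typed by a
# "kind" field (fix | report | reset), with a schema-versioned header
# line; timestamps carry an explicit UTC offset.  read/write round-trips
# are byte-stable.

EVENT_SCHEMA <- "jitai-events/1"
TIME_FMT <- "%Y-%m-%dT%H:%M:%S%z"

fmt_time <- function(t, tz) format(t, format = TIME_FMT, tz = tz)

parse_time <- function(s) {
  t <- as.POSIXct(strptime(s, TIME_FMT, tz = "UTC"))
  if (is.na(t)) stop_jitai("unparseable timestamp '%s'", s,
                           class = "jitai_parse")
  t
}

#' Write an event log file
#'
#' @param events list of [location_fix()], [smoking_report()] and
#'   [quit_reset()] events.
#' @param path output file path.
#' @param tz timezone used to render local timestamps (offsets are
#'   explicit, so readers recover absolute time regardless).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path, tz = "UTC") {
  hdr <- sprintf('{"kind":"header","schema":"%s","tz":"%s"}',
                 EVENT_SCHEMA, tz)
  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.7f", x))
  lines <- vapply(events, function(ev) {
    if (inherits(ev, "location_fix")) {
      sprintf('{"kind":"fix","t":"%s","lat":%s,"lon":%s,"acc":%s}',
              fmt_time(ev$time, tz), fmt_num(ev$lat), fmt_num(ev$lon),
              fmt_num(ev$accuracy_m))
    } else if (inherits(ev, "smoking_report")) {
      sprintf(paste0('{"kind":"report","t":"%s","lat":%s,"lon":%s,',
                     '"urge":%d,"stress":%d,"mood":%d,"situation":"%s",',
                     '"others":%s}'),
              fmt_time(ev$time, tz),
              if (is.na(ev$lat)) "null" else fmt_num(ev$lat),
              if (is.na(ev$lon)) "null" else fmt_num(ev$lon),
              ev$urge_strength, ev$stress, ev$mood, ev$situation,
              if (ev$others_present) "true" else "false")
    } else if (inherits(ev, "quit_reset")) {
      sprintf('{"kind":"reset","t":"%s","quit_date":"%s"}',
              fmt_time(ev$time, tz), format(ev$quit_date))
    } else {
      stop_jitai("unserialisable event", class = "jitai_validation")
    }
  }, character(1))
  writeLines(c(hdr, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read an event log file
#'
#' @param path path to a file written by [write_event_log()] (or any file
#'   in the same line-delimited format).
#' @return list of typed events in file order; the log timezone is
#'   attached as attribute `tz`.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop_jitai("no such file: %s", path,
                                     class = "jitai_parse")
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop_jitai("empty file (missing header): %s",
                                     path, class = "jitai_parse")
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e)
    stop_jitai("line 1: malformed header", class = "jitai_parse"))
  if (!identical(hdr$kind, "header") ||
      !identical(hdr$schema, EVENT_SCHEMA)) {
    stop_jitai("line 1: unknown schema '%s'", hdr$schema %||% "<none>",
               class = "jitai_parse")
  }
  body <- lines[-1]
  events <- vector("list", length(body))
  for (i in seq_along(body)) {
    rec <- tryCatch(jsonlite::fromJSON(body[i]), error = function(e)
      stop_jitai("line %d: malformed JSON", i + 1, class = "jitai_parse"))
    events[[i]] <- switch(
      rec$kind %||% "<missing>",
      fix = location_fix(parse_time(rec$t), rec$lat, rec$lon, rec$acc),
      report = smoking_report(parse_time(rec$t),
                              lat = rec$lat %||% NA_real_,
                              lon = rec$lon %||% NA_real_,
                              urge_strength = rec$urge, stress = rec$stress,
                              mood = rec$mood, situation = rec$situation,
                              others_present = isTRUE(rec$others)),
      reset = quit_reset(parse_time(rec$t), as.Date(rec$quit_date)),
      stop_jitai("line %d: unknown kind '%s'", i + 1,
                 rec$kind %||% "<missing>", class = "jitai_parse"))
  }
  attr(events, "tz") <- hdr$tz %||% "UTC"
  events
}

#' Write a decisions table as CSV
#'
#' @param decisions the `decisions` data.frame from [replay_event_log()].
#' @param path output path.
#' @param tz timezone for rendering times.
#' @return `path`, invisibly.
#' @export
write_decisions_csv <- function(decisions, path, tz = "UTC") {
  out <- data.frame(time = fmt_time(decisions$time, tz),
                    fence_id = decisions$fence_id,
                    reason = decisions$reason,
                    fired = decisions$fired,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Known run-config keys, with coercers.
config_schema <- function() {
  num <- as.numeric; int <- function(x) as.integer(as.numeric(x))
  chr <- identity
  list(
    "seed" = int,
    "out_dir" = chr,
    "engine.fence_radius_m" = num,
    "engine.min_reports_for_fence" = int,
    "engine.min_dwell_minutes" = num,
    "engine.redecision_interval_hours" = num,
    "engine.active_window_start_min" = num,
    "engine.active_window_end_min" = num,
    "engine.stage2_duration_days" = num,
    "engine.monthly_decay_factor" = num,
    "engine.support_stop_months" = num,
    "engine.trigger_threshold" = int,
    "engine.month_length_days" = num,
    "engine.tz" = chr,
    "sim.n_app" = int,
    "sim.n_usual" = int,
    "sim.train_days" = num,
    "sim.horizon_days" = num,
    "sim.reporting_adherence" = num,
    "sim.coverage_prob" = num,
    "sim.install_prob" = num,
    "sim.engagement_median_days" = num,
    "sim.engagement_sdlog" = num,
    "sim.followup_prob_6m" = num,
    "sim.followup_prob_6w" = num,
    "sim.saliva_return_app" = num,
    "sim.saliva_return_usual" = num,
    "sim.misreport_prob" = num,
    "sim.engine_detail" = function(x) tolower(x) %in% c("true", "1", "yes"),
    "analysis.alpha" = num
  )
}

#' Read a key-value run configuration file
#'
#' Lines of `key = value`; `#` starts a comment.  Unknown keys are
#' rejected; `seed` is mandatory.
#'
#' @param path config file path.
#' @return a named list of parsed values (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_jitai("no such config file: %s", path,
                                     class = "jitai_parse")
  schema <- config_schema()
  lines <- readLines(path, encoding = "UTF-8")
  vals <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9._]+)\\s*=\\s*(.*?)\\s*$",
                                  line))[[1]]
    if (length(m) != 3) stop_jitai("config line %d is not 'key = value'",
                                   i, class = "jitai_parse")
    key <- m[2]; raw <- m[3]
    if (!key %in% names(schema)) {
      stop_jitai("unknown config key '%s' (line %d)", key, i,
                 class = "jitai_parse")
    }
    vals[[key]] <- schema[[key]](raw)
  }
  if (is.null(vals[["seed"]])) {
    stop_jitai("config must set a seed", class = "jitai_parse")
  }
  structure(vals, class = "run_config")
}

#' Materialise engine and simulation parameters from a run config
#'
#' @param cfg a `run_config` from [read_run_config()].
#' @return `list(engine =, params =, n_app =, n_usual =, seed =,
#'   alpha =, engine_detail =)`.
#' @export
build_run <- function(cfg) {
  g <- function(key, default) cfg[[key]] %||% default
  eng <- engine_config(
    fence_radius_m = g("engine.fence_radius_m", 100),
    min_reports_for_fence = g("engine.min_reports_for_fence", 2L),
    min_dwell_minutes = g("engine.min_dwell_minutes", 5),
    redecision_interval_hours = g("engine.redecision_interval_hours", 3),
    active_window = c(g("engine.active_window_start_min", 480),
                      g("engine.active_window_end_min", 1290)),
    stage2_duration_days = g("engine.stage2_duration_days", 28),
    monthly_decay_factor = g("engine.monthly_decay_factor", 0.5),
    support_stop_months = g("engine.support_stop_months", 3),
    trigger_threshold = g("engine.trigger_threshold", 2L),
    month_length_days = g("engine.month_length_days", 30),
    tz = g("engine.tz", "UTC"))
  em <- engagement_model(
    install_prob = g("sim.install_prob", 0.75),
    engagement_meanlog = log(g("sim.engagement_median_days", 10)),
    engagement_sdlog = g("sim.engagement_sdlog", 1.8),
    followup_prob_6m = g("sim.followup_prob_6m", 0.77),
    followup_prob_6w = g("sim.followup_prob_6w", 0.71),
    saliva_return_prob_by_arm = c(app = g("sim.saliva_return_app", 0.52),
                                  usual_care = g("sim.saliva_return_usual",
                                                 0.19)),
    misreport_prob = g("sim.misreport_prob", 0.05))
  params <- sim_params(engine = eng, engagement = em,
                       train_days = g("sim.train_days", 7),
                       horizon_days = g("sim.horizon_days", 180),
                       reporting_adherence = g("sim.reporting_adherence",
                                               0.9),
                       coverage_prob = g("sim.coverage_prob", 0.5))
  list(engine = eng, params = params,
       n_app = g("sim.n_app", 104L), n_usual = g("sim.n_usual", 105L),
       seed = cfg[["seed"]], alpha = g("analysis.alpha", 0.05),
       engine_detail = g("sim.engine_detail", TRUE),
       out_dir = g("out_dir", "."))
}

#' Write a trial dataset to disk
#'
#' One participants CSV plus a manifest (schema version, seed, parameter
#' fingerprint).
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_trial_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$participants,
                   file.path(dir, "participants.csv"), row.names = FALSE)
  flat <- unlist(dataset$params[c("train_days", "horizon_days",
                                  "reporting_adherence", "coverage_prob")])
  manifest <- list(schema = "jitai-trial/1", seed = dataset$seed,
                   n = nrow(dataset$participants),
                   param_hash = fnv1a_hex(paste(names(flat), flat,
                                                sep = "=")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Read a participants CSV back as a data.frame
#'
#' @param path `participants.csv` path.
#' @return a `data.frame`.
#' @export
read_participants_csv <- function(path) {
  if (!file.exists(path)) stop_jitai("no such file: %s", path,
                                     class = "jitai_parse")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
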