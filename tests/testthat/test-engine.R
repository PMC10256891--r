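# Decision-engine unit tests: fence learning, dwell/trigger rules,
# relapse detection, stage transitions, replay.

cfg <- engine_config()

test_that("reports cluster into candidates and fences by distance", {
  st <- engine_new(cfg)
  st <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-04 10:00:00"), HOME[["lat"]],
                       HOME[["lon"]]), cfg)
  expect_length(st$fences, 0)
  expect_length(st$candidates, 1)

  # second report 30 m away -> same cluster -> fence
  p30 <- north_of(HOME, 30)
  st2 <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-04 11:00:00"), p30[["lat"]],
                       p30[["lon"]]), cfg)
  expect_length(st2$fences, 1)
  expect_length(st2$candidates, 0)
  expect_equal(st2$fences[[1]]$radius_m, cfg$fence_radius_m)
  expect_equal(sum(st2$fences[[1]]$tally), 2)

  # second report 500 m away -> separate candidate, no fence
  p500 <- north_of(HOME, 500)
  st3 <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-04 11:00:00"), p500[["lat"]],
                       p500[["lon"]]), cfg)
  expect_length(st3$fences, 0)
  expect_length(st3$candidates, 2)
})

test_that("report ingestion rejects bad input", {
  st <- fenced_state(cfg)
  expect_error(
    ingest_smoking_report(
      st, smoking_report(ts_utc("2021-01-04 09:00:00"), HOME[["lat"]],
                         HOME[["lon"]]), cfg),
    class = "jitai_ordering")
  expect_error(smoking_report(ts_utc("2021-01-04 09:00:00"),
                              urge_strength = 9),
               class = "jitai_validation")
  expect_error(smoking_report(ts_utc("2021-01-04 09:00:00"),
                              situation = "pub"),
               class = "jitai_validation")
})

test_that("post-quit reports are lapses and feed episode counts", {
  st <- fenced_state(cfg)
  st <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-12 09:00:00"), HOME[["lat"]],
                       HOME[["lon"]]), cfg)
  st <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-12 15:00:00"), HOME[["lat"]],
                       HOME[["lon"]]), cfg)
  expect_equal(unname(st$daily_episode_counts[["2021-01-12"]]), 2L)
  expect_false(detect_relapse(st, as.Date("2021-01-12"), cfg))
  st <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-13 09:00:00"), HOME[["lat"]],
                       HOME[["lon"]]), cfg)
  st <- ingest_smoking_report(
    st, smoking_report(ts_utc("2021-01-13 11:00:00"), HOME[["lat"]],
                       HOME[["lon"]]), cfg)
  expect_true(detect_relapse(st, as.Date("2021-01-13"), cfg))
})

test_that("five-minute dwell gates the first decision", {
  st <- fenced_state(cfg)
  start <- ts_utc("2021-01-12 10:00:00")

  # 0 s and 240 s inside, then exit: dwell never reaches 5 minutes
  out <- run_fixes(st, cfg, start, c(0, 240))
  far <- north_of(HOME, 5000)
  out2 <- ingest_location_fix(
    out$state, location_fix(start + 400, far[["lat"]], far[["lon"]]), cfg)
  expect_length(c(out$decisions, out2$decisions), 0)

  # 0, 150, 300 s: boundary case, one decision evaluated at +300 s
  out <- run_fixes(st, cfg, start, c(0, 150, 300))
  expect_length(out$decisions, 1)
  expect_equal(out$decisions[[1]]$time, start + 300)
  expect_equal(out$decisions[[1]]$reason, "fired")
})

test_that("continuous presence re-decides every 3 hours", {
  st <- fenced_state(cfg)
  start <- ts_utc("2021-01-12 09:00:00")
  out <- run_fixes(st, cfg, start, seq(0, 7 * 3600, by = 60))
  times <- do.call(c, lapply(out$decisions, `[[`, "time"))
  expect_equal(times,
               start + c(300, 3 * 3600 + 300, 6 * 3600 + 300))
  fired <- vapply(out$decisions, `[[`, logical(1), "fired")
  ftimes <- times[fired]
  if (length(ftimes) > 1) {
    expect_true(all(diff(as.numeric(ftimes)) >= 3 * 3600))
  }
})

test_that("decide_trigger applies window, stop, threshold, cooldown", {
  st <- fenced_state(cfg)
  f <- st$fences[[1]]

  d <- decide_trigger(st, f, ts_utc("2021-01-12 07:00:00"), cfg)
  expect_equal(d$reason, "outside_window")
  expect_false(d$fired)

  d <- decide_trigger(st, f, ts_utc("2021-01-11 10:30:00") + 100 * 86400,
                      cfg)
  expect_equal(d$reason, "stopped")

  # tally 2 in the 10:00-ish bin (both training reports), threshold 2
  d <- decide_trigger(st, f, ts_utc("2021-01-12 10:00:00"), cfg)
  expect_equal(d$reason, "fired")
  expect_true(d$fired)

  # a different time-of-day bin has no reports -> below threshold
  d <- decide_trigger(st, f, ts_utc("2021-01-12 20:00:00"), cfg)
  expect_equal(d$reason, "below_threshold")

  # recent message -> cooldown
  st$messages_sent <- data.frame(time = ts_utc("2021-01-12 09:30:00"),
                                 fence_id = f$id, message_id = "m001",
                                 stringsAsFactors = FALSE)
  d <- decide_trigger(st, f, ts_utc("2021-01-12 10:00:00"), cfg)
  expect_equal(d$reason, "cooldown")
})

test_that("relapse detector matches the exhaustive window scan", {
  # all count vectors of length <= 6 with entries in 0..3
  for (len in 1:6) {
    grids <- as.matrix(expand.grid(rep(list(0:3), len)))
    # sample the longer grids to keep runtime modest; short ones in full
    rows <- if (len <= 3) seq_len(nrow(grids)) else {
      set.seed(100 + len)
      sample(nrow(grids), 120)
    }
    for (ri in rows) {
      counts <- grids[ri, ]
      st <- engine_new(cfg, quit_date = as.Date("2021-01-11"))
      dates <- as.Date("2021-01-11") + seq_len(len) - 1
      tallies <- as.integer(counts)
      names(tallies) <- as.character(dates)
      st$daily_episode_counts <- tallies[tallies > 0]
      for (j in seq_len(len)) {
        expect_identical(detect_relapse(st, dates[j], cfg),
                         oracle_relapse(counts, j))
      }
    }
  }
  # spot checks from the rule definition
  st <- engine_new(cfg, quit_date = as.Date("2021-01-11"))
  st$daily_episode_counts <- c("2021-01-11" = 2L, "2021-01-12" = 2L)
  expect_true(detect_relapse(st, as.Date("2021-01-12"), cfg))
  st$daily_episode_counts <- c("2021-01-11" = 1L, "2021-01-12" = 2L)
  expect_false(detect_relapse(st, as.Date("2021-01-12"), cfg))
  st$daily_episode_counts <- c("2021-01-11" = 2L, "2021-01-13" = 2L)
  expect_false(detect_relapse(st, as.Date("2021-01-13"), cfg))
})

test_that("fence construction matches the brute-force clustering oracle", {
  for (case in 1:12) {
    set.seed(1000 + case)
    n <- sample(5:50, 1)
    centers <- matrix(c(52.63, 1.297, 52.64, 1.31, 52.62, 1.28),
                      ncol = 2, byrow = TRUE)
    ci <- sample(1:3, n, replace = TRUE)
    lat <- centers[ci, 1] + rnorm(n, 0, 0.0015)
    lon <- centers[ci, 2] + rnorm(n, 0, 0.0015)
    st <- engine_new(cfg)
    t <- ts_utc("2021-01-04 09:00:00")
    for (i in seq_len(n)) {
      st <- ingest_smoking_report(
        st, smoking_report(t + i * 600, lat[i], lon[i]), cfg)
    }
    oracle <- oracle_cluster(lat, lon, cfg$fence_radius_m,
                             cfg$min_reports_for_fence)
    expect_equal(length(st$fences), nrow(oracle), info = paste("case", case))
    if (length(st$fences) > 0) {
      got <- data.frame(
        lat = vapply(st$fences, `[[`, numeric(1), "lat"),
        lon = vapply(st$fences, `[[`, numeric(1), "lon"),
        count = vapply(st$fences, function(f) sum(f$tally), integer(1)))
      got <- got[order(got$lat, got$lon), ]
      want <- oracle[order(oracle$lat, oracle$lon), ]
      expect_equal(got$lat, want$lat, tolerance = 1e-12)
      expect_equal(got$count, want$count)
    }
  }
})

test_that("quit-date reset restarts the support clocks", {
  st <- fenced_state(cfg)
  st <- advance_stage(st, ts_utc("2021-06-01 10:00:00"), cfg)
  expect_equal(st$stage, "stopped")
  f <- st$fences[[1]]
  expect_equal(decide_trigger(st, f, ts_utc("2021-06-01 10:00:00"),
                              cfg)$reason, "stopped")

  st$last_event_time <- ts_utc("2021-06-01 10:00:00")
  st2 <- reset_quit_attempt(st, as.Date("2021-06-01"), cfg)
  expect_equal(st2$stage, "committed")
  expect_length(st2$fences, 1)            # fences retained
  d <- decide_trigger(st2, f, ts_utc("2021-06-02 10:00:00"), cfg)
  expect_equal(d$reason, "fired")         # stop clock restarted

  # idempotent
  st3 <- reset_quit_attempt(st2, as.Date("2021-06-01"), cfg)
  expect_identical(st2, st3)

  expect_error(reset_quit_attempt(st, as.Date("2021-05-01"), cfg),
               class = "jitai_validation")
})

test_that("stage transitions follow the quit-date clock", {
  st <- engine_new(cfg, quit_date = as.Date("2021-01-11"))
  qd <- ts_utc("2021-01-11 00:00:00")
  expect_equal(advance_stage(st, qd - 1, cfg)$stage, "training")
  expect_equal(advance_stage(st, qd, cfg)$stage, "committed")
  expect_equal(advance_stage(st, qd + 27 * 86400, cfg)$stage, "committed")
  expect_equal(advance_stage(st, qd + 28 * 86400, cfg)$stage, "maintenance")
  expect_equal(advance_stage(st, qd + 89 * 86400, cfg)$stage, "maintenance")
  expect_equal(advance_stage(st, qd + 90 * 86400, cfg)$stage, "stopped")
})

test_that("replay equals composing the ingest operations", {
  expect_equal(replay_event_log(list(), cfg)$decisions |> nrow(), 0)

  start <- ts_utc("2021-01-04 10:00:00")
  events <- list(
    smoking_report(start, HOME[["lat"]], HOME[["lon"]], situation = "home"),
    smoking_report(start + 1200, HOME[["lat"]], HOME[["lon"]],
                   situation = "home"),
    location_fix(ts_utc("2021-01-12 10:00:00"), HOME[["lat"]],
                 HOME[["lon"]]),
    location_fix(ts_utc("2021-01-12 10:05:00"), HOME[["lat"]],
                 HOME[["lon"]]))
  res <- replay_event_log(events, cfg, quit_date = as.Date("2021-01-11"),
                          seed = 7)

  # manual fold
  st <- engine_new(cfg, quit_date = as.Date("2021-01-11"), seed = 7)
  st <- ingest_smoking_report(st, events[[1]], cfg)
  st <- ingest_smoking_report(st, events[[2]], cfg)
  o1 <- ingest_location_fix(st, events[[3]], cfg)
  o2 <- ingest_location_fix(o1$state, events[[4]], cfg)
  expect_equal(nrow(res$decisions), length(o2$decisions))
  expect_equal(res$decisions$reason, vapply(o2$decisions, `[[`,
                                            character(1), "reason"))
  expect_equal(res$state$messages_sent, o2$state$messages_sent)

  # determinism
  res2 <- replay_event_log(events, cfg, quit_date = as.Date("2021-01-11"),
                           seed = 7)
  expect_identical(res, res2)

  # unordered stream names the offending record
  bad <- events[c(1, 3, 2)]
  expect_error(replay_event_log(bad, cfg), "record 3",
               class = "jitai_ordering")
})

test_that("randomized streams respect window, spacing and stop rules", {
  stop_secs <- cfg$support_stop_months * cfg$month_length_days * 86400
  for (case in 1:8) {
    set.seed(2000 + case)
    st <- fenced_state(cfg, seed = case)
    start <- ts_utc("2021-01-12 00:00:00")
    # random in/out fix walk over 100 days at random hours
    offs <- sort(sample(0:(100 * 86400), 800))
    decisions <- list()
    for (o in offs) {
      inside <- runif(1) < 0.6
      pt <- if (inside) HOME else north_of(HOME, 3000)
      out <- ingest_location_fix(
        st, location_fix(start + o, pt[["lat"]], pt[["lon"]]), cfg)
      st <- out$state
      decisions <- c(decisions, out$decisions)
    }
    fired <- Filter(function(d) d$fired, decisions)
    for (d in fired) {
      mins <- as.POSIXlt(d$time, tz = cfg$tz)$hour * 60 +
        as.POSIXlt(d$time, tz = cfg$tz)$min
      expect_gte(mins, 480)
      expect_lte(mins, 1290)
      expect_lt(as.numeric(d$time) - as.numeric(ts_utc("2021-01-11 00:00:00")),
                stop_secs)
    }
    ftimes <- vapply(fired, function(d) as.numeric(d$time), numeric(1))
    if (length(ftimes) > 1) {
      expect_true(all(diff(sort(ftimes)) >=
                        cfg$redecision_interval_hours * 3600 - 1e-6))
    }
  }
})
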