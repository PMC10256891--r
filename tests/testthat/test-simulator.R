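# Cohort simulator: movement, reporting, lapse mechanism, measurement,
# allocation, reproducibility.

test_that("movement follows the template and is reproducible", {
  prof <- smoker_profile(seed = 1)
  prof$schedule[] <- "home"             # degenerate template: always home
  fixes <- simulate_movement(prof, horizon_days = 1, seed = 2)
  places <- default_places()
  home <- places[places$label == "home", ]
  d <- vapply(fixes, function(f) haversine_m(home$lat, home$lon, f$lat,
                                             f$lon), numeric(1))
  expect_lt(max(d), 100)                # 10 m noise sd, generous bound

  f1 <- simulate_movement(prof, horizon_days = 1, seed = 9)
  f2 <- simulate_movement(prof, horizon_days = 1, seed = 9)
  expect_identical(f1, f2)
})

test_that("long-run place occupancy matches the weekly template", {
  prof <- smoker_profile(seed = 1)
  fixes <- simulate_movement(prof, horizon_days = 7, seed = 3,
                             fix_interval_s = 60)     # 10,080 fixes
  places <- default_places()
  nearest <- vapply(fixes, function(f) {
    d <- haversine_m(places$lat, places$lon, f$lat, f$lon)
    places$label[which.min(d)]
  }, character(1))
  got <- table(factor(nearest, levels = places$label)) / length(nearest)
  want <- table(factor(prof$schedule, levels = places$label)) /
    length(prof$schedule)
  expect_true(all(abs(got - want) < 0.05))
})

test_that("pre-quit reporting volume matches its Poisson mean", {
  prof <- smoker_profile(seed = 1)
  prof$cigarettes_per_day <- 15
  expect_length(simulate_pre_quit(prof, train_days = 7, seed = 1,
                                  reporting_adherence = 0), 0)
  counts <- vapply(1:1000, function(s)
    length(simulate_pre_quit(prof, train_days = 7, seed = s,
                             reporting_adherence = 1)), numeric(1))
  expect_equal(mean(counts), 105, tolerance = 0.03)

  # reports inherit the occupied place's situation label
  reps <- simulate_pre_quit(prof, train_days = 2, seed = 5)
  places <- default_places()
  for (r in reps) {
    d <- haversine_m(places$lat, places$lon, r$lat, r$lon)
    expect_equal(r$situation, places$situation[which.min(d)])
  }
})

test_that("zero hazard keeps the trajectory abstinent", {
  prof <- smoker_profile(seed = 1, baseline_lapse_hazard = 0)
  post <- simulate_post_quit(prof, horizon_days = 60, seed = 4)
  expect_equal(post$n_lapses, 0L)
  expect_true(is.na(post$relapse_day))
  expect_false(any(post$smoked_days))
})

test_that("a null message effect leaves the lapse process unchanged", {
  cfg <- engine_config()
  prof <- smoker_profile(seed = 2, baseline_lapse_hazard = 0.05,
                         message_effect_multiplier = 1)
  for (s in 1:5) {
    with_engine <- simulate_post_quit(prof, engine = list(
      state = fenced_state(cfg), config = cfg), horizon_days = 30,
      seed = s, engaged_days = 30)
    without <- simulate_post_quit(prof, engine = NULL, horizon_days = 30,
                                  seed = s)
    expect_identical(with_engine$n_lapses, without$n_lapses)
    expect_identical(with_engine$relapse_day, without$relapse_day)
  }
})

test_that("message coverage halves the per-exposure lapse rate", {
  cfg <- engine_config()
  lapses_c <- 0; lapses_u <- 0; exp_c <- 0; exp_u <- 0
  for (s in 1:40) {
    prof <- smoker_profile(seed = 400 + s, baseline_lapse_hazard = 0.3,
                           message_effect_multiplier = 0.5,
                           relapse_given_lapse = 0)
    post <- simulate_post_quit(prof, engine = list(
      state = fenced_state(cfg), config = cfg), horizon_days = 60,
      seed = s, engaged_days = 60)
    lapses_c <- lapses_c + post$lapses_covered
    lapses_u <- lapses_u + post$lapses_uncovered
    exp_c <- exp_c + post$covered_exposures
    exp_u <- exp_u + post$exposures - post$covered_exposures
  }
  expect_gt(exp_c, 1000)                # both arms of the comparison exist
  expect_gt(exp_u, 1000)
  ratio <- (lapses_c / exp_c) / (lapses_u / exp_u)
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("measurement model follows the missingness rules", {
  truth <- list(prolonged_6m = TRUE, pp7_6m = TRUE, pp7_6w = TRUE)
  em0 <- engagement_model(followup_prob_6m = 0, followup_prob_6w = 0,
                          withdraw_prob = 0)
  obs <- simulate_measurement(truth, "app", em0, seed = 1)
  expect_true(is.na(obs$self_report_prolonged))
  rec <- outcome_record("app",
                        self_report_prolonged = obs$self_report_prolonged,
                        self_report_7day_6m = obs$self_report_7day_6m,
                        cotinine = obs$cotinine, withdrawn = obs$withdrawn)
  expect_false(derive_validated_prolonged(rec))   # missing = smoking

  em1 <- engagement_model(followup_prob_6m = 1, followup_prob_6w = 1,
                          saliva_return_prob_by_arm = c(app = 1,
                                                        usual_care = 1),
                          misreport_prob = 0, withdraw_prob = 0)
  obs <- simulate_measurement(truth, "app", em1, seed = 2)
  expect_lt(obs$cotinine, 10)           # true abstainer assays clean

  smoker <- list(prolonged_6m = FALSE, pp7_6m = FALSE, pp7_6w = FALSE)
  em2 <- engagement_model(followup_prob_6m = 1, followup_prob_6w = 1,
                          saliva_return_prob_by_arm = c(app = 1,
                                                        usual_care = 1),
                          misreport_prob = 1, withdraw_prob = 0)
  obs <- simulate_measurement(smoker, "app", em2, seed = 3)
  expect_true(obs$self_report_7day_6m)  # misreported abstinence
  expect_gte(obs$cotinine, 10)          # exposed by the assay
  rec <- outcome_record("app",
                        self_report_prolonged = obs$self_report_prolonged,
                        self_report_7day_6m = obs$self_report_7day_6m,
                        cotinine = obs$cotinine)
  expect_false(derive_validated_prolonged(rec))
})

test_that("stratified blocks bound within-stratum imbalance", {
  set.seed(77)
  strata <- sample(c("heavy/low", "heavy/other", "light/low",
                     "light/other"), 400, replace = TRUE)
  arms <- allocate_stratified(strata, block_sizes = c(2, 4), seed = 5)
  for (s in unique(strata)) {
    tab <- table(arms[strata == s])
    expect_lte(abs(tab[["app"]] - tab[["usual_care"]]), 3)  # max block - 1
  }
})

test_that("trial generation is seed-reproducible", {
  p1 <- sim_params(horizon_days = 50)
  d1 <- simulate_trial(15, 15, p1, seed = 42, engine_detail = FALSE)
  d2 <- simulate_trial(15, 15, p1, seed = 42, engine_detail = FALSE)
  expect_identical(d1$participants, d2$participants)
  d3 <- simulate_trial(15, 15, p1, seed = 43, engine_detail = FALSE)
  expect_false(identical(d1$participants, d3$participants))
})

test_that("engine-in-loop and fast paths agree on arm-level rates", {
  p <- sim_params(horizon_days = 60)
  slow <- simulate_trial(60, 60, p, seed = 8, engine_detail = TRUE)
  fast <- do.call(rbind, lapply(1:6, function(s)
    simulate_trial(60, 60, p, seed = 8 + s,
                   engine_detail = FALSE)$participants))
  ps <- slow$participants
  # same movement template, hazards and measurement model: usual-care
  # true-abstinence rates should agree within Monte-Carlo noise
  uc_slow <- mean(ps$true_pp7_6m[ps$arm == "usual_care"])
  uc_fast <- mean(fast$true_pp7_6m[fast$arm == "usual_care"])
  se <- sqrt(uc_fast * (1 - uc_fast) * (1 / 60 + 1 / 360))
  expect_lt(abs(uc_slow - uc_fast), 4 * se + 0.02)
  # engine participants exist exactly for installed app-arm users
  expect_true(all(vapply(seq_len(nrow(ps)), function(i)
    is.null(slow$engines[[i]]) ==
      !(ps$arm[i] == "app" && ps$installed[i] && ps$set_quit_date[i]),
    logical(1))))
})

test_that("outcome cohort matches its configured marginal rates", {
  coh <- simulate_outcome_cohort(5000, 5000, seed = 99)
  app <- coh$arm == "app"
  expect_equal(mean(coh$installed[app]), 0.75, tolerance = 0.05)
  expect_equal(mean(coh$responded_6m), 0.77 * (1 - 0.03),
               tolerance = 0.03)
  expect_equal(median(coh$engagement_days[coh$installed]), 10,
               tolerance = 0.2)
})
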