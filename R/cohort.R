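# Vectorised outcome-level cohort simulation for repeated-trial
# calibration studies (type-I error, interval coverage, parameter
# recovery).  This path shares the hazard/measurement model of
# simulate_trial(engine_detail = FALSE) but draws every participant in
# vector form, making hundreds of large-n replicate trials cheap.  It is
# cross-checked against the per-participant path in the test suite.

#' Simulate an outcome-level cohort (vectorised)
#'
#' Draws, for `n_app + n_usual` participants: app installation and
#' engagement, cue-exposure counts, coverage of engaged-period exposures,
#' lapses (hazard multiplied by `rho` when covered), relapse, the three
#' true abstinence outcomes, and the full measurement model (follow-up,
#' withdrawal, misreporting, arm-differential saliva return, assays).
#'
#' @param n_app,n_usual arm sizes.
#' @param engagement an [engagement_model()].
#' @param baseline_lapse_hazard per-exposure lapse probability.
#' @param message_effect_multiplier rho, hazard multiplier under coverage.
#' @param relapse_given_lapse escalation probability per lapse.
#' @param coverage_prob probability an engaged-period exposure is covered.
#' @param exposures_per_day mean cue exposures per day.
#' @param train_days,horizon_days training and follow-up windows.
#' @param seed integer.
#' @return a `data.frame` with the observed columns used by
#'   [analyze_trial()] plus ground truth.
#' @export
simulate_outcome_cohort <- function(n_app = 104, n_usual = 105,
                                    engagement = engagement_model(),
                                    baseline_lapse_hazard = 0.004,
                                    message_effect_multiplier = 0.5,
                                    relapse_given_lapse = 0.5,
                                    coverage_prob = 0.5,
                                    exposures_per_day = 5.3,
                                    train_days = 7, horizon_days = 180,
                                    seed = 1L) {
  set.seed(seed)
  e <- engagement
  n <- n_app + n_usual
  arm <- c(rep("app", n_app), rep("usual_care", n_usual))
  h <- baseline_lapse_hazard
  rho <- message_effect_multiplier

  installed <- arm == "app" & stats::runif(n) < e$install_prob
  set_qd <- installed & stats::runif(n) < e$set_quit_date_given_install
  engagement_days <- ifelse(installed,
                            stats::rlnorm(n, e$engagement_meanlog,
                                          e$engagement_sdlog), 0)
  engaged_frac <- pmin(1, pmax(0, engagement_days - train_days) /
                            horizon_days)
  cov_p <- ifelse(set_qd, coverage_prob * engaged_frac, 0)

  exposures <- stats::rpois(n, exposures_per_day * horizon_days)
  cov_n <- stats::rbinom(n, exposures, cov_p)
  n_lapses <- stats::rbinom(n, exposures - cov_n, h) +
    stats::rbinom(n, cov_n, h * rho)
  relapsed <- stats::runif(n) < 1 - (1 - relapse_given_lapse)^n_lapses
  # lapse days uniform over the horizon: thin into recent windows
  p_any_week <- 1 - (1 - 7 / horizon_days)^n_lapses
  smoked_last7 <- relapsed | stats::runif(n) < p_any_week
  smoked_wk6 <- relapsed | stats::runif(n) < p_any_week
  true_prolonged <- !relapsed & n_lapses <= 5 & !smoked_last7
  true_pp7_6m <- !smoked_last7
  true_pp7_6w <- !smoked_wk6

  withdrawn <- stats::runif(n) < e$withdraw_prob
  responded_6m <- !withdrawn & stats::runif(n) < e$followup_prob_6m
  responded_6w <- !withdrawn & stats::runif(n) < e$followup_prob_6w
  misreport <- stats::runif(n) < e$misreport_prob
  sr <- function(truth, responded) ifelse(responded, truth | misreport, NA)
  self_prolonged <- sr(true_prolonged, responded_6m)
  self_pp7 <- sr(true_pp7_6m, responded_6m)
  self_pp7_6w <- sr(true_pp7_6w, responded_6w)

  saliva_p <- e$saliva_return_prob_by_arm[arm]
  returned <- !is.na(self_pp7) & self_pp7 & stats::runif(n) < saliva_p
  cotinine <- ifelse(returned,
                     ifelse(true_pp7_6m, stats::runif(n, 0, 5),
                            stats::runif(n, 50, 300)), NA_real_)
  anabasine <- ifelse(returned,
                      ifelse(true_pp7_6m, stats::runif(n, 0, 0.1),
                             stats::runif(n, 0.5, 5)), NA_real_)
  nrt <- stats::runif(n) < e$nrt_prob

  data.frame(id = sprintf("p%05d", seq_len(n)), arm = arm,
             installed = installed, set_quit_date = set_qd,
             engagement_days = engagement_days,
             n_lapses = n_lapses,
             true_prolonged_6m = true_prolonged,
             true_pp7_6m = true_pp7_6m, true_pp7_6w = true_pp7_6w,
             withdrawn = withdrawn,
             responded_6m = responded_6m, responded_6w = responded_6w,
             self_report_prolonged = self_prolonged,
             self_report_7day_6m = self_pp7,
             self_report_7day_6w = self_pp7_6w,
             cotinine = cotinine, anabasine = anabasine, nrt_use = nrt,
             stringsAsFactors = FALSE)
}

#' Validated-outcome 2x2 table of a participant table (vectorised)
#'
#' Applies the Russell-standard classification (missing = smoking) in
#' vector form and tabulates validated prolonged abstinence by arm.
#' Agrees with per-record [derive_validated_prolonged()]; the test suite
#' asserts so.
#'
#' @param participants a participants `data.frame`.
#' @param criteria a [russell_criteria()].
#' @return a [two_by_two()] (app arm as the exposed group).
#' @export
validated_counts <- function(participants, criteria = russell_criteria()) {
  p <- participants
  ok <- !p$withdrawn &
    !is.na(p$self_report_prolonged) & p$self_report_prolonged &
    !is.na(p$self_report_7day_6m) & p$self_report_7day_6m &
    !is.na(p$cotinine) & p$cotinine < criteria$cotinine_cutoff_ng_ml &
    (!p$nrt_use | (!is.na(p$anabasine) &
                     p$anabasine < criteria$anabasine_cutoff_ng_ml))
  app <- p$arm == "app"
  two_by_two(sum(ok & app), sum(app) - sum(ok & app),
             sum(ok & !app), sum(!app) - sum(ok & !app))
}
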