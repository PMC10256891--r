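# Derivation of trial abstinence outcomes and assembly of the
# outcome/feasibility reports.  The anticipated primary outcome follows
# the Russell-standard convention: self-reported prolonged abstinence
# (at most five cigarettes since the quit date and none in the previous
# week) biochemically validated by saliva cotinine < 10 ng/ml, with
# anabasine < 0.2 ng/ml additionally required for users of non-tobacco
# nicotine substitution, and withdrawn or missing treated as smoking.

#' Russell-standard outcome criteria
#'
#' @param max_cigarettes_since_quit allowed cigarettes since quitting.
#' @param no_smoking_days smoke-free days required before follow-up.
#' @param cotinine_cutoff_ng_ml saliva cotinine threshold.
#' @param anabasine_cutoff_ng_ml anabasine threshold for nicotine
#'   substitution users.
#' @param missing_is_smoking treat missing/withdrawn as smoking?
#' @return an object of class `russell_criteria`.
#' @export
russell_criteria <- function(max_cigarettes_since_quit = 5,
                             no_smoking_days = 7,
                             cotinine_cutoff_ng_ml = 10,
                             anabasine_cutoff_ng_ml = 0.2,
                             missing_is_smoking = TRUE) {
  stopifnot(cotinine_cutoff_ng_ml > 0, anabasine_cutoff_ng_ml > 0,
            no_smoking_days > 0)
  structure(list(max_cigarettes_since_quit = max_cigarettes_since_quit,
                 no_smoking_days = no_smoking_days,
                 cotinine_cutoff_ng_ml = cotinine_cutoff_ng_ml,
                 anabasine_cutoff_ng_ml = anabasine_cutoff_ng_ml,
                 missing_is_smoking = missing_is_smoking),
            class = "russell_criteria")
}

#' A participant's observed outcome record
#'
#' @param arm `"app"` or `"usual_care"`.
#' @param self_report_prolonged prolonged-abstinence self-report (logical
#'   or `NA` if missing).
#' @param self_report_7day_6m 7-day point-prevalence self-report at 6
#'   months (logical or `NA`).
#' @param self_report_7day_6w as above at 6 weeks.
#' @param cotinine saliva cotinine ng/ml, or `NA` if no sample returned.
#' @param anabasine saliva anabasine ng/ml, or `NA`.
#' @param nicotine_substitution_use uses non-tobacco nicotine products?
#' @param withdrawn withdrew from the trial?
#' @return an object of class `outcome_record`.
#' @export
outcome_record <- function(arm,
                           self_report_prolonged = NA,
                           self_report_7day_6m = NA,
                           self_report_7day_6w = NA,
                           cotinine = NA_real_,
                           anabasine = NA_real_,
                           nicotine_substitution_use = FALSE,
                           withdrawn = FALSE) {
  stopifnot(arm %in% c("app", "usual_care"))
  if ((!is.na(cotinine) && cotinine < 0) ||
      (!is.na(anabasine) && anabasine < 0)) {
    stop_jitai("assay concentrations cannot be negative",
               class = "jitai_validation")
  }
  structure(list(arm = arm,
                 self_report_prolonged = self_report_prolonged,
                 self_report_7day_6m = self_report_7day_6m,
                 self_report_7day_6w = self_report_7day_6w,
                 cotinine = cotinine, anabasine = anabasine,
                 nicotine_substitution_use = isTRUE(nicotine_substitution_use),
                 withdrawn = isTRUE(withdrawn)),
            class = "outcome_record")
}

#' Derive biochemically validated prolonged abstinence
#'
#' `TRUE` only when the participant self-reports both prolonged abstinence
#' and 7-day point prevalence, a saliva sample was returned with cotinine
#' below the cutoff, and -- for nicotine-substitution users -- anabasine
#' below its cutoff.  Withdrawn participants and any missing pathway are
#' classified as smoking.
#'
#' @param record an [outcome_record()].
#' @param criteria a [russell_criteria()].
#' @return `TRUE`/`FALSE`.
#' @export
derive_validated_prolonged <- function(record,
                                       criteria = russell_criteria()) {
  stopifnot(inherits(record, "outcome_record"),
            inherits(criteria, "russell_criteria"))
  if (record$withdrawn) return(FALSE)
  if (is.na(record$self_report_prolonged) ||
      !isTRUE(record$self_report_prolonged)) return(FALSE)
  if (is.na(record$self_report_7day_6m) ||
      !isTRUE(record$self_report_7day_6m)) return(FALSE)
  if (is.na(record$cotinine)) return(FALSE)
  if (record$cotinine >= criteria$cotinine_cutoff_ng_ml) return(FALSE)
  if (record$nicotine_substitution_use) {
    if (is.na(record$anabasine) ||
        record$anabasine >= criteria$anabasine_cutoff_ng_ml) return(FALSE)
  }
  TRUE
}

#' Derive validated 7-day point-prevalence abstinence at 6 months
#'
#' @inheritParams derive_validated_prolonged
#' @return `TRUE`/`FALSE`.
#' @export
derive_validated_7day <- function(record, criteria = russell_criteria()) {
  stopifnot(inherits(record, "outcome_record"))
  if (record$withdrawn) return(FALSE)
  if (is.na(record$self_report_7day_6m) ||
      !isTRUE(record$self_report_7day_6m)) return(FALSE)
  if (is.na(record$cotinine) ||
      record$cotinine >= criteria$cotinine_cutoff_ng_ml) return(FALSE)
  if (record$nicotine_substitution_use) {
    if (is.na(record$anabasine) ||
        record$anabasine >= criteria$anabasine_cutoff_ng_ml) return(FALSE)
  }
  TRUE
}

#' Derive a self-reported outcome with missing = smoking
#'
#' @param value logical or `NA` self-report.
#' @param withdrawn withdrawn flag.
#' @return `TRUE`/`FALSE`.
#' @export
derive_self_report <- function(value, withdrawn = FALSE) {
  if (isTRUE(withdrawn)) return(FALSE)
  isTRUE(value)
}

outcome_row <- function(name, k1, n1, k2, n2, alpha = 0.05) {
  rd <- risk_difference_newcombe(two_by_two(k1, n1 - k1, k2, n2 - k2),
                                 alpha)
  or <- tryCatch(odds_ratio_wald(two_by_two(k1, n1 - k1, k2, n2 - k2),
                                 alpha),
                 jitai_degenerate = function(e) NULL)
  data.frame(
    outcome = name,
    app_n = k1, app_N = n1, app_pct = 100 * k1 / n1,
    usual_n = k2, usual_N = n2, usual_pct = 100 * k2 / n2,
    diff_pct = 100 * rd$estimate,
    diff_lo = 100 * rd$ci_low, diff_hi = 100 * rd$ci_high,
    or = if (is.null(or)) NA_real_ else or$estimate,
    or_lo = if (is.null(or)) NA_real_ else or$ci_low,
    or_hi = if (is.null(or)) NA_real_ else or$ci_high,
    p_value = if (is.null(or)) NA_real_ else or$p_value,
    estimable = !is.null(or),
    stringsAsFactors = FALSE
  )
}

#' Analyse a trial dataset into an outcome table
#'
#' Derives the four abstinence outcomes (validated prolonged, validated
#' 7-day at 6 months, self-reported 7-day at 6 months and at 6 weeks)
#' under missing = smoking, and reports per-arm counts, Newcombe risk
#' differences and Wald odds ratios -- one row per outcome.
#'
#' @param dataset a `trial_dataset` from [simulate_trial()], or a
#'   `data.frame` shaped like its `participants` component.
#' @param criteria a [russell_criteria()].
#' @param alpha interval error rate.
#' @return a `data.frame`, one row per outcome.
#' @export
analyze_trial <- function(dataset, criteria = russell_criteria(),
                          alpha = 0.05) {
  p <- if (inherits(dataset, "trial_dataset")) dataset$participants
       else dataset
  stopifnot(is.data.frame(p), nrow(p) > 0,
            all(c("arm", "self_report_prolonged", "self_report_7day_6m",
                  "self_report_7day_6w", "cotinine", "anabasine",
                  "nrt_use", "withdrawn") %in% names(p)))
  derive <- function(i) {
    rec <- outcome_record(
      arm = p$arm[i],
      self_report_prolonged = p$self_report_prolonged[i],
      self_report_7day_6m = p$self_report_7day_6m[i],
      self_report_7day_6w = p$self_report_7day_6w[i],
      cotinine = p$cotinine[i], anabasine = p$anabasine[i],
      nicotine_substitution_use = p$nrt_use[i],
      withdrawn = p$withdrawn[i])
    c(prolonged = derive_validated_prolonged(rec, criteria),
      pp7_valid = derive_validated_7day(rec, criteria),
      pp7_self = derive_self_report(rec$self_report_7day_6m, rec$withdrawn),
      pp7_6w = derive_self_report(rec$self_report_7day_6w, rec$withdrawn))
  }
  derived <- t(vapply(seq_len(nrow(p)), derive, logical(4)))
  app <- p$arm == "app"
  n1 <- sum(app); n2 <- sum(!app)
  rows <- rbind(
    outcome_row("prolonged_6m_validated",
                sum(derived[app, "prolonged"]), n1,
                sum(derived[!app, "prolonged"]), n2, alpha),
    outcome_row("pp7_6m_validated",
                sum(derived[app, "pp7_valid"]), n1,
                sum(derived[!app, "pp7_valid"]), n2, alpha),
    outcome_row("pp7_6m_self_report",
                sum(derived[app, "pp7_self"]), n1,
                sum(derived[!app, "pp7_self"]), n2, alpha),
    outcome_row("pp7_6w_self_report",
                sum(derived[app, "pp7_6w"]), n1,
                sum(derived[!app, "pp7_6w"]), n2, alpha))
  rows
}

#' Feasibility summary
#'
#' Completion, installation and engagement rates with Wald 95% intervals,
#' plus advertising cost per recruit.
#'
#' @param dataset a `trial_dataset` or participants `data.frame` (may be
#'   `NULL` if only costs are of interest).
#' @param costs optional list: `total` advertising cost and optionally
#'   named per-channel lists `list(cost =, recruits =)` under `channels`.
#' @param alpha interval error rate.
#' @return a list of rate estimates and cost arithmetic.
#' @export
feasibility_summary <- function(dataset = NULL, costs = NULL,
                                alpha = 0.05) {
  out <- list()
  if (!is.null(dataset)) {
    p <- if (inherits(dataset, "trial_dataset")) dataset$participants
         else dataset
    n <- nrow(p)
    if (n == 0) stop_jitai("no randomized participants",
                           class = "jitai_degenerate")
    rate <- function(k, n) {
      est <- tryCatch(proportion_ci_wald(k, n, alpha),
                      jitai_degenerate = function(e)
                        proportion_ci_clopper_pearson(k, n, alpha))
      list(k = k, n = n, prop = k / n, ci_low = est$ci_low,
           ci_high = est$ci_high, method = est$method)
    }
    out$followup_6m <- rate(sum(p$responded_6m), n)
    out$followup_6w <- rate(sum(p$responded_6w), n)
    self_abst <- !is.na(p$self_report_prolonged) & p$self_report_prolonged &
      !p$withdrawn
    if (any(self_abst)) {
      out$saliva_return <- rate(sum(!is.na(p$cotinine[self_abst])),
                                sum(self_abst))
    }
    app <- p$arm == "app"
    if (any(app)) {
      out$install <- rate(sum(p$installed[app]), sum(app))
      inst <- app & p$installed
      if (any(inst)) {
        out$engaged_gt7d <- rate(sum(p$engagement_days[inst] > 7),
                                 sum(inst))
        out$median_engagement_days <-
          stats::median(p$engagement_days[inst])
      }
    }
  }
  if (!is.null(costs)) {
    n_recruits <- costs$recruits %||%
      (if (!is.null(dataset)) nrow(if (inherits(dataset, "trial_dataset"))
        dataset$participants else dataset) else NULL)
    if (is.null(n_recruits) || n_recruits == 0) {
      stop_jitai("cost per recruit needs a positive recruit count",
                 class = "jitai_degenerate")
    }
    out$cost_per_recruit <- costs$total / n_recruits
    if (!is.null(costs$channels)) {
      out$channel_cost_per_recruit <- lapply(costs$channels, function(ch)
        ch$cost / ch$recruits)
    }
  }
  out
}
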