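# Message tailoring and ancillary in-app feedback features.
#
# Message bodies are placeholders: what matters (and is tested) is the tag
# taxonomy and the selection contract -- stage and situation filters,
# context tailoring, and a no-repeat-until-exhausted cycling policy.

CONTEXT_TAGS <- c("stress", "low_mood", "strong_urge", "others_present",
                  "generic")

#' Build a message library
#'
#' @param messages a `data.frame` with columns `id`, `stage_tags`,
#'   `situation_tags`, `context_tags` (each a `|`-separated tag string),
#'   `bct_tag` and `body`.
#' @param cycle_policy only `"no_repeat_until_exhausted"` is supported.
#' @return an object of class `message_library`.
#' @export
message_library <- function(messages,
                            cycle_policy = "no_repeat_until_exhausted") {
  stopifnot(is.data.frame(messages), nrow(messages) > 0,
            all(c("id", "stage_tags", "situation_tags", "context_tags",
                  "bct_tag", "body") %in% names(messages)),
            cycle_policy == "no_repeat_until_exhausted")
  if (anyDuplicated(messages$id)) {
    stop_jitai("message ids must be unique", class = "jitai_validation")
  }
  if (any(!nzchar(messages$stage_tags))) {
    stop_jitai("every message needs at least one stage tag",
               class = "jitai_validation")
  }
  for (st in c("training", "committed", "maintenance")) {
    for (sit in SITUATIONS) {
      ok <- has_tag(messages$stage_tags, st) &
        (has_tag(messages$situation_tags, sit) |
           has_tag(messages$situation_tags, "any"))
      if (!any(ok)) {
        stop_jitai("no message eligible for stage %s / situation %s",
                   st, sit, class = "jitai_validation")
      }
    }
  }
  structure(list(messages = messages, cycle_policy = cycle_policy),
            class = "message_library")
}

has_tag <- function(tags, tag) {
  vapply(strsplit(tags, "|", fixed = TRUE),
         function(x) tag %in% x, logical(1))
}

#' Default built-in message library
#'
#' One placeholder message per (stage, situation, context) combination,
#' each labelled with a behaviour-change-technique carrier tag.  Bodies are
#' synthetic stand-ins; the deployed advice text is not public.
#'
#' @return a `message_library`.
#' @export
default_message_library <- function() {
  grid <- expand.grid(stage = c("training", "committed", "maintenance"),
                      situation = SITUATIONS,
                      context = CONTEXT_TAGS,
                      stringsAsFactors = FALSE)
  msgs <- data.frame(
    id = sprintf("msg_%03d", seq_len(nrow(grid))),
    stage_tags = grid$stage,
    situation_tags = grid$situation,
    context_tags = grid$context,
    bct_tag = sprintf("bct_%02d", (seq_len(nrow(grid)) - 1L) %% 21L + 1L),
    body = sprintf("[%s/%s/%s] placeholder support text",
                   grid$stage, grid$situation, grid$context),
    stringsAsFactors = FALSE
  )
  message_library(msgs)
}

#' Dominant context of a geofence
#'
#' Modal elevated-context tag over the fence's smoking reports; ties are
#' broken by the fixed priority urge > stress > mood > others.  Returns
#' `"generic"` when no context was ever elevated.
#'
#' @param fence a fence element of an `engine_state`.
#' @return a context tag string.
#' @export
fence_dominant_context <- function(fence) {
  counts <- fence$context[c("strong_urge", "stress", "low_mood",
                            "others_present")]
  if (all(counts == 0)) return("generic")
  names(counts)[which.max(counts)]  # which.max takes the first = priority
}

modal_situation <- function(fence) {
  s <- fence$situations
  if (all(s == 0)) return("other")
  names(s)[which.max(s)]
}

eligible_messages <- function(library, stage, situation) {
  m <- library$messages
  ok <- has_tag(m$stage_tags, stage) &
    (has_tag(m$situation_tags, situation) |
       has_tag(m$situation_tags, "any"))
  m[ok, , drop = FALSE]
}

pick_deterministic <- function(ids, seed, counter) {
  ids <- sort(ids)
  ids[floor(counter_unif(seed, counter) * length(ids)) + 1L]
}

#' Select a geofence-triggered support message
#'
#' Filters the library to the engine stage and the fence's modal situation,
#' prefers messages tailored to the fence's dominant context, and among the
#' eligible set prefers ids not yet in `history` (the cycle resets once all
#' eligible messages have been sent).  Selection is deterministic given
#' `(seed, history)`.
#'
#' @param library a [message_library()].
#' @param fence a fence element of an `engine_state`.
#' @param dominant_context optional context tag; defaults to
#'   [fence_dominant_context()].
#' @param stage engine stage.
#' @param history character vector of previously sent message ids.
#' @param seed integer.
#' @return one row of the library as a list (a support message).
#' @export
select_gts_message <- function(library, fence, dominant_context = NULL,
                               stage = "committed", history = character(0),
                               seed = 1L) {
  stopifnot(inherits(library, "message_library"))
  ctx <- dominant_context %||% fence_dominant_context(fence)
  elig <- eligible_messages(library, stage, modal_situation(fence))
  if (nrow(elig) == 0) {
    elig <- library$messages[has_tag(library$messages$context_tags,
                                     "generic"), , drop = FALSE]
  }
  if (nrow(elig) == 0) {
    stop_jitai("message library has no eligible or generic messages",
               class = "jitai_config")
  }
  unsent <- elig[!elig$id %in% history, , drop = FALSE]
  pool <- if (nrow(unsent) > 0) unsent else elig  # exhausted -> cycle reset
  tailored <- pool[has_tag(pool$context_tags, ctx), , drop = FALSE]
  if (nrow(tailored) > 0) pool <- tailored
  id <- pick_deterministic(pool$id, seed, length(history))
  as.list(pool[pool$id == id, ])
}

#' Feedback message after a smoking report
#'
#' Mirrors the on-screen feedback that follows each smoking report: the
#' chosen message's context tag matches the report's most elevated context
#' field (urge >= 4, stress >= 4, mood <= 1, other smokers present, in that
#' priority order), falling back to a generic message.
#'
#' @param report a [smoking_report()].
#' @param state an `engine_state` (its stage selects the stage tag).
#' @param library a [message_library()].
#' @return a support message (list).
#' @export
post_report_feedback <- function(report, state,
                                 library = default_message_library()) {
  stopifnot(inherits(report, "smoking_report"))
  inc <- report_context_increments(report)
  ctx <- if (inc[["strong_urge"]] > 0) "strong_urge"
    else if (inc[["stress"]] > 0) "stress"
    else if (inc[["low_mood"]] > 0) "low_mood"
    else if (inc[["others_present"]] > 0) "others_present"
    else "generic"
  stage <- if (state$stage == "stopped") "maintenance" else state$stage
  elig <- eligible_messages(library, stage, report$situation)
  tailored <- elig[has_tag(elig$context_tags, ctx), , drop = FALSE]
  pool <- if (nrow(tailored) > 0) tailored else
    elig[has_tag(elig$context_tags, "generic"), , drop = FALSE]
  as.list(pool[1, ])
}

#' Scheduled morning message
#'
#' One message per local day, oriented around the quit date: pre-quit days
#' draw from training-stage messages (countdown), the quit day and later
#' from committed/maintenance-stage messages, indexed deterministically by
#' the signed day offset so repeated calls on one day agree.
#'
#' @param library a [message_library()].
#' @param date today's `Date`.
#' @param quit_date quit `Date`.
#' @return a support message (list).
#' @export
morning_message <- function(library, date, quit_date) {
  stopifnot(inherits(date, "Date"), inherits(quit_date, "Date"))
  offset <- as.integer(date - quit_date)
  stage <- if (offset < 0) "training"
    else if (offset < 28) "committed" else "maintenance"
  m <- library$messages[has_tag(library$messages$stage_tags, stage), ,
                        drop = FALSE]
  m <- m[order(m$id), , drop = FALSE]
  as.list(m[abs(offset) %% nrow(m) + 1L, ])
}

#' Profile statistics: days quit and money saved
#'
#' `money_saved = days_quit * cigarettes_per_day * price_per_cigarette`,
#' with `days_quit` the whole days elapsed since the quit date (0 before
#' it).
#'
#' @param quit_date quit `Date`.
#' @param now current `Date`.
#' @param cigarettes_per_day baseline smoking rate.
#' @param price_per_cigarette currency units per cigarette.
#' @return `list(days_quit =, money_saved =)`.
#' @export
profile_stats <- function(quit_date, now, cigarettes_per_day,
                          price_per_cigarette) {
  stopifnot(inherits(quit_date, "Date"), inherits(now, "Date"),
            cigarettes_per_day >= 0, price_per_cigarette >= 0)
  days <- max(0L, as.integer(now - quit_date))
  list(days_quit = days,
       money_saved = days * cigarettes_per_day * price_per_cigarette)
}

#' End-of-day survey entry with emoji feedback code
#'
#' The calendar emoji code is a pure function of the three survey
#' responses: smoked yes/no, craving level and self-efficacy (both 0-5,
#' split at >= 3).
#'
#' @param date `Date` of the entry.
#' @param smoked did the user smoke today?
#' @param craving_level ordinal 0-5.
#' @param self_efficacy ordinal 0-5.
#' @return a list with the responses and derived `emoji_code`.
#' @export
end_of_day_entry <- function(date, smoked, craving_level, self_efficacy) {
  stopifnot(inherits(date, "Date"),
            craving_level >= 0, craving_level <= 5,
            self_efficacy >= 0, self_efficacy <= 5)
  code <- paste(
    if (smoked) "smoked" else "smoke_free",
    if (craving_level >= 3) "craving_high" else "craving_low",
    if (self_efficacy >= 3) "confidence_high" else "confidence_low",
    sep = "|")
  list(date = date, smoked = isTRUE(smoked),
       craving_level = as.integer(craving_level),
       self_efficacy = as.integer(self_efficacy),
       emoji_code = code)
}

#' Summarise reported smoking triggers
#'
#' Counts and proportions of smoking reports by situation, presence of
#' other smokers, and elevated urge/stress -- the data behind the app's
#' smoking-pattern feedback.
#'
#' @param reports list of [smoking_report()] events.
#' @return a list of `data.frame`s (`situation`, `others_present`,
#'   `high_urge`, `high_stress`), each with `count` and `prop` columns, or
#'   an empty list for no reports.
#' @export
smoking_pattern_summary <- function(reports) {
  if (length(reports) == 0) return(list())
  tab <- function(values, levels) {
    counts <- vapply(levels, function(l) sum(values == l), integer(1))
    data.frame(level = levels, count = counts,
               prop = counts / length(values),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  situations <- vapply(reports, function(r) r$situation, character(1))
  others <- vapply(reports, function(r) r$others_present, logical(1))
  urge <- vapply(reports, function(r) r$urge_strength >= 4, logical(1))
  stress <- vapply(reports, function(r) r$stress >= 4, logical(1))
  list(situation = tab(situations, SITUATIONS),
       others_present = tab(others, c(TRUE, FALSE)),
       high_urge = tab(urge, c(TRUE, FALSE)),
       high_stress = tab(stress, c(TRUE, FALSE)))
}
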