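engagement_levels <- c("infrequent", "intermediate", "frequent")

#' Fraction of window days with a registered symptom score
#'
#' App usage is measured as the fraction of days the user registered a
#' symptom score out of the days in a window defined relative to an
#' exacerbation onset (day 0). The canonical windows are the 70 days
#' prior (`c(-70, -1)`), the 70 days post (`c(1, 70)`) and the 21 days
#' immediately prior (`c(-21, -1)`).
#'
#' @param symptoms validated symptom table.
#' @param user user identifier.
#' @param onset_date event onset (day 0), `Date`.
#' @param window integer vector `c(start_offset, end_offset)` in days
#'   relative to onset, inclusive.
#' @return fraction in \[0, 1\].
#' @export
usage_fraction <- function(symptoms, user, onset_date, window = c(-70, -1)) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  len <- window[2] - window[1] + 1L
  if (len < 1) stop("zero-length window")
  lo <- as.Date(onset_date) + window[1]
  hi <- as.Date(onset_date) + window[2]
  uid <- user
  n <- nrow(unique(data.table::as.data.table(symptoms)[
    user_id == uid & date >= lo & date <= hi], by = "date"))
  n / len
}

#' Classify engagement from a usage fraction
#'
#' Frequent users register activity on at least 66% of the possible
#' days, infrequent users on fewer than 33%, intermediate in between.
#' Boundaries follow the printed thresholds: `frequent` is closed at the
#' upper threshold (0.66 maps to frequent) and `infrequent` open at the
#' lower one (0.33 maps to intermediate).
#'
#' @param fraction numeric vector of usage fractions in \[0, 1\].
#' @param lower,upper class boundaries (defaults 0.33 and 0.66).
#' @return ordered factor with levels `infrequent < intermediate <
#'   frequent`.
#' @export
classify_engagement <- function(fraction, lower = 0.33, upper = 0.66) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1))
    stop("usage fraction must lie in [0, 1]")
  cls <- ifelse(fraction >= upper, "frequent",
                ifelse(fraction < lower, "infrequent", "intermediate"))
  factor(cls, levels = engagement_levels, ordered = TRUE)
}

#' Detect transitional engagement near exacerbation
#'
#' A non-frequent user (by 70-day class) transitions to "engaged near
#' exacerbation" when their usage fraction over the 21 days immediately
#' prior to onset classifies into a strictly higher engagement class.
#' Frequent users have no higher class and are always `consistent`.
#'
#' @param class70 engagement class over the 70-day pre-window (factor or
#'   character).
#' @param pre21_fraction usage fraction over days -21..-1.
#' @inheritParams classify_engagement
#' @return factor with levels `consistent`, `engaged_near_exacerbation`.
#' @export
classify_transition <- function(class70, pre21_fraction, lower = 0.33, upper = 0.66) {
  c70 <- factor(as.character(class70), levels = engagement_levels, ordered = TRUE)
  if (anyNA(c70)) stop("invalid engagement class")
  c21 <- classify_engagement(pre21_fraction, lower, upper)
  out <- ifelse(c21 > c70, "engaged_near_exacerbation", "consistent")
  factor(out, levels = c("consistent", "engaged_near_exacerbation"))
}

#' Label pre-exacerbation self-report quality
#'
#' Pre-onset reports (days -70..-1) are labelled: `undetermined` with
#' fewer than `min_reports` reports; `fixed_reporting` when all reports
#' share one distinct score (e.g. only 1s or only 3s, carrying no
#' predictive signal); `reporting_with_signal` when scores vary and the
#' mean over the final week (days -7..-1) exceeds the mean over the
#' prior baseline (days -70..-8) by at least `signal_rise` (the
#' deterioration is visible in the diary); otherwise `neither`.
#'
#' @param day_offset integer day offsets relative to onset (must lie in
#'   -70..-1).
#' @param score symptom scores for those offsets.
#' @param min_reports minimum number of reports to assess quality.
#' @param signal_rise required mean-score rise (score points) in the
#'   final week relative to baseline.
#' @return one of `"fixed_reporting"`, `"reporting_with_signal"`,
#'   `"neither"`, `"undetermined"`.
#' @export
classify_quality <- function(day_offset, score, min_reports = 5, signal_rise = 0.5) {
  stopifnot(length(day_offset) == length(score))
  keep <- day_offset >= -70 & day_offset <= -1
  day_offset <- day_offset[keep]; score <- score[keep]
  if (length(score) < min_reports) return("undetermined")
  if (length(unique(score)) == 1L) return("fixed_reporting")
  recent <- score[day_offset >= -7]
  base <- score[day_offset <= -8]
  if (length(recent) && length(base) &&
      mean(recent) - mean(base) >= signal_rise)
    return("reporting_with_signal")
  "neither"
}

#' Flag possible disengagement after an exacerbation
#'
#' True when the event window shows either a registered symptom score of
#' 4 (needed to seek emergency care) anywhere in days -70..+70, or a
#' notable reporting gap directly after the event: at least `gap_days`
#' consecutive unreported days starting within days +1..+14.
#'
#' @param day_offset integer day offsets (-70..+70) with a registered
#'   score.
#' @param score scores at those offsets.
#' @param gap_days length of an unreported run counting as a notable gap.
#' @return logical scalar.
#' @export
flag_post_disengagement <- function(day_offset, score, gap_days = 14) {
  stopifnot(length(day_offset) == length(score))
  if (any(score == 4 & day_offset >= -70 & day_offset <= 70)) return(TRUE)
  reported <- unique(day_offset[day_offset >= 1 & day_offset <= 70])
  for (s in 1:14) {
    if (s + gap_days - 1 > 70) break
    if (!any(reported >= s & reported <= s + gap_days - 1)) return(TRUE)
  }
  FALSE
}

#' Build per-event engagement profiles
#'
#' For each exacerbation event, computes the 70-day pre/post and 21-day
#' pre usage fractions, the engagement classes they imply, the
#' transition label, the pre-onset self-report quality label, and the
#' post-event disengagement flag.
#'
#' @param events `exacerbation_events` table from
#'   [identify_exacerbations()].
#' @param symptoms validated symptom table.
#' @param lower,upper engagement class boundaries.
#' @param min_reports,signal_rise see [classify_quality()].
#' @param gap_days see [flag_post_disengagement()].
#' @return `data.table` of class `engagement_profiles`, one row per
#'   event, with an `event_id` key and a `group` column naming the five
#'   evaluation strata (frequent, intermediate/infrequent x
#'   consistent/engaged-near-exacerbation).
#' @export
build_engagement_profiles <- function(events, symptoms, lower = 0.33, upper = 0.66,
                                      min_reports = 5, signal_rise = 0.5,
                                      gap_days = 14) {
  ev <- data.table::as.data.table(events)
  sy <- data.table::as.data.table(symptoms)
  if (!nrow(ev)) stop("no events to profile")
  ev <- ev[order(user_id, onset_date)]
  ev[, event_id := sprintf("%s_e%02d", user_id, seq_len(.N)), by = user_id]

  one <- function(uid, onset) {
    s <- sy[user_id == uid & date >= onset - 70 & date <= onset + 70]
    off <- as.integer(s$date - onset)
    list(off = off, score = s$score)
  }
  res <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    w <- one(ev$user_id[i], ev$onset_date[i])
    pre70 <- sum(w$off >= -70 & w$off <= -1) / 70
    post70 <- sum(w$off >= 1 & w$off <= 70) / 70
    pre21 <- sum(w$off >= -21 & w$off <= -1) / 21
    keep <- w$off >= -70 & w$off <= -1
    res[[i]] <- data.table::data.table(
      pre70_fraction = pre70, post70_fraction = post70, pre21_fraction = pre21,
      quality = classify_quality(w$off[keep], w$score[keep], min_reports, signal_rise),
      post_disengaged = flag_post_disengagement(w$off, w$score, gap_days))
  }
  out <- cbind(ev[, .(event_id, user_id, onset_date, course_length,
                      first_for_user, retrospective)],
               data.table::rbindlist(res))
  out[, class70 := classify_engagement(pre70_fraction, lower, upper)]
  out[, class21 := classify_engagement(pre21_fraction, lower, upper)]
  out[, transition := classify_transition(class70, pre21_fraction, lower, upper)]
  out[, group := engagement_group(class70, transition)]
  data.table::setattr(out, "class", c("engagement_profiles", class(out)))
  out[]
}

#' Five evaluation strata from class and transition
#'
#' @param class70 engagement class (factor/character).
#' @param transition transition label (factor/character).
#' @return factor with levels `infrequent_consistent`, `infrequent_ene`,
#'   `intermediate_consistent`, `intermediate_ene`, `frequent`.
#' @export
engagement_group <- function(class70, transition) {
  cls <- as.character(class70)
  tr <- as.character(transition)
  g <- ifelse(cls == "frequent", "frequent",
              paste0(cls, ifelse(tr == "engaged_near_exacerbation", "_ene", "_consistent")))
  factor(g, levels = c("infrequent_consistent", "infrequent_ene",
                       "intermediate_consistent", "intermediate_ene", "frequent"))
}

#' Summarise an engagement-profile collection
#'
#' Counts and percentage shares per engagement class, per transition
#' label within the non-frequent classes (plus their combined share),
#' and per quality label within each class. Counts are conserved and
#' percentages within a margin sum to 100 up to rounding.
#'
#' @param profiles `engagement_profiles` table (or any table with
#'   `class70`, `transition`, `quality`, `post_disengaged`,
#'   `retrospective` columns).
#' @return list of class `engagement_summary`: `n_events`,
#'   `class_counts`, `class_pct`, `transition_pct` (per non-frequent
#'   class), `transition_combined_pct` (share of transitional events
#'   among all non-frequent events), `quality_pct` (class x quality),
#'   `post_disengaged_pct`, `retrospective_pct` (per class, of events
#'   with a known entry date).
#' @export
engagement_summary <- function(profiles) {
  p <- data.table::as.data.table(profiles)
  if (!nrow(p)) stop("empty profile collection")
  n <- nrow(p)
  cls <- factor(as.character(p$class70), levels = engagement_levels)
  class_counts <- table(cls)
  class_pct <- 100 * as.numeric(class_counts) / n
  names(class_pct) <- names(class_counts)

  nf <- p[as.character(class70) != "frequent"]
  trans_pct <- sapply(c("infrequent", "intermediate"), function(k) {
    sub <- p[as.character(class70) == k]
    if (!nrow(sub)) return(NA_real_)
    100 * mean(as.character(sub$transition) == "engaged_near_exacerbation")
  })
  trans_combined <- if (nrow(nf))
    100 * mean(as.character(nf$transition) == "engaged_near_exacerbation") else NA_real_

  quality_pct <- p[, .(n = .N), by = .(class70 = as.character(class70),
                                       quality = as.character(quality))]
  quality_pct[, pct := 100 * n / sum(n), by = class70]

  retro <- p[!is.na(retrospective),
             .(pct = 100 * mean(retrospective)), by = .(class70 = as.character(class70))]

  out <- list(
    n_events = n,
    class_counts = stats::setNames(as.integer(class_counts), names(class_counts)),
    class_pct = class_pct,
    transition_pct = trans_pct,
    transition_combined_pct = trans_combined,
    quality_pct = quality_pct[],
    post_disengaged_pct = 100 * mean(p$post_disengaged %in% TRUE),
    retrospective_pct = stats::setNames(retro$pct, retro$class70))
  class(out) <- "engagement_summary"
  out
}

#' @export
print.engagement_summary <- function(x, ...) {
  cat("Engagement summary over", x$n_events, "exacerbation events\n")
  for (k in names(x$class_pct))
    cat(sprintf("  %-12s %4d (%.1f%%)\n", k, x$class_counts[[k]], x$class_pct[[k]]))
  cat(sprintf("  transitional (engaged near exacerbation): %.1f%% of non-frequent\n",
              x$transition_combined_pct))
  cat(sprintf("  post-event disengagement flag: %.1f%% of events\n",
              x$post_disengaged_pct))
  invisible(x)
}
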