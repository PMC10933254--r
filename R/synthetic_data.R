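#' Configuration for the synthetic diary cohort
#'
#' Defaults encode the study world the package emulates: a cohort of 243
#' users contributing ~727 rescue-pack exacerbations, an engagement mix
#' of 18.2% infrequent / 21.5% intermediate / 60.3% frequent (the
#' printed 132/156/438 shares), transition probabilities of 14.4%
#' (infrequent) and 21.8% (intermediate), retrospective rescue-pack
#' entry for 69.7% of infrequent events, reliever (salbutamol) usage
#' whose mean peaks on the onset day while mean symptom scores peak
#' `saba_lead_days` (3) days later, and a 7-day prodromal rise in
#' scores before onset.
#'
#' @param n_users number of synthetic users.
#' @param engagement_mix named proportions over
#'   infrequent/intermediate/frequent (must sum to 1).
#' @param transition_prob per-class probability that an event shows the
#'   near-onset engagement rise.
#' @param report_prob per-class daily reporting probability (archetype
#'   band centres: <0.33, 0.33-0.66, >=0.66).
#' @param ene_report_prob reporting probability over the 21 days before
#'   onset for transition-flagged events: just above the next class's
#'   lower boundary (transitioners cross into the next engagement
#'   class, they do not jump to its band centre).
#' @param baseline_score_dist categorical distribution of scores
#'   {1,2,3} on unremarkable days.
#' @param high_score_dist score distribution {1..4} at peak severity.
#' @param prodrome_days days of prodromal score rise before onset.
#' @param prodrome_shift maximum mixing weight moved from the baseline
#'   to the high-score distribution at peak severity (0-1).
#' @param prodrome_power exponent of the pre-onset severity ramp; values
#'   above 1 concentrate the score rise in the final days before onset
#'   (the event-aligned mean-score curve rises steeply just before the
#'   rescue pack is started and peaks a few days after).
#' @param class_shift_factor per-class multiplier on the severity
#'   signal carried by self-reports: confidence in recognising
#'   deterioration grows with engagement and exacerbation experience,
#'   so less engaged users' scores under-express severity.
#' @param first_event_shift_factor multiplier on `prodrome_shift` for a
#'   user's first event (first-timers under-report symptom severity).
#' @param saba_lead_days days by which the mean SABA peak (onset day)
#'   precedes the mean symptom-score peak.
#' @param saba_base,saba_amp baseline and peak-added Poisson rate of
#'   daily reliever doses.
#' @param events_per_user_lambda Poisson rate; events per user is
#'   `1 + Poisson(lambda)` truncated at 6.
#' @param course_length_range inclusive range of rescue-pack course
#'   lengths in days (within the 10-day event limit).
#' @param retrospective_prob per-class probability the rescue pack is
#'   entered in-app more than 10 days after onset.
#' @param post_gap_prob probability of a forced reporting gap directly
#'   after the event.
#' @param emergency_prob probability an event carries a score-4
#'   (emergency care) report.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_users = 243,
                          engagement_mix = c(infrequent = 0.182, intermediate = 0.215,
                                             frequent = 0.603),
                          transition_prob = c(infrequent = 0.144, intermediate = 0.218,
                                              frequent = 0),
                          report_prob = c(infrequent = 0.15, intermediate = 0.50,
                                          frequent = 0.85),
                          ene_report_prob = c(infrequent = 0.40, intermediate = 0.70),
                          baseline_score_dist = c(0.55, 0.35, 0.10),
                          high_score_dist = c(0.01, 0.19, 0.79, 0.01),
                          prodrome_days = 7,
                          prodrome_shift = 0.95,
                          prodrome_power = 2,
                          class_shift_factor = c(infrequent = 0.7, intermediate = 0.85,
                                                 frequent = 1),
                          first_event_shift_factor = 0.6,
                          saba_lead_days = 3,
                          saba_base = 0.3, saba_amp = 3,
                          events_per_user_lambda = 2,
                          course_length_range = c(5, 7),
                          retrospective_prob = c(infrequent = 0.697, intermediate = 0.20,
                                                 frequent = 0.05),
                          post_gap_prob = 0.05,
                          emergency_prob = 0.02,
                          seed = 20240312) {
  cfg <- as.list(environment())
  if (abs(sum(engagement_mix) - 1) > 1e-8) stop("engagement_mix must sum to 1")
  for (nm in c("transition_prob", "report_prob", "retrospective_prob",
               "class_shift_factor"))
    if (!all(engagement_levels %in% names(cfg[[nm]])))
      stop(nm, " must be named over ", paste(engagement_levels, collapse = "/"))
  if (!all(c("infrequent", "intermediate") %in% names(ene_report_prob)))
    stop("ene_report_prob must be named over infrequent/intermediate")
  if (any(unlist(cfg[c("transition_prob", "report_prob", "retrospective_prob",
                       "post_gap_prob", "emergency_prob")]) < 0) ||
      any(unlist(cfg[c("transition_prob", "report_prob", "retrospective_prob",
                       "post_gap_prob", "emergency_prob")]) > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(baseline_score_dist) - 1) > 1e-8 || length(baseline_score_dist) != 3)
    stop("baseline_score_dist must be a length-3 distribution over scores 1..3")
  if (abs(sum(high_score_dist) - 1) > 1e-8 || length(high_score_dist) != 4)
    stop("high_score_dist must be a length-4 distribution over scores 1..4")
  stopifnot(prodrome_shift >= 0, prodrome_shift <= 1,
            course_length_range[1] >= 1, course_length_range[2] <= 10,
            prodrome_days >= 1, saba_lead_days >= 0)
  class(cfg) <- "cohort_config"
  cfg
}

# Severity weight in [0,1] for day offsets relative to one onset. The
# rescue pack is started in response to deterioration, so severity is
# already high (onset_value) on day 0: a convex (power) ramp through the
# prodrome reaches onset_value at d = 0, climbs linearly to 1 at
# +peak_day (scores peak after reliever use), then decays to 0 over
# `recovery` days. Unique argmax at peak_day.
severity_curve <- function(offsets, prodrome_days, peak_day, recovery = 10,
                           power = 2, onset_value = 0.9) {
  s <- numeric(length(offsets))
  up <- offsets >= -prodrome_days & offsets <= -1
  s[up] <- onset_value *
    ((offsets[up] + prodrome_days + 1) / (prodrome_days + 1))^power
  plat <- offsets >= 0 & offsets <= peak_day
  s[plat] <- if (peak_day > 0)
    onset_value + (1 - onset_value) * offsets[plat] / peak_day else 1
  down <- offsets > peak_day & offsets <= peak_day + recovery
  s[down] <- 1 - (offsets[down] - peak_day) / (recovery + 1)
  s
}

# SABA Poisson-rate weight: peaks at day 0 (onset), unique argmax.
saba_curve <- function(offsets, prodrome_days, recovery = 14) {
  s <- numeric(length(offsets))
  up <- offsets >= -prodrome_days & offsets <= 0
  s[up] <- (offsets[up] + prodrome_days + 1) / (prodrome_days + 1)
  down <- offsets > 0 & offsets <= recovery
  s[down] <- 1 - offsets[down] / (recovery + 1)
  s
}

sample_cat <- function(n, probs) {
  if (n == 0) return(integer())
  findInterval(runif(n), cumsum(probs)[-length(probs)]) + 1L
}

#' Generate a synthetic diary cohort
#'
#' Produces raw symptom, medication and profile tables that stand in for
#' the study's diaries, together with the ground-truth labels used by
#' the generator. Each exacerbation is marked by a rescue-pack course at
#' onset; mean reliever (SABA) usage peaks on the onset day while mean
#' symptom scores peak `saba_lead_days` later; per-class daily reporting
#' probability targets the class's archetype band; transition-flagged
#' events raise reporting to the next class's band over the 21 days
#' before onset.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with validated `symptoms`,
#'   `medications`, `profiles` tables and `truth` (per-user classes and
#'   per-event flags).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  origin <- as.Date("2020-01-01")

  empty_res <- function() {
    sy <- data.table::data.table(user_id = character(), date = as.Date(character()),
                                 score = integer())
    md <- data.table::data.table(user_id = character(), drug_class = character(),
                                 use_date = as.Date(character()),
                                 entry_date = as.Date(character()),
                                 course_length = integer(), daily_count = integer())
    pr <- data.table::data.table(user_id = character(), age = integer(),
                                 sex = character(), cat_score = integer(),
                                 mmrc = integer(),
                                 moderate_exacerbations_last_year = integer(),
                                 hospitalisations_last_year = integer())
    list(symptoms = sy, medications = md, profiles = pr,
         truth = list(users = data.table::data.table(), events = data.table::data.table()))
  }
  if (cfg$n_users == 0) {
    out <- empty_res()
    class(out) <- c("synthetic_cohort", class(out))
    return(out)
  }

  classes <- engagement_levels[sample_cat(cfg$n_users, cfg$engagement_mix[engagement_levels])]

  sy_l <- vector("list", cfg$n_users)
  md_l <- vector("list", cfg$n_users)
  ev_l <- vector("list", cfg$n_users)

  for (u in seq_len(cfg$n_users)) {
    uid <- sprintf("u%03d", u)
    cls <- classes[u]
    n_ev <- min(6L, 1L + rpois(1, cfg$events_per_user_lambda))
    gaps <- sample(160:240, n_ev, replace = TRUE)
    onset_days <- 100L + cumsum(gaps) - gaps[1]
    span <- max(onset_days) + 100L
    days <- seq_len(span)

    trans <- runif(n_ev) < cfg$transition_prob[[cls]]
    retro <- runif(n_ev) < cfg$retrospective_prob[[cls]]
    post_gap <- runif(n_ev) < cfg$post_gap_prob
    emergency <- runif(n_ev) < cfg$emergency_prob
    course_len <- sample(cfg$course_length_range[1]:cfg$course_length_range[2],
                         n_ev, replace = TRUE)

    # daily reporting probability
    p <- rep(cfg$report_prob[[cls]], span)
    sev <- numeric(span)
    sab <- numeric(span)
    for (e in seq_len(n_ev)) {
      o <- onset_days[e]
      if (trans[e] && cls != "frequent") {
        idx <- pmax(1L, o - 21L):(o - 1L)
        p[idx] <- cfg$ene_report_prob[[cls]]
      }
      if (post_gap[e]) {
        gl <- 14L + rpois(1, 4)
        idx <- (o + 1L):min(span, o + gl)
        p[idx] <- 0
      }
      shift <- cfg$prodrome_shift * cfg$class_shift_factor[[cls]] *
        (if (e == 1L) cfg$first_event_shift_factor else 1)
      off <- days - o
      sev <- pmax(sev, shift * severity_curve(off, cfg$prodrome_days, cfg$saba_lead_days,
                                              power = cfg$prodrome_power))
      sab <- pmax(sab, saba_curve(off, cfg$prodrome_days))
    }

    reported <- which(runif(span) < p)
    if (length(reported)) {
      base4 <- c(cfg$baseline_score_dist, 0)
      w <- sev[reported]
      u01 <- runif(length(reported))
      pm <- outer(1 - w, base4) + outer(w, cfg$high_score_dist)
      cm <- t(apply(pm, 1, cumsum))
      cm[, 4] <- 1
      score <- max.col(cm >= u01, ties.method = "first")
      sy <- data.table::data.table(user_id = uid, date = origin + reported - 1L,
                                   score = as.integer(score))
    } else sy <- NULL

    # emergency score-4 report on the day after onset (overrides/creates)
    for (e in which(emergency)) {
      d4 <- origin + onset_days[e]  # day offset +1
      if (is.null(sy)) sy <- data.table::data.table(user_id = uid, date = d4, score = 4L)
      else if (d4 %in% sy$date) sy[date == d4, score := 4L]
      else sy <- rbind(sy, data.table::data.table(user_id = uid, date = d4, score = 4L))
    }
    sy_l[[u]] <- sy

    # SABA records
    counts <- rpois(span, cfg$saba_base + cfg$saba_amp * sab)
    has <- which(counts > 0)
    saba_dt <- if (length(has))
      data.table::data.table(user_id = uid, drug_class = "saba",
                             use_date = origin + has - 1L,
                             entry_date = origin + has - 1L,
                             course_length = NA_integer_,
                             daily_count = as.integer(counts[has])) else NULL

    entry_lag <- ifelse(retro, 11L + rpois(n_ev, 7), sample(0:3, n_ev, replace = TRUE))
    rp_dt <- data.table::data.table(
      user_id = uid, drug_class = "rescue_pack",
      use_date = origin + onset_days - 1L,
      entry_date = origin + onset_days - 1L + entry_lag,
      course_length = as.integer(course_len), daily_count = NA_integer_)
    md_l[[u]] <- rbind(saba_dt, rp_dt)

    ev_l[[u]] <- data.table::data.table(
      user_id = uid, class = cls, onset_date = origin + onset_days - 1L,
      course_length = as.integer(course_len), transition = trans,
      retrospective = retro, post_gap = post_gap, emergency = emergency,
      first_for_user = seq_len(n_ev) == 1L)
  }

  # user profiles; exacerbation history loosely tied to engagement so the
  # GOLD cross-tab shows more C/D among frequent users
  hist_lambda <- c(infrequent = 0.8, intermediate = 1.2, frequent = 1.8)
  profiles <- data.table::data.table(
    user_id = sprintf("u%03d", seq_len(cfg$n_users)),
    age = as.integer(pmin(95, pmax(40, round(rnorm(cfg$n_users, 68.8, 8.3))))),
    sex = ifelse(runif(cfg$n_users) < 0.607, "male", "female"),
    cat_score = as.integer(pmin(40, pmax(0, round(rnorm(cfg$n_users, 18, 8))))),
    mmrc = sample(0:4, cfg$n_users, replace = TRUE,
                  prob = c(0.1, 0.2, 0.3, 0.25, 0.15)),
    moderate_exacerbations_last_year =
      as.integer(rpois(cfg$n_users, hist_lambda[classes])),
    hospitalisations_last_year = as.integer(runif(cfg$n_users) < 0.15))

  out <- list(
    symptoms = validate_symptoms(data.table::rbindlist(sy_l[!vapply(sy_l, is.null, TRUE)])),
    medications = validate_medications(data.table::rbindlist(md_l)),
    profiles = validate_profiles(profiles),
    truth = list(
      users = data.table::data.table(user_id = sprintf("u%03d", seq_len(cfg$n_users)),
                                     class = classes),
      events = data.table::rbindlist(ev_l)))
  class(out) <- c("synthetic_cohort", class(out))
  out
}

#' Event-aligned series container
#'
#' Canonical container for exacerbation-aligned symptom series: one
#' record per (series, day offset in -70..+70) with a score, plus a
#' per-series info table (group label, course length).
#'
#' @param records `data.table` with `series_id`, `day_offset`, `score`.
#' @param info `data.table` with `series_id`, `group`, `course_length`.
#' @return list of class `exa_series`.
#' @export
exa_series <- function(records, info) {
  records <- data.table::as.data.table(records)
  info <- data.table::as.data.table(info)
  stopifnot(all(c("series_id", "day_offset", "score") %in% names(records)),
            all(c("series_id", "course_length") %in% names(info)))
  if (!"group" %in% names(info)) info[, group := NA_character_]
  if (nrow(records)) {
    if (any(records$day_offset < -70 | records$day_offset > 70))
      stop("day offsets must lie in [-70, 70]")
    if (anyDuplicated(records, by = c("series_id", "day_offset")))
      stop("at most one record per (series, offset)")
    if (!all(records$series_id %in% info$series_id))
      stop("records reference unknown series")
  }
  structure(list(records = records[], info = info[]), class = "exa_series")
}

#' @export
print.exa_series <- function(x, ...) {
  cat("exa_series:", nrow(x$info), "series,", nrow(x$records), "records\n")
  invisible(x)
}

#' Extract event-aligned series from diaries
#'
#' Cuts each profiled exacerbation's +/-70-day symptom window out of the
#' diary and re-indexes it by day offset (onset = 0), yielding the
#' series collection on which group profiles are fitted.
#'
#' @param profiles `engagement_profiles` table (carries event ids,
#'   onsets, course lengths and group labels).
#' @param symptoms validated symptom table.
#' @return an [exa_series()].
#' @export
event_series <- function(profiles, symptoms) {
  p <- data.table::as.data.table(profiles)
  sy <- data.table::as.data.table(symptoms)
  recs <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    s <- sy[user_id == p$user_id[i] &
              date >= p$onset_date[i] - 70 & date <= p$onset_date[i] + 70]
    if (nrow(s))
      recs[[i]] <- data.table::data.table(
        series_id = p$event_id[i],
        day_offset = as.integer(s$date - p$onset_date[i]),
        score = s$score)
  }
  exa_series(
    records = data.table::rbindlist(recs[!vapply(recs, is.null, TRUE)]),
    info = p[, .(series_id = event_id, group = as.character(group), course_length)])
}

#' Fit a day-offset-conditioned empirical group profile
#'
#' For one engagement group, estimates for every day offset d in
#' -70..+70 the probability that a series carries a report at d (share
#' of source series reporting) and the categorical score distribution at
#' d. Score frequencies are pooled over a +/- `score_bin` day bin so
#' sparse offsets borrow strength from their neighbours; a bin with no
#' observations falls back to the group's pooled distribution. The
#' course-length distribution of the source series is retained so
#' simulated series can carry one.
#'
#' @param series an [exa_series()] (typically already filtered to one
#'   group).
#' @param group optional group label stored on the profile.
#' @param score_bin half-width (days) of the score pooling bin.
#' @return list of class `group_profile` with `report_prob` (141
#'   values), `score_dist` (141 x 4 matrix, rows sum to 1),
#'   `course_dist`, `n_source_series`.
#' @export
fit_group_profile <- function(series, group = NULL, score_bin = 3) {
  stopifnot(inherits(series, "exa_series"))
  n <- nrow(series$info)
  if (n < 1) stop("need at least one source series")
  offsets <- -70:70
  rec <- series$records
  col <- function(d) d + 71L

  rep_counts <- tabulate(col(rec$day_offset), nbins = 141L)
  report_prob <- rep_counts / n

  counts <- matrix(0, nrow = 141, ncol = 4)
  if (nrow(rec)) {
    tb <- rec[, .N, by = .(day_offset, score)]
    counts[cbind(col(tb$day_offset), tb$score)] <- tb$N
  }
  cs <- apply(counts, 2, cumsum)
  lo <- pmax(col(offsets) - score_bin, 1L)
  hi <- pmin(col(offsets) + score_bin, 141L)
  binned <- cs[hi, , drop = FALSE] -
    rbind(0, cs)[lo, , drop = FALSE]  # rbind(0, cs)[k,] == cs[k-1,] with 0 row
  tot <- rowSums(binned)
  pooled <- colSums(counts)
  pooled <- if (sum(pooled) > 0) pooled / sum(pooled) else rep(0.25, 4)
  score_dist <- binned / ifelse(tot > 0, tot, 1)
  if (any(tot == 0))
    score_dist[tot == 0, ] <- matrix(pooled, nrow = sum(tot == 0), ncol = 4,
                                     byrow = TRUE)

  cl <- table(factor(series$info$course_length, levels = 1:10))
  course_dist <- as.numeric(cl) / sum(cl)

  structure(list(group = group %||% unique(stats::na.omit(series$info$group))[1],
                 offsets = offsets, report_prob = report_prob,
                 score_dist = score_dist, course_dist = course_dist,
                 n_source_series = n, score_bin = score_bin),
            class = "group_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.group_profile <- function(x, ...) {
  cat("group_profile:", x$group %||% "<unlabelled>", "- fitted on",
      x$n_source_series, "series\n")
  cat(sprintf("  mean report prob (pre/post): %.2f / %.2f\n",
              mean(x$report_prob[1:70]), mean(x$report_prob[72:141])))
  invisible(x)
}

#' Simulate exacerbation-aligned series from a group profile
#'
#' Draws `n` complete series from 70 days prior to 70 days post
#' exacerbation: at each day offset a report occurs with the profile's
#' reporting probability and its score is drawn from the profile's
#' offset-conditioned score distribution. Course lengths are sampled
#' from the profile's empirical course-length distribution. Each series
#' uses its own RNG substream derived from `seed`, so output is fully
#' determined by (`n`, `seed`) independent of iteration order.
#'
#' @param profile a [fit_group_profile()] result.
#' @param n number of series to simulate.
#' @param seed integer seed.
#' @return an [exa_series()].
#' @export
simulate_exacerbation_series <- function(profile, n, seed = 1L) {
  stopifnot(inherits(profile, "group_profile"), n >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  cum <- t(apply(profile$score_dist, 1, cumsum))
  cum[, 4] <- 1
  grp <- profile$group %||% "group"
  recs <- vector("list", n)
  clens <- integer(n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    rep_on <- which(runif(141) < profile$report_prob)
    clens[i] <- if (sum(profile$course_dist) > 0)
      sample.int(10L, 1, prob = profile$course_dist) else 5L
    if (length(rep_on)) {
      u <- runif(length(rep_on))
      score <- max.col(cum[rep_on, , drop = FALSE] >= u, ties.method = "first")
      recs[[i]] <- data.table::data.table(
        series_id = sprintf("%s_s%04d", grp, i),
        day_offset = rep_on - 71L, score = as.integer(score))
    }
  }
  exa_series(
    records = data.table::rbindlist(recs[!vapply(recs, is.null, TRUE)]),
    info = data.table::data.table(series_id = sprintf("%s_s%04d", grp, seq_len(n)),
                                  group = grp, course_length = clens))
}
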