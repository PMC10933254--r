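#' Event-aligned symptom, SABA and usage profiles
#'
#' For the first-exacerbation and subsequent-exacerbation cohorts,
#' computes per day offset (-70..+70): mean registered symptom score
#' (over events with a report that day), mean daily reliever (SABA)
#' dose count (days without a SABA record count as zero), and the
#' percentage of events with a registered score.
#'
#' @param events `exacerbation_events` (with `first_for_user`).
#' @param symptoms validated symptom table.
#' @param medications validated medication table (SABA rows used).
#' @return `data.table` with `cohort` (`first`/`subsequent`),
#'   `day_offset`, `mean_score`, `mean_saba`, `pct_reporting`.
#' @export
event_aligned_profiles <- function(events, symptoms, medications = NULL) {
  ev <- data.table::as.data.table(events)
  sy <- data.table::as.data.table(symptoms)
  sb <- if (is.null(medications)) NULL
        else data.table::as.data.table(medications)[drug_class == "saba"]
  out <- list()
  for (cohort in c("first", "subsequent")) {
    sub <- if (cohort == "first") ev[first_for_user == TRUE] else ev[first_for_user == FALSE]
    if (!nrow(sub)) stop("empty cohort: ", cohort)
    n_ev <- nrow(sub)
    score_sum <- score_n <- saba_sum <- numeric(141)
    for (i in seq_len(n_ev)) {
      onset <- sub$onset_date[i]
      s <- sy[user_id == sub$user_id[i] & date >= onset - 70 & date <= onset + 70]
      if (nrow(s)) {
        k <- as.integer(s$date - onset) + 71L
        score_sum[k] <- score_sum[k] + s$score
        score_n[k] <- score_n[k] + 1
      }
      if (!is.null(sb)) {
        m <- sb[user_id == sub$user_id[i] & use_date >= onset - 70 & use_date <= onset + 70]
        if (nrow(m)) {
          k <- as.integer(m$use_date - onset) + 71L
          saba_sum[k] <- saba_sum[k] + ifelse(is.na(m$daily_count), 1, m$daily_count)
        }
      }
    }
    out[[cohort]] <- data.table::data.table(
      cohort = cohort, day_offset = -70:70,
      mean_score = ifelse(score_n > 0, score_sum / score_n, NA_real_),
      mean_saba = saba_sum / n_ev,
      pct_reporting = 100 * score_n / n_ev)
  }
  data.table::rbindlist(out)
}

#' Chi-square comparison of pooled score distributions
#'
#' Pools all registered daily scores in the +/-70-day event windows of
#' two cohorts into a score-category x cohort contingency table and
#' applies Pearson's chi-square (no continuity correction). Score
#' categories with zero total count are pooled into the nearest lower
#' (else upper) category so no expected count is zero.
#'
#' @param scores_first,scores_subsequent integer score vectors (1..4)
#'   pooled over the two cohorts' event windows.
#' @return list with `statistic`, `df`, `p_value` and the `table` used.
#' @export
chi_square_scores <- function(scores_first, scores_subsequent) {
  if (!length(scores_first) || !length(scores_subsequent))
    stop("both cohorts need scores")
  tab <- rbind(first = table(factor(scores_first, levels = 1:4)),
               subsequent = table(factor(scores_subsequent, levels = 1:4)))
  tot <- colSums(tab)
  while (any(tot == 0) && ncol(tab) > 1) {
    z <- which(tot == 0)[1]
    nb <- if (z > 1) z - 1 else z + 1
    tab[, nb] <- tab[, nb] + tab[, z]
    tab <- tab[, -z, drop = FALSE]
    tot <- colSums(tab)
  }
  if (ncol(tab) < 2) stop("fewer than two score categories with counts; cannot test")
  ct <- stats::chisq.test(t(tab), correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' Lag between the SABA-usage peak and the symptom-score peak
#'
#' `argmax(score_curve) - argmax(saba_curve)` in days; on ties the
#' earliest offset wins. Positive values mean reliever use peaks before
#' self-reported symptom scores do.
#'
#' @param saba_curve,score_curve numeric curves over the same offsets.
#' @param offsets integer day offsets the curves are indexed by
#'   (default -70..+70).
#' @return integer lag in days.
#' @export
peak_lag <- function(saba_curve, score_curve, offsets = -70:70) {
  if (!length(saba_curve) || !length(score_curve)) stop("empty curve")
  stopifnot(length(saba_curve) == length(offsets),
            length(score_curve) == length(offsets))
  o <- order(offsets)
  saba_curve <- saba_curve[o]; score_curve <- score_curve[o]
  offsets <- offsets[o]
  as.integer(offsets[which.max(score_curve)] - offsets[which.max(saba_curve)])
}

#' GOLD 2022 combined-assessment group
#'
#' Crosses exacerbation-history risk (high: >= 2 moderate exacerbations
#' or >= 1 hospitalisation in the last year) with symptom burden (high:
#' CAT >= 10 or mMRC >= 2): A = low risk/low symptoms, B = low
#' risk/high symptoms, C = high risk/low symptoms, D = high/high.
#' Users with all symptom measures missing are `NA` (undetermined).
#'
#' @param profiles validated profile table.
#' @param cat_cut,mmrc_cut,exac_cut,hosp_cut thresholds of the combined
#'   assessment.
#' @return factor with levels A, B, C, D (NA = undetermined).
#' @export
gold_group <- function(profiles, cat_cut = 10, mmrc_cut = 2, exac_cut = 2,
                       hosp_cut = 1) {
  p <- data.table::as.data.table(profiles)
  ex <- ifelse(is.na(p$moderate_exacerbations_last_year), 0L,
               p$moderate_exacerbations_last_year)
  ho <- ifelse(is.na(p$hospitalisations_last_year), 0L,
               p$hospitalisations_last_year)
  high_risk <- ex >= exac_cut | ho >= hosp_cut
  cat_hi <- !is.na(p$cat_score) & p$cat_score >= cat_cut
  mmrc_hi <- !is.na(p$mmrc) & p$mmrc >= mmrc_cut
  no_symptom_info <- is.na(p$cat_score) & is.na(p$mmrc)
  high_sympt <- cat_hi | mmrc_hi
  g <- ifelse(no_symptom_info, NA_character_,
              ifelse(high_risk,
                     ifelse(high_sympt, "D", "C"),
                     ifelse(high_sympt, "B", "A")))
  factor(g, levels = c("A", "B", "C", "D"))
}

#' Engagement-by-GOLD percentage cross-tabulation
#'
#' @param engagement_class per-user engagement class (factor or
#'   character over infrequent/intermediate/frequent).
#' @param gold per-user GOLD group from [gold_group()].
#' @return `data.table` with one row per engagement class, percentage
#'   columns A-D (rows sum to 100 up to rounding) and an `n` column.
#' @export
engagement_by_gold <- function(engagement_class, gold) {
  stopifnot(length(engagement_class) == length(gold))
  keep <- !is.na(gold) & !is.na(engagement_class)
  if (!any(keep)) stop("no labelled users")
  cls <- factor(as.character(engagement_class)[keep], levels = engagement_levels)
  gd <- factor(as.character(gold)[keep], levels = c("A", "B", "C", "D"))
  tab <- table(cls, gd)
  pct <- 100 * prop.table(tab, margin = 1)
  out <- data.table::as.data.table(as.data.frame.matrix(pct), keep.rownames = "engagement")
  out[, n := as.integer(rowSums(tab))]
  out[]
}
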