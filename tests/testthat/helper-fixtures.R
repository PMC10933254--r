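# Fixture builders and independent oracles shared across test files.

make_symptoms <- function(user = "u1", dates, scores) {
  validate_symptoms(data.frame(user_id = user, date = as.Date(dates),
                               score = scores))
}

make_rescue <- function(user = "u1", use, len, entry = use) {
  data.frame(user_id = user, drug_class = "rescue_pack",
             use_date = as.Date(use), entry_date = as.Date(entry),
             course_length = as.integer(len), daily_count = NA_integer_)
}

# one event-aligned series as an exa_series
make_series <- function(offsets, scores, id = "s1", course_length = 5L,
                        group = "g") {
  exa_series(
    records = data.table::data.table(series_id = id, day_offset = as.integer(offsets),
                                     score = as.integer(scores)),
    info = data.table::data.table(series_id = id, group = group,
                                  course_length = as.integer(course_length)))
}

bind_series <- function(...) {
  xs <- list(...)
  exa_series(records = data.table::rbindlist(lapply(xs, `[[`, "records")),
             info = data.table::rbindlist(lapply(xs, `[[`, "info")))
}

# degenerate profile: report with probability 1, score always `score`
constant_profile <- function(score = 2L, course_length = 5L) {
  sd <- matrix(0, 141, 4); sd[, score] <- 1
  cd <- numeric(10); cd[course_length] <- 1
  structure(list(group = "const", offsets = -70:70,
                 report_prob = rep(1, 141), score_dist = sd,
                 course_dist = cd, n_source_series = 1L, score_bin = 3L),
            class = "group_profile")
}

# --- independent oracles ---------------------------------------------

# AUROC by explicit enumeration of positive-negative pairs (ties = 1/2)
oracle_auroc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# average precision by looping over descending unique thresholds and
# recounting precision/recall from scratch at each
oracle_average_precision <- function(labels, scores) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Pearson chi-square straight from the textbook formula sum (O-E)^2 / E
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# brute-force scan counting qualifying (merged) rescue-pack courses
oracle_event_count <- function(med) {
  med <- med[med$drug_class == "rescue_pack", ]
  if (!nrow(med)) return(0L)
  n <- 0L
  for (u in unique(med$user_id)) {
    m <- med[med$user_id == u, ]
    days <- sort(unique(unlist(mapply(
      function(s, l) as.integer(s) + 0:(l - 1), m$use_date, m$course_length,
      SIMPLIFY = FALSE))))
    runs <- split(days, cumsum(c(1, diff(days) > 1)))
    n <- n + sum(vapply(runs, length, 1L) <= 10)
  }
  n
}
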