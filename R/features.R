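feature_names <- function(windows = c(4L, 8L, 15L)) {
  as.vector(vapply(windows, function(w)
    paste0(c("mean", "sd", "count", "min", "max"), "_w", w), character(5)))
}

#' Trailing-window summary of registered scores
#'
#' Statistics over the registered scores in the trailing window
#' `[day_offset - w + 1, day_offset]` (inclusive of the current day):
#' mean, sample standard deviation, count, minimum and maximum. Only
#' registered scores contribute; `count` is always defined, `sd` is
#' `NA` when fewer than two scores are registered, all others `NA` when
#' none are.
#'
#' @param records `data.table`/data.frame with `day_offset` and `score`
#'   for one series.
#' @param day_offset day the prediction is made for.
#' @param w window length in days; must be one of `allowed`.
#' @param allowed admissible window lengths (default the Table of model
#'   inputs: 4, 8, 15).
#' @return named numeric vector `mean, sd, count, min, max`.
#' @export
window_features <- function(records, day_offset, w, allowed = c(4L, 8L, 15L)) {
  if (!w %in% allowed) stop("invalid window length: ", w)
  d <- day_offset
  r <- data.table::as.data.table(records)
  s <- r$score[r$day_offset >= d - w + 1L & r$day_offset <= d]
  n <- length(s)
  c(mean = if (n) mean(s) else NA_real_,
    sd = if (n >= 2) stats::sd(s) else NA_real_,
    count = as.numeric(n),
    min = if (n) as.numeric(min(s)) else NA_real_,
    max = if (n) as.numeric(max(s)) else NA_real_)
}

#' Build prediction instances from event-aligned series
#'
#' One instance per series per day offset in `span` (-55..+70 by
#' default, the -55 start guaranteeing the 15-day window lies inside
#' the -70..+70 series), excluding offsets during the exacerbation
#' (0..course_length-1). The label is 1 iff onset (day 0) lies within
#' the next `horizon` days, i.e. offsets -3..-1 under the 3-day
#' horizon. Features are the trailing-window statistics of
#' [window_features()] for each window length; missing values stay
#' missing (`NA`).
#'
#' Instances are built for every eligible day, including days with no
#' registered score (the model can be scored daily from history);
#' set `reporting_days_only = TRUE` to restrict to days with a report.
#'
#' @param series an [exa_series()].
#' @param windows trailing window lengths.
#' @param horizon prediction horizon in days.
#' @param span inclusive day-offset range instances are built for.
#' @param reporting_days_only keep only instances on days with a
#'   registered score.
#' @return `data.table` of class `prediction_instances`: `series_id`,
#'   `group`, `day_offset`, one column per feature, `label`.
#' @export
build_instances <- function(series, windows = c(4L, 8L, 15L), horizon = 3L,
                            span = c(-55L, 70L), reporting_days_only = FALSE) {
  stopifnot(inherits(series, "exa_series"))
  if (span[1] - max(windows) + 1L < -70L || span[2] > 70L)
    stop("span plus longest window exceeds the -70..+70 series extent")
  info <- series$info
  if (anyNA(info$course_length)) stop("course_length required for every series")
  n <- nrow(info)
  ids <- info$series_id
  rec <- series$records

  # score matrix: series x day offsets -70..70
  M <- matrix(NA_real_, nrow = n, ncol = 141L, dimnames = list(ids, NULL))
  if (nrow(rec))
    M[cbind(match(rec$series_id, ids), rec$day_offset + 71L)] <- rec$score

  ind <- !is.na(M)
  V <- ifelse(ind, M, 0)
  zero <- matrix(0, nrow = n, ncol = 1)
  Cn <- cbind(zero, t(apply(ind, 1, cumsum)))
  Cs <- cbind(zero, t(apply(V, 1, cumsum)))
  Cq <- cbind(zero, t(apply(V^2, 1, cumsum)))

  cols <- (span[1]:span[2]) + 71L  # matrix columns for output offsets
  feats <- list()
  for (w in windows) {
    cnt <- Cn[, cols + 1L] - Cn[, cols + 1L - w]
    sm <- Cs[, cols + 1L] - Cs[, cols + 1L - w]
    sq <- Cq[, cols + 1L] - Cq[, cols + 1L - w]
    mu <- ifelse(cnt > 0, sm / cnt, NA_real_)
    var <- ifelse(cnt >= 2, pmax(sq - sm^2 / cnt, 0) / (cnt - 1), NA_real_)
    mn <- mx <- NULL
    for (k in 0:(w - 1L)) {
      sub <- M[, cols - k, drop = FALSE]
      mn <- if (is.null(mn)) sub else pmin(mn, sub, na.rm = TRUE)
      mx <- if (is.null(mx)) sub else pmax(mx, sub, na.rm = TRUE)
    }
    feats[[paste0("mean_w", w)]] <- mu
    feats[[paste0("sd_w", w)]] <- sqrt(var)
    feats[[paste0("count_w", w)]] <- cnt
    feats[[paste0("min_w", w)]] <- mn
    feats[[paste0("max_w", w)]] <- mx
  }

  offs <- span[1]:span[2]
  out <- data.table::data.table(
    series_id = rep(ids, times = length(offs)),
    group = rep(as.character(info$group), times = length(offs)),
    day_offset = rep(offs, each = n))
  for (nm in names(feats)) data.table::set(out, j = nm, value = as.vector(feats[[nm]]))
  data.table::set(out, j = "label",
                  value = as.integer(out$day_offset >= -horizon & out$day_offset <= -1L))

  # drop days during the exacerbation (0 .. course_length - 1)
  out <- merge(out, info[, .(series_id, course_length)], by = "series_id")
  out <- out[!(day_offset >= 0L & day_offset <= course_length - 1L)]
  out[, course_length := NULL]
  if (reporting_days_only) {
    reported <- data.table::data.table(series_id = rec$series_id,
                                       day_offset = rec$day_offset, rep = TRUE)
    out <- merge(out, reported, by = c("series_id", "day_offset"))[, rep := NULL]
  }
  data.table::setorder(out, series_id, day_offset)
  data.table::setattr(out, "class", c("prediction_instances", class(out)))
  out[]
}
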