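#' Read and validate diary tables
#'
#' Reads the three tidy per-user diary CSVs (daily symptom scores,
#' medication records, user profiles), enforces the domain invariants and
#' returns typed `data.table`s. Dates must be ISO-8601 (`YYYY-MM-DD`).
#'
#' The symptom diary holds one row per user-day with a self-assessed
#' score on the 4-point scale (1 = usual self .. 4 = needed emergency
#' care). Medication rows are one per reported use: `rescue_pack` rows
#' carry a `course_length` in days, `saba` rows a `daily_count` of
#' reliever doses, `routine` rows neither.
#'
#' @param symptoms path to `symptoms.csv` (`user_id,date,score`).
#' @param medications path to `medications.csv`
#'   (`user_id,drug_class,use_date,entry_date,course_length,daily_count`).
#' @param profiles path to `profiles.csv` (`user_id,age,sex,cat_score,
#'   mmrc,moderate_exacerbations_last_year,hospitalisations_last_year`).
#' @return list with validated `data.table`s `symptoms`, `medications`,
#'   `profiles` (elements `NULL` when the corresponding path is `NULL`).
#' @export
read_diaries <- function(symptoms = NULL, medications = NULL, profiles = NULL) {
  out <- list(symptoms = NULL, medications = NULL, profiles = NULL)
  if (!is.null(symptoms)) {
    stopifnot(file.exists(symptoms))
    out$symptoms <- validate_symptoms(data.table::fread(symptoms, colClasses = list(character = "user_id")))
  }
  if (!is.null(medications)) {
    stopifnot(file.exists(medications))
    out$medications <- validate_medications(data.table::fread(medications, colClasses = list(character = "user_id")))
  }
  if (!is.null(profiles)) {
    stopifnot(file.exists(profiles))
    out$profiles <- validate_profiles(data.table::fread(profiles, colClasses = list(character = "user_id")))
  }
  out
}

parse_iso_date <- function(x, what) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) || anyNA(d))
    stop(sprintf("malformed %s date at row %d: '%s'", what,
                 if (length(bad)) bad[1] else which(is.na(d))[1],
                 as.character(x)[if (length(bad)) bad[1] else which(is.na(d))[1]]))
  d
}

#' Validate a symptom-score table
#'
#' Enforces: required columns, ISO dates, scores in `{1,2,3,4}` and at
#' most one record per (user, day).
#'
#' @param dt data.frame/data.table with `user_id`, `date`, `score`.
#' @return keyed `data.table` of class `symptom_table`.
#' @export
validate_symptoms <- function(dt) {
  dt <- data.table::as.data.table(dt)
  need <- c("user_id", "date", "score")
  if (!all(need %in% names(dt)))
    stop("symptoms table must have columns: ", paste(need, collapse = ", "))
  dt[, date := parse_iso_date(date, "symptom")]
  bad <- dt[!score %in% 1:4]
  if (nrow(bad))
    stop(sprintf("symptom score out of range {1..4} for user %s on %s (score=%s)",
                 bad$user_id[1], format(bad$date[1]), bad$score[1]))
  dup <- dt[duplicated(dt, by = c("user_id", "date"))]
  if (nrow(dup))
    stop(sprintf("duplicate symptom record for user %s on %s",
                 dup$user_id[1], format(dup$date[1])))
  dt[, score := as.integer(score)]
  data.table::setkey(dt, user_id, date)
  data.table::setattr(dt, "class", c("symptom_table", class(dt)))
  dt[]
}

#' Validate a medication table
#'
#' @param dt data.frame/data.table with `user_id`, `drug_class`,
#'   `use_date`, `entry_date` and, where applicable, `course_length`
#'   (rescue packs, 1+ days) and `daily_count` (SABA doses, 0+).
#' @return keyed `data.table` of class `medication_table`.
#' @export
validate_medications <- function(dt) {
  dt <- data.table::as.data.table(dt)
  need <- c("user_id", "drug_class", "use_date")
  if (!all(need %in% names(dt)))
    stop("medications table must have columns: ", paste(need, collapse = ", "))
  if (!"entry_date" %in% names(dt)) dt[, entry_date := use_date]
  if (!"course_length" %in% names(dt)) dt[, course_length := NA_integer_]
  if (!"daily_count" %in% names(dt)) dt[, daily_count := NA_integer_]
  ok_class <- c("saba", "rescue_pack", "routine")
  if (!all(dt$drug_class %in% ok_class))
    stop("drug_class must be one of: ", paste(ok_class, collapse = ", "))
  dt[, use_date := parse_iso_date(use_date, "medication use")]
  has_entry <- !is.na(dt$entry_date)
  if (any(has_entry)) {
    parsed <- parse_iso_date(dt$entry_date[has_entry], "medication entry")
    dt[, entry_date := as.Date(NA)]
    dt[has_entry, entry_date := parsed]
  } else dt[, entry_date := as.Date(NA)]
  dt[, course_length := as.integer(course_length)]
  dt[, daily_count := as.integer(daily_count)]
  rp <- dt[drug_class == "rescue_pack"]
  if (nrow(rp) && (anyNA(rp$course_length) || any(rp$course_length < 1)))
    stop("rescue_pack rows require course_length >= 1")
  if (any(!is.na(dt$course_length) & dt$drug_class != "rescue_pack"))
    stop("course_length only valid for rescue_pack rows")
  sb <- dt[drug_class == "saba"]
  if (nrow(sb) && any(!is.na(sb$daily_count) & sb$daily_count < 0))
    stop("saba daily_count must be >= 0")
  data.table::setkey(dt, user_id, use_date)
  data.table::setattr(dt, "class", c("medication_table", class(dt)))
  dt[]
}

#' Validate a user-profile table
#'
#' @param dt data.frame/data.table with `user_id`, `age`, `sex`,
#'   `cat_score` (0-40), `mmrc` (0-4),
#'   `moderate_exacerbations_last_year`, `hospitalisations_last_year`.
#' @return `data.table` of class `profile_table`.
#' @export
validate_profiles <- function(dt) {
  dt <- data.table::as.data.table(dt)
  need <- c("user_id")
  if (!all(need %in% names(dt))) stop("profiles table must have a user_id column")
  for (col in c("age", "cat_score", "mmrc", "moderate_exacerbations_last_year",
                "hospitalisations_last_year"))
    if (!col %in% names(dt)) dt[, (col) := NA_integer_]
  if (!"sex" %in% names(dt)) dt[, sex := NA_character_]
  if (any(!is.na(dt$cat_score) & (dt$cat_score < 0 | dt$cat_score > 40)))
    stop("cat_score must lie in [0, 40]")
  if (any(!is.na(dt$mmrc) & (dt$mmrc < 0 | dt$mmrc > 4)))
    stop("mmrc must lie in [0, 4]")
  if (any(!is.na(dt$moderate_exacerbations_last_year) & dt$moderate_exacerbations_last_year < 0) ||
      any(!is.na(dt$hospitalisations_last_year) & dt$hospitalisations_last_year < 0))
    stop("exacerbation history counts must be >= 0")
  if (anyDuplicated(dt$user_id)) stop("duplicate user_id in profiles")
  data.table::setattr(dt, "class", c("profile_table", class(dt)))
  dt[]
}

#' Identify exacerbation events from rescue-pack courses
#'
#' An exacerbation is a rescue-pack course (home-kept short course of
#' oral steroids plus antibiotics) with a well-defined start date. The
#' onset (day 0) is the first day of the course. Courses longer than 10
#' days are excluded as weaning/maintenance prescriptions. Courses of one
#' user whose day ranges overlap or abut are merged into a single event
#' with onset at the earliest start; if the merged span exceeds 10 days
#' the whole merged course is excluded as a long course.
#'
#' @param medications a validated `medication_table` (see
#'   [validate_medications()]).
#' @return `data.table` of class `exacerbation_events` with columns
#'   `user_id`, `onset_date`, `course_length`, `first_for_user`,
#'   `retrospective` (logical, `NA` when no entry date was recorded),
#'   sorted by user and onset.
#' @export
identify_exacerbations <- function(medications) {
  rp <- data.table::as.data.table(medications)[drug_class == "rescue_pack"]
  empty <- data.table::data.table(
    user_id = character(), onset_date = as.Date(character()),
    course_length = integer(), first_for_user = logical(),
    retrospective = logical())
  if (!nrow(rp)) {
    data.table::setattr(empty, "class", c("exacerbation_events", class(empty)))
    return(empty[])
  }
  rp <- rp[order(user_id, use_date)]
  rp[, end_date := use_date + course_length - 1L]
  # merge overlapping/abutting courses per user
  rp[, grp := {
    g <- integer(.N); cur <- 1L; g[1] <- 1L
    if (.N > 1) {
      run_end <- end_date[1]
      for (i in 2:.N) {
        if (use_date[i] > run_end + 1L) cur <- cur + 1L
        run_end <- max(run_end, end_date[i])
        g[i] <- cur
      }
    }
    g
  }, by = user_id]
  ev <- rp[, .(
    onset_date = min(use_date),
    course_length = as.integer(max(end_date) - min(use_date) + 1L),
    entry_date = if (all(is.na(entry_date))) as.Date(NA) else min(entry_date, na.rm = TRUE)
  ), by = .(user_id, grp)]
  ev <- ev[course_length >= 1L & course_length <= 10L]
  ev <- ev[order(user_id, onset_date)]
  ev[, first_for_user := seq_len(.N) == 1L, by = user_id]
  ev[, retrospective := flag_retrospective(onset_date, entry_date)]
  ev[, c("grp", "entry_date") := NULL]
  data.table::setattr(ev, "class", c("exacerbation_events", class(ev)))
  ev[]
}

#' Flag retrospectively entered exacerbations
#'
#' An event is retrospective when the rescue-pack medication was entered
#' in-app more than 10 days after the onset. Missing entry dates yield
#' `NA` (undetermined), not `FALSE`.
#'
#' @param onset_date onset (day 0) of the event, `Date`.
#' @param entry_date date the record was created in-app, `Date` (may be
#'   `NA`).
#' @return logical vector; `NA` where `entry_date` is missing.
#' @export
flag_retrospective <- function(onset_date, entry_date) {
  ifelse(is.na(entry_date), NA,
         as.numeric(as.Date(entry_date) - as.Date(onset_date)) > 10)
}
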