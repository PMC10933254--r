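#' Study configuration
#'
#' Single configuration object for the end-to-end study. Defaults hold
#' the study's printed constants: 70-day engagement windows, 21-day
#' transition window, 0.33/0.66 class boundaries, 10-day course limit,
#' 3-day prediction horizon, instances from day -55 to +70, 1000
#' simulated series per engagement group, 75-25 series-level split and
#' 5-fold grouped cross-validation.
#'
#' @param cohort list of overrides passed to [cohort_config()] (or a
#'   ready `cohort_config`).
#' @param paths optional list with `symptoms`, `medications`,
#'   `profiles` CSV paths; when given, diaries are read instead of
#'   generated.
#' @param lower,upper engagement class boundaries.
#' @param min_reports,signal_rise,gap_days quality/disengagement
#'   thresholds (see [classify_quality()],
#'   [flag_post_disengagement()]).
#' @param n_per_group simulated series per engagement group.
#' @param score_bin half-width of the score-distribution pooling bin.
#' @param min_source_series smallest group still simulated.
#' @param windows,horizon,span feature construction (see
#'   [build_instances()]).
#' @param test_fraction,k train/test split and fold count.
#' @param budget hyperparameter-search budget (configurations).
#' @param boot_reps bootstrap resamples for the evaluation CIs.
#' @param with_baseline also fit/evaluate the logistic baseline.
#' @param write_instances write the (large) instances.csv.
#' @param seed root seed; stage substreams are derived from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(cohort = list(), paths = NULL,
                         lower = 0.33, upper = 0.66,
                         min_reports = 5, signal_rise = 0.5, gap_days = 14,
                         n_per_group = 1000L, score_bin = 3L,
                         min_source_series = 5L,
                         windows = c(4L, 8L, 15L), horizon = 3L,
                         span = c(-55L, 70L),
                         test_fraction = 0.25, k = 5L,
                         budget = 30L, boot_reps = 1000L,
                         with_baseline = TRUE, write_instances = FALSE,
                         seed = 20240312L) {
  cfg <- as.list(environment())
  stopifnot(lower > 0, upper < 1, lower < upper, horizon >= 1,
            n_per_group >= 1, budget >= 1, seed == as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [study_config()]; the
#' `cohort` block holds [cohort_config()] overrides.
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in c("windows", "span"))
    if (!is.null(y[[nm]])) y[[nm]] <- as.integer(y[[nm]])
  do.call(study_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

write_json_file <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)

#' Run the full study end-to-end
#'
#' Orchestrates every stage from one configuration: generate (or
#' ingest) diaries; identify rescue-pack exacerbations; phenotype
#' engagement and summarise; run the descriptive event-aligned
#' analyses; fit day-offset-conditioned empirical profiles per
#' engagement group and simulate `n_per_group` series each; build
#' prediction instances; split at the series level, tune and train the
#' boosted-tree risk model; evaluate per group with bootstrap CIs
#' (plus the logistic baseline); write the report bundle to `out_dir`.
#'
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   all file output.
#' @return list of class `study_result` with every stage's objects.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(nm) {
    timings[[nm]] <<- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## 1. diaries ---------------------------------------------------------
  diaries <- stage("ingestion", {
    if (!is.null(config$paths)) {
      d <- do.call(read_diaries, config$paths)
      if (is.null(d$symptoms) || !nrow(d$symptoms))
        stop("empty or missing symptom diary")
      d
    } else {
      cc <- if (inherits(config$cohort, "cohort_config")) config$cohort
            else do.call(cohort_config, modifyList(list(seed = config$seed),
                                                   as.list(config$cohort)))
      co <- generate_cohort(cc)
      if (!nrow(co$symptoms)) stop("empty cohort")
      co
    }
  })
  tick("ingestion")

  ## 2. events + engagement phenotyping ---------------------------------
  events <- stage("event_identification", identify_exacerbations(diaries$medications))
  profiles <- stage("engagement_phenotyping",
                    build_engagement_profiles(events, diaries$symptoms,
                                              lower = config$lower, upper = config$upper,
                                              min_reports = config$min_reports,
                                              signal_rise = config$signal_rise,
                                              gap_days = config$gap_days))
  summary <- engagement_summary(profiles)
  tick("phenotyping")

  ## 3. descriptive analyses --------------------------------------------
  descriptive <- stage("descriptive", {
    aligned <- event_aligned_profiles(events, diaries$symptoms, diaries$medications)
    ser <- event_series(profiles, diaries$symptoms)
    firsts <- profiles$event_id[profiles$first_for_user == TRUE]
    chi <- chi_square_scores(
      ser$records[series_id %in% firsts, score],
      ser$records[!series_id %in% firsts, score])
    sub <- aligned[cohort == "subsequent"]
    lag <- peak_lag(sub$mean_saba,
                    ifelse(is.na(sub$mean_score), -Inf, sub$mean_score),
                    sub$day_offset)
    gold <- gold_group(diaries$profiles)
    user_cls <- data.table::as.data.table(profiles)[
      , .(frac = mean(pre70_fraction)), by = user_id]
    user_cls[, class := classify_engagement(frac, config$lower, config$upper)]
    gd <- data.table::data.table(user_id = diaries$profiles$user_id, gold = gold)
    merged <- merge(user_cls, gd, by = "user_id")
    crosstab <- engagement_by_gold(merged$class, merged$gold)
    list(aligned = aligned, chi_square = chi, peak_lag = lag,
         gold_crosstab = crosstab)
  })
  tick("descriptive")

  ## 4. group-conditioned simulation ------------------------------------
  sim <- stage("simulation", {
    ser <- event_series(profiles, diaries$symptoms)
    groups <- levels(profiles$group)
    fitted <- list(); sims <- list()
    for (g in groups) {
      ids <- profiles$event_id[as.character(profiles$group) == g]
      if (length(ids) < config$min_source_series) next
      sub <- exa_series(ser$records[series_id %in% ids],
                        ser$info[series_id %in% ids])
      fitted[[g]] <- fit_group_profile(sub, group = g, score_bin = config$score_bin)
      sims[[g]] <- simulate_exacerbation_series(fitted[[g]], config$n_per_group,
                                                seed = config$seed + 1L + match(g, groups))
    }
    if (!length(sims)) stop("no group had enough source series to simulate")
    all_sim <- exa_series(
      records = data.table::rbindlist(lapply(sims, `[[`, "records")),
      info = data.table::rbindlist(lapply(sims, `[[`, "info")))
    list(profiles = fitted, series = all_sim)
  })
  tick("simulation")

  ## 5. features ---------------------------------------------------------
  instances <- stage("featurisation",
                     build_instances(sim$series, windows = config$windows,
                                     horizon = config$horizon, span = config$span))
  tick("featurisation")

  ## 6. model ------------------------------------------------------------
  plan <- stage("split", split_series(sim$series$info$series_id,
                                      test_fraction = config$test_fraction,
                                      k = config$k, seed = config$seed + 11L))
  tuned <- stage("training", tune_and_train(instances, plan, budget = config$budget,
                                            seed = config$seed + 12L))
  tick("training")
  test_inst <- instances[series_id %in% plan$test]
  evaluation <- stage("evaluation",
                      evaluate_by_group(tuned, test_inst,
                                        boot_reps = config$boot_reps,
                                        seed = config$seed + 13L))
  baseline <- baseline_eval <- NULL
  if (isTRUE(config$with_baseline)) {
    baseline <- stage("baseline", train_logistic_baseline(instances, plan))
    baseline_eval <- stage("baseline_evaluation",
                           evaluate_by_group(baseline, test_inst,
                                             boot_reps = config$boot_reps,
                                             seed = config$seed + 13L))
  }
  tick("evaluation")

  result <- structure(list(
    config = config, diaries = diaries, events = events, profiles = profiles,
    summary = summary, descriptive = descriptive, sim = sim,
    instances = instances, plan = plan, tuned = tuned,
    evaluation = evaluation, baseline = baseline,
    baseline_eval = baseline_eval,
    log = list(seed = config$seed, timings = timings,
               r_version = R.version.string,
               package_version = as.character(utils::packageVersion("copdengage")))),
    class = "study_result")

  if (!is.null(out_dir)) stage("report", write_study_result(result, out_dir))
  result
}

#' Write a study result bundle to disk
#'
#' @param result a `study_result` from [run_study()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_result <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  data.table::fwrite(result$profiles, fp("engagement_profiles.csv"))
  s <- result$summary
  s$quality_pct <- as.data.frame(s$quality_pct)
  write_json_file(unclass(s), fp("summary.json"))
  data.table::fwrite(result$descriptive$aligned, fp("profiles_first_vs_subsequent.csv"))
  data.table::fwrite(result$descriptive$gold_crosstab, fp("gold_crosstab.csv"))
  chi <- result$descriptive$chi_square
  chi$table <- as.data.frame.matrix(chi$table)
  write_json_file(c(chi, peak_lag_days = result$descriptive$peak_lag),
                  fp("chi_square.json"))
  prof_json <- lapply(result$sim$profiles, function(p) list(
    group = p$group, n_source_series = p$n_source_series,
    score_bin = p$score_bin, offsets = p$offsets,
    report_prob = round(p$report_prob, 6),
    score_dist = apply(round(p$score_dist, 6), 1, as.numeric, simplify = FALSE),
    course_dist = round(p$course_dist, 6)))
  write_json_file(prof_json, fp("profiles.json"))
  data.table::fwrite(result$sim$series$records, fp("simulated_series.csv"))
  data.table::fwrite(result$sim$series$info, fp("simulated_series_info.csv"))
  if (isTRUE(result$config$write_instances))
    data.table::fwrite(result$instances, fp("instances.csv"))
  data.table::fwrite(result$evaluation, fp("evaluation_report.csv"))
  write_json_file(list(model = result$evaluation,
                       baseline = result$baseline_eval,
                       best_params = result$tuned$best_params),
                  fp("evaluation_report.json"))
  data.table::fwrite(result$tuned$trials, fp("tuning_trials.csv"))
  write_json_file(result$log, fp("run_log.json"))
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", x$summary$n_events, "events,",
      nrow(x$sim$series$info), "simulated series,",
      nrow(x$instances), "instances\n")
  print(x$evaluation[, .(group, auroc, average_precision)])
  invisible(x)
}
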