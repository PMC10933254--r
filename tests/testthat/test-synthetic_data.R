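test_that("generate_cohort is deterministic and validates its config", {
  a <- generate_cohort(cohort_config(n_users = 10, seed = 3))
  b <- generate_cohort(cohort_config(n_users = 10, seed = 3))
  expect_identical(a$symptoms, b$symptoms)
  expect_identical(a$medications, b$medications)
  expect_identical(a$truth$events, b$truth$events)
  c <- generate_cohort(cohort_config(n_users = 10, seed = 4))
  expect_false(identical(a$symptoms, c$symptoms))

  empty <- generate_cohort(cohort_config(n_users = 0, seed = 1))
  expect_equal(nrow(empty$symptoms), 0L)
  expect_equal(nrow(empty$medications), 0L)

  expect_error(cohort_config(engagement_mix = c(infrequent = 0.5, intermediate = 0.5,
                                                frequent = 0.5)), "sum to 1")
  expect_error(cohort_config(transition_prob = c(infrequent = 1.4, intermediate = 0,
                                                 frequent = 0)), "\\[0, 1\\]")
})

test_that("an all-frequent cohort lands in the frequent usage band", {
  co <- generate_cohort(cohort_config(
    n_users = 200, engagement_mix = c(infrequent = 0, intermediate = 0, frequent = 1),
    events_per_user_lambda = 0, seed = 9))
  ev <- identify_exacerbations(co$medications)
  prof <- build_engagement_profiles(ev, co$symptoms)
  # reporting probability 0.85 over 70 days: essentially all events >= 0.66
  expect_gte(mean(prof$pre70_fraction >= 0.66), 0.98)
  expect_gte(mean(prof$pre70_fraction), 0.80)
})

test_that("the cohort reproduces its configured engagement mix", {
  cfg <- cohort_config(n_users = 300, seed = 21)
  co <- generate_cohort(cfg)
  counts <- table(factor(co$truth$users$class, levels = names(cfg$engagement_mix)))
  # each class within ~4 binomial standard errors of its target share
  for (k in names(cfg$engagement_mix)) {
    p <- cfg$engagement_mix[[k]]
    se <- sqrt(p * (1 - p) / 300)
    expect_lt(abs(counts[[k]] / 300 - p), 4 * se + 1e-9)
  }
})

test_that("mean SABA usage peaks saba_lead_days before mean symptom scores", {
  co <- generate_cohort(cohort_config(n_users = 120, seed = 31))
  ev <- identify_exacerbations(co$medications)
  prof <- event_aligned_profiles(ev, co$symptoms, co$medications)
  sub <- prof[cohort == "subsequent"]
  lag <- peak_lag(sub$mean_saba, ifelse(is.na(sub$mean_score), -Inf, sub$mean_score),
                  sub$day_offset)
  expect_equal(lag, cohort_config()$saba_lead_days)
  expect_equal(sub$day_offset[which.max(sub$mean_saba)], 0L)
})

test_that("fit_group_profile matches direct tallies", {
  # all series report score 2 every day -> prob 1 everywhere, point mass on 2
  s <- bind_series(
    make_series(-70:70, rep(2, 141), id = "a"),
    make_series(-70:70, rep(2, 141), id = "b"))
  p <- fit_group_profile(s)
  expect_equal(p$report_prob, rep(1, 141))
  expect_equal(unname(p$score_dist[, 2]), rep(1, 141))
  expect_equal(p$n_source_series, 2L)

  # one series reporting on even offsets only
  even <- seq(-70, 70, by = 2)
  pe <- fit_group_profile(make_series(even, rep(1, length(even))))
  expect_equal(pe$report_prob[seq(1, 141, by = 2)], rep(1, 71))  # even offsets
  expect_equal(pe$report_prob[seq(2, 141, by = 2)], rep(0, 70))  # odd offsets

  # 50-series random fixture vs a hand-rolled count oracle
  set.seed(77)
  sers <- lapply(1:50, function(i) {
    off <- sort(sample(-70:70, sample(30:100, 1)))
    make_series(off, sample(1:4, length(off), replace = TRUE), id = paste0("s", i))
  })
  s50 <- do.call(bind_series, sers)
  p50 <- fit_group_profile(s50, score_bin = 3)
  rec <- s50$records
  for (d in c(-70, -35, -1, 0, 33, 70)) {
    expect_equal(p50$report_prob[d + 71],
                 sum(rec$day_offset == d) / 50)
    in_bin <- rec[rec$day_offset >= d - 3 & rec$day_offset <= d + 3]
    tall <- tabulate(in_bin$score, 4) / nrow(in_bin)
    expect_equal(unname(p50$score_dist[d + 71, ]), tall)
  }
  expect_error(fit_group_profile(make_series(integer(), integer())[c()]), "exa_series")
})

test_that("simulate_exacerbation_series honours the profile and the seed", {
  p <- constant_profile(score = 2L, course_length = 5L)
  s <- simulate_exacerbation_series(p, 10, seed = 5)
  expect_equal(nrow(s$info), 10L)
  expect_equal(nrow(s$records), 10L * 141L)
  expect_true(all(s$records$score == 2L))
  expect_true(all(s$info$course_length == 5L))
  # determinism
  s2 <- simulate_exacerbation_series(p, 10, seed = 5)
  expect_identical(s$records, s2$records)
  # a stochastic profile must react to the seed
  ph <- constant_profile(); ph$report_prob <- rep(0.5, 141)
  expect_false(identical(simulate_exacerbation_series(ph, 10, seed = 5)$records,
                         simulate_exacerbation_series(ph, 10, seed = 6)$records))
  expect_error(simulate_exacerbation_series(p, 0, seed = 1))
})
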