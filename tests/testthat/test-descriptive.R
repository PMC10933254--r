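test_that("event_aligned_profiles averages scores and SABA per day offset", {
  onset <- as.Date("2021-05-01")
  sy <- make_symptoms(dates = onset + (-70:70), scores = rep(2L, 141))
  ev <- identify_exacerbations(validate_medications(make_rescue(use = onset, len = 5)))
  # single (first) event, constant score 2, no SABA records
  prof <- suppressWarnings(tryCatch(event_aligned_profiles(ev, sy),
                                    error = function(e) e))
  expect_s3_class(prof, "error")  # subsequent cohort empty -> error

  med2 <- validate_medications(rbind(
    make_rescue(use = onset, len = 5),
    make_rescue(user = "u2", use = onset, len = 5),
    make_rescue(user = "u2", use = onset + 200, len = 5)))
  sy2 <- validate_symptoms(rbind(
    data.frame(user_id = "u1", date = onset + (-70:70), score = 2L),
    data.frame(user_id = "u2", date = onset - 5, score = 1L),
    data.frame(user_id = "u2", date = onset + 195, score = 3L)))
  prof2 <- event_aligned_profiles(identify_exacerbations(med2), sy2)
  first <- prof2[cohort == "first"]
  expect_equal(first[day_offset == 0, mean_score], 2)
  expect_true(all(first$mean_saba == 0))
  # two first events with scores 1 and 2 at offset -5 -> mean 1.5
  expect_equal(first[day_offset == -5, mean_score], 1.5)
  expect_equal(first[day_offset == -5, pct_reporting], 100)
  sub <- prof2[cohort == "subsequent"]
  expect_equal(sub[day_offset == -5, mean_score], 3)
})

test_that("chi_square_scores matches the closed-form 2x2 oracle and scales", {
  same <- chi_square_scores(rep(c(1, 2), c(10, 10)), rep(c(1, 2), c(10, 10)))
  expect_equal(same$statistic, 0)
  t22 <- chi_square_scores(rep(c(1, 2), c(20, 10)), rep(c(1, 2), c(10, 20)))
  expect_equal(t22$df, 1)
  expect_equal(t22$statistic, 20 / 3, tolerance = 1e-9)
  # doubling all cells doubles the statistic
  t44 <- chi_square_scores(rep(c(1, 2), c(40, 20)), rep(c(1, 2), c(20, 40)))
  expect_equal(t44$statistic, 2 * t22$statistic, tolerance = 1e-9)
  # zero-count categories are pooled, not fatal
  ok <- chi_square_scores(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_true(is.finite(ok$statistic))
  expect_error(chi_square_scores(numeric(), c(1, 2)), "both cohorts")
})

test_that("chi_square_scores equals sum((O-E)^2/E) on random tables", {
  set.seed(41)
  for (rep in 1:50) {
    n1 <- sample(50:200, 1); n2 <- sample(50:200, 1)
    s1 <- sample(1:4, n1, replace = TRUE, prob = runif(4) + 0.1)
    s2 <- sample(1:4, n2, replace = TRUE, prob = runif(4) + 0.1)
    got <- chi_square_scores(s1, s2)
    expect_equal(got$statistic, oracle_chisq(t(got$table)), tolerance = 1e-9)
  }
})

test_that("peak_lag returns the offset difference with earliest-tie rule", {
  off <- -10:10
  saba <- ifelse(off == 0, 5, 1)
  score <- ifelse(off == 3, 3, 1)
  expect_equal(peak_lag(saba, score, off), 3L)
  expect_equal(peak_lag(saba, saba, off), 0L)
  bimodal <- ifelse(off %in% c(-1, 4), 9, 1)
  expect_equal(peak_lag(saba, bimodal, off), -1L)  # earliest max wins
  expect_error(peak_lag(numeric(), numeric(), integer()), "empty")
})

test_that("gold_group applies the 2022 combined assessment", {
  p <- data.frame(user_id = paste0("u", 1:6),
                  age = 70, sex = "male",
                  cat_score = c(5, 15, 20, 5, NA, NA),
                  mmrc = c(1, 1, 1, 1, 3, NA),
                  moderate_exacerbations_last_year = c(0, 2, 1, 0, 0, 1),
                  hospitalisations_last_year = c(0, 0, 0, 1, 0, 0))
  g <- gold_group(validate_profiles(p))
  expect_equal(as.character(g),
               c("A",  # 0 exac, CAT 5
                 "D",  # 2 exac, CAT 15
                 "B",  # 1 moderate, no hospitalisation, CAT 20
                 "C",  # hospitalised, low symptoms
                 "B",  # CAT missing but mMRC 3 high
                 NA))  # all symptom measures missing -> undetermined
})

test_that("engagement_by_gold rows are percentages that sum to 100", {
  cls <- rep(c("frequent", "intermediate", "infrequent"), each = 4)
  gold <- factor(rep("D", 12), levels = c("A", "B", "C", "D"))
  tab <- engagement_by_gold(cls, gold)
  expect_equal(tab$D, rep(100, 3))
  expect_equal(sum(tab$n), 12L)

  # hand-tabulated 12-user fixture
  gold2 <- factor(c("A", "A", "B", "D",  "B", "B", "C", "D",  "D", "D", "D", "C"),
                  levels = c("A", "B", "C", "D"))
  tab2 <- engagement_by_gold(cls, gold2)
  f <- tab2[tab2$engagement == "frequent"]
  expect_equal(unlist(f[, c("A", "B", "C", "D")], use.names = FALSE),
               c(50, 25, 0, 25))
  expect_equal(rowSums(as.matrix(tab2[, c("A", "B", "C", "D")])), rep(100, 3),
               ignore_attr = TRUE)
  expect_error(engagement_by_gold(character(), factor(character())), "no labelled")
})
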