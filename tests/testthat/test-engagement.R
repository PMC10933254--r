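test_that("usage_fraction counts registered days over the window length", {
  onset <- as.Date("2021-06-01")
  s35 <- make_symptoms(dates = onset - seq(1, 70, by = 2), scores = rep(2, 35))
  expect_equal(usage_fraction(s35, "u1", onset, c(-70, -1)), 0.5)
  expect_equal(usage_fraction(s35, "nobody", onset, c(-70, -1)), 0)
  sall <- make_symptoms(dates = onset - 1:70, scores = rep(2, 70))
  expect_equal(usage_fraction(sall, "u1", onset, c(-70, -1)), 1)
  expect_equal(usage_fraction(sall, "u1", onset, c(-21, -1)), 1)
  expect_error(usage_fraction(sall, "u1", onset, c(-1, -5)))
})

test_that("classify_engagement honours the printed boundaries", {
  expect_equal(as.character(classify_engagement(0.70)), "frequent")
  expect_equal(as.character(classify_engagement(0.50)), "intermediate")
  expect_equal(as.character(classify_engagement(0.10)), "infrequent")
  # >=66% is frequent (closed); <33% is infrequent (open at 0.33)
  expect_equal(as.character(classify_engagement(0.66)), "frequent")
  expect_equal(as.character(classify_engagement(0.33)), "intermediate")
  expect_error(classify_engagement(1.2), "\\[0, 1\\]")
  expect_error(classify_engagement(-0.1), "\\[0, 1\\]")
  # monotone step function
  grid <- classify_engagement(seq(0, 1, by = 0.01))
  expect_true(all(diff(as.integer(grid)) >= 0))
})

test_that("classify_transition flags only strict upward class changes", {
  expect_equal(as.character(classify_transition("infrequent", 0.70)),
               "engaged_near_exacerbation")
  expect_equal(as.character(classify_transition("frequent", 0.90)), "consistent")
  expect_equal(as.character(classify_transition("intermediate", 0.20)), "consistent")
  expect_equal(as.character(classify_transition("intermediate", 0.70)),
               "engaged_near_exacerbation")
  # property: no transition when the 21-day class does not exceed the 70-day class
  set.seed(4)
  for (i in 1:200) {
    f70 <- runif(1); f21 <- runif(1)
    c70 <- classify_engagement(f70)
    tr <- classify_transition(c70, f21)
    if (classify_engagement(f21) <= c70)
      expect_equal(as.character(tr), "consistent")
    if (f21 <= f70)
      expect_equal(as.character(tr), "consistent")
  }
})

test_that("classify_quality separates fixed reporting from reporting with signal", {
  expect_equal(classify_quality(-(1:20), rep(3, 20)), "fixed_reporting")
  # baseline mean 1.2 over -70..-8, final-week mean 2.5
  off <- c(-60:-51, -7:-1)
  sc <- c(rep(1, 8), rep(2, 2), c(2, 2, 3, 3, 2, 3, 2))
  expect_equal(classify_quality(off, sc), "reporting_with_signal")
  expect_equal(classify_quality(-(1:3), c(1, 2, 3)), "undetermined")
  # varying scores but flat trend
  expect_equal(classify_quality(-(1:30), rep(c(1, 2), 15)), "neither")
  # reports outside -70..-1 are ignored
  expect_equal(classify_quality(c(0, 5, 10), c(3, 3, 3)), "undetermined")
})

test_that("post-event disengagement flags score 4 or an early long gap", {
  expect_true(flag_post_disengagement(1, 4))
  expect_false(flag_post_disengagement(1:70, rep(2, 70)))
  # no reports on +1..+20, then daily: gap of 20 >= 14 starting day +1
  expect_true(flag_post_disengagement(21:70, rep(2, 50)))
  # gap starting after day +14 does not count
  off <- c(1:14, 29:70)
  expect_false(flag_post_disengagement(off, rep(2, length(off))))
  # score 4 before onset also flags
  expect_true(flag_post_disengagement(c(-5, 1:70), c(4, rep(2, 70))))
})

test_that("engagement_summary conserves counts and percentages", {
  p <- data.table::data.table(
    class70 = c("frequent", "infrequent", "intermediate", "frequent"),
    transition = c("consistent", "engaged_near_exacerbation", "consistent", "consistent"),
    quality = c("fixed_reporting", "undetermined", "neither", "reporting_with_signal"),
    post_disengaged = c(FALSE, TRUE, FALSE, FALSE),
    retrospective = c(FALSE, TRUE, NA, FALSE))
  s <- engagement_summary(p)
  expect_equal(sum(s$class_counts), 4L)
  expect_equal(sum(s$class_pct), 100)
  expect_equal(s$transition_combined_pct, 50)
  expect_equal(s$post_disengaged_pct, 25)
  s1 <- engagement_summary(p[1])
  expect_equal(unname(s1$class_pct["frequent"]), 100)
  expect_error(engagement_summary(p[0]), "empty")
})

test_that("profiles built from a constructed diary carry the expected labels", {
  onset <- as.Date("2021-06-01")
  # daily reporting before onset with a final-week rise; full post reporting
  pre_dates <- onset - 1:70
  pre_scores <- ifelse(1:70 <= 7, 3L, 1L)  # days -1..-7 high
  post_dates <- onset + 1:70
  sy <- make_symptoms(dates = c(pre_dates, post_dates),
                      scores = c(pre_scores, rep(1L, 70)))
  med <- validate_medications(make_rescue(use = onset, len = 5))
  prof <- build_engagement_profiles(identify_exacerbations(med), sy)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$pre70_fraction, 1)
  expect_equal(as.character(prof$class70), "frequent")
  expect_equal(as.character(prof$transition), "consistent")
  expect_equal(prof$quality, "reporting_with_signal")
  expect_false(prof$post_disengaged)
  expect_equal(as.character(prof$group), "frequent")
})
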