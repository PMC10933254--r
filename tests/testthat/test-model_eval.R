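test_that("split_series produces a disjoint, balanced, reproducible plan", {
  ids <- sprintf("s%03d", 1:100)
  plan <- split_series(ids, seed = 5)
  expect_length(plan$train, 75)
  expect_length(plan$test, 25)
  expect_length(intersect(plan$train, plan$test), 0)
  expect_setequal(c(plan$train, plan$test), ids)
  expect_setequal(names(plan$fold), plan$train)
  expect_lte(diff(range(table(plan$fold))), 1)
  expect_identical(split_series(ids, seed = 5), plan)
  expect_false(identical(split_series(ids, seed = 6), plan))
  expect_error(split_series(ids[1:4], k = 5), "too few")
})

test_that("auroc matches its definition and handles ties", {
  expect_equal(auroc(c(1, 0, 0, 0), c(0.9, 0.1, 0.2, 0.3)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5)), 0.75)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("average_precision matches its definition", {
  expect_equal(average_precision(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(average_precision(c(1, 0), c(0.2, 0.8)), 0.5)
  expect_error(average_precision(c(0, 0), c(0.1, 0.2)), "positive")
  # expectation under random ranking ~ positive fraction
  set.seed(8)
  lab <- rbinom(20000, 1, 0.1)
  expect_lt(abs(average_precision(lab, runif(20000)) - 0.1), 0.02)
})

test_that("ranking metrics agree with brute-force oracles on small inputs", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
    sc <- sample(seq(0.1, 0.9, by = 0.1), n, replace = TRUE)  # ties likely
    expect_equal(auroc(lab, sc), oracle_auroc(lab, sc), tolerance = 1e-12)
    expect_equal(average_precision(lab, sc), oracle_average_precision(lab, sc),
                 tolerance = 1e-12)
  }
})

test_that("the boosted-tree learner separates a separable toy problem", {
  set.seed(3)
  x <- matrix(c(rnorm(300, -2), rnorm(300, 2)), ncol = 1)
  y <- rep(c(0, 1), each = 300)
  m <- copdengage:::gbt_fit(x, y, n_trees = 60L, max_depth = 2L,
                            learning_rate = 0.3, seed = 1)
  expect_gte(auroc(y, predict(m, x)), 0.99)
  expect_error(copdengage:::gbt_fit(x, rep(1, 600), n_trees = 5L), "single-class")
  # missing values routed by the learned default direction still score
  x2 <- x; x2[sample(600, 60)] <- NA
  m2 <- copdengage:::gbt_fit(x2, y, n_trees = 60L, max_depth = 2L,
                             learning_rate = 0.3, seed = 1)
  expect_gte(auroc(y, predict(m2, x2)), 0.95)
})

# small labelled instance set builder used by the tuning/evaluation tests;
# noise = 0 gives a cleanly separable problem, larger values blur it
toy_instances <- function(n_series = 60, signal = TRUE, seed = 1, noise = 0) {
  set.seed(seed)
  sers <- lapply(seq_len(n_series), function(i) {
    off <- -70:70
    base <- sample(1:2, 141, replace = TRUE)
    if (signal) {
      hot <- off >= -3 & off <= -1
      base[hot] <- ifelse(runif(3) < 1 - noise, 3L, base[hot])
      if (noise > 0) {
        flip <- runif(141) < noise / 4
        base[flip & !hot] <- 3L
      }
    }
    make_series(off, base, id = sprintf("t%03d", i), course_length = 5L)
  })
  build_instances(do.call(bind_series, sers))
}

test_that("tune_and_train respects the budget and finds signal", {
  inst <- toy_instances(40)
  plan <- split_series(unique(inst$series_id), seed = 2)
  tm1 <- tune_and_train(inst, plan, budget = 1, seed = 4)
  expect_equal(nrow(tm1$trials), 1L)
  expect_s3_class(tm1$model, "gbt_model")
  tm1b <- tune_and_train(inst, plan, budget = 1, seed = 4)
  expect_equal(tm1$trials, tm1b$trials)
  expect_equal(predict(tm1, inst[1:50]), predict(tm1b, inst[1:50]))
  test_inst <- inst[series_id %in% plan$test]
  expect_gte(auroc(test_inst$label, predict(tm1, test_inst)), 0.9)
})

test_that("series-permuted labels give chance-level held-out performance", {
  inst <- toy_instances(80, seed = 6)
  # permute at series level: positives all moved to 3 random offsets per series
  set.seed(9)
  inst[, label := 0L]
  for (sid in unique(inst$series_id)) {
    offs <- inst[series_id == sid, day_offset]
    pick <- sample(offs, 3)
    inst[series_id == sid & day_offset %in% pick, label := 1L]
  }
  plan <- split_series(unique(inst$series_id), seed = 2)
  tm <- tune_and_train(inst, plan, budget = 2, seed = 5)
  test_inst <- inst[series_id %in% plan$test]
  expect_gte(nrow(test_inst), 2000)
  a <- auroc(test_inst$label, predict(tm, test_inst))
  expect_gte(a, 0.45); expect_lte(a, 0.55)
})

test_that("evaluate_by_group reports per group with series-bootstrap CIs", {
  inst <- toy_instances(60, seed = 11)
  plan <- split_series(unique(inst$series_id), seed = 3)
  tm <- tune_and_train(inst, plan, budget = 1, seed = 7)
  test_inst <- inst[series_id %in% plan$test]

  # identical data across two groups -> identical metrics
  two <- data.table::copy(test_inst)[, group := rep(c("g1", "g2"), length.out = .N)]
  two <- rbind(data.table::copy(test_inst)[, group := "g1"],
               data.table::copy(test_inst)[, group := "g2"])
  rep2 <- evaluate_by_group(tm, two, boot_reps = 50, seed = 1)
  expect_equal(nrow(rep2), 2L)
  expect_equal(rep2$auroc[1], rep2$auroc[2])
  expect_equal(rep2$average_precision[1], rep2$average_precision[2])
  expect_true(all(rep2$auroc_lo <= rep2$auroc & rep2$auroc <= rep2$auroc_hi))

  # five groups in -> five rows out; one-class group reported unevaluable
  five <- data.table::copy(test_inst)[, group := sample(paste0("g", 1:5), .N, replace = TRUE)]
  expect_equal(nrow(evaluate_by_group(tm, five, boot_reps = 20, seed = 1)), 5L)
  onec <- data.table::copy(test_inst)[, group := "only"][label == 0]
  r1 <- evaluate_by_group(tm, onec, boot_reps = 20, seed = 1)
  expect_true(r1$unevaluable)
  expect_true(is.na(r1$auroc))

  # determinism of the bootstrap
  ra <- evaluate_by_group(tm, two, boot_reps = 50, seed = 9)
  rb <- evaluate_by_group(tm, two, boot_reps = 50, seed = 9)
  expect_identical(ra, rb)
})

test_that("bootstrap CI width shrinks when the test set quadruples", {
  set.seed(15)
  small <- toy_instances(40, seed = 21, noise = 0.5)[, group := "g"]
  big <- toy_instances(160, seed = 21, noise = 0.5)[, group := "g"]
  plan_s <- split_series(unique(small$series_id), test_fraction = 0.5, k = 2, seed = 1)
  m <- tune_and_train(small, plan_s, budget = 1, seed = 2)
  w <- function(inst) {
    r <- evaluate_by_group(m, inst, boot_reps = 200, seed = 3)
    r$auroc_hi - r$auroc_lo
  }
  expect_lt(w(big), w(small))
})

test_that("the logistic baseline is deterministic and finds the same signal", {
  inst <- toy_instances(40, seed = 31)
  plan <- split_series(unique(inst$series_id), seed = 2)
  b1 <- train_logistic_baseline(inst, plan)
  b2 <- train_logistic_baseline(inst, plan)
  expect_identical(b1$coef, b2$coef)
  test_inst <- inst[series_id %in% plan$test]
  expect_gte(auroc(test_inst$label, predict(b1, test_inst)), 0.9)
  expect_error(train_logistic_baseline(inst[label == 0], plan), "single-class")
})
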