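test_that("item generation spans the rating scale and validates its input", {
  items <- gen_items(180, seed = 1)
  expect_equal(nrow(items), 180)
  expect_false(any(duplicated(items$item_id)))
  expect_true(all(abs(items$latent_taste) <= 5))
  expect_true(all(abs(items$latent_health) <= 5))
  # the set should cover most of the scale, not cluster at 0
  expect_gt(diff(range(items$latent_taste)), 6)
  expect_equal(nrow(gen_items(2, seed = 1)), 2)
  expect_error(gen_items(1), "invalid design")
})

test_that("rating phases cover 180 items in sessions 1/5 and the 60-item core in 2-4", {
  items <- gen_items(180, seed = 2)
  r <- gen_ratings(items, n_subjects = 2, seed = 3)
  counts <- with(r[r$subject_id == 1 & r$attribute == "taste", ],
                 tapply(item_id, session, function(x) length(unique(x))))
  expect_equal(as.vector(counts[c("1", "5")]), c(180, 180))
  expect_equal(as.vector(counts[c("2", "3", "4")]), c(60, 60, 60))
  # the core subset is the same fixed set in every middle session
  core <- unique(r$item_id[r$session == 2])
  expect_setequal(unique(r$item_id[r$session == 4]), core)
  expect_true(all(abs(r$value) <= 5))
  expect_error(gen_ratings(items, 2, between_sd = -1), ">= 0")
})

test_that("noise-free ratings are identical across sessions", {
  items <- gen_items(60, seed = 4)
  r <- gen_ratings(items, n_subjects = 3, within_sd = 0, seed = 5)
  w <- reshape(r[r$attribute == "health" & r$subject_id == 2, ],
               idvar = "item_id", timevar = "session", direction = "wide",
               drop = c("subject_id", "attribute"))
  vals <- as.matrix(w[, -1])
  expect_true(all(vals == vals[, 1]))
})

test_that("session designs hit the study constants exactly", {
  items <- gen_items(180, seed = 6)
  ratings <- gen_ratings(items, 1, sessions = 1, seed = 7)
  d <- build_design(ratings, subject = 1, seed = 8)
  expect_equal(nrow(d$trials), 210)
  expect_equal(nrow(d$blocks), 17)
  expect_equal(sum(d$blocks$condition == "health"), 9)
  expect_equal(sum(d$blocks$condition == "natural"), 8)
  expect_equal(sum(d$blocks$n_trials), 210)
  # healthier labeling: hd strictly positive, challenge means tastier is less healthy
  expect_true(all(d$trials$hd > 0))
  expect_true(all(d$trials$td[d$trials$challenge] < 0))
  expect_equal(sum(d$trials$challenge), 105)
  # left-right coding is consistent with healthier/less-healthy coding
  flip <- d$trials$healthier_side == "left"
  expect_equal(d$trials$hd_lr, ifelse(flip, d$trials$hd, -d$trials$hd))
  # same seed, byte-identical design
  d2 <- build_design(ratings, subject = 1, seed = 8)
  expect_identical(d, d2)
})

test_that("condition trial totals vary around 110/100 across seeds", {
  items <- gen_items(180, seed = 9)
  ratings <- gen_ratings(items, 1, sessions = 1, seed = 10)
  totals <- sapply(1:12, function(s) {
    d <- build_design(ratings, subject = 1, seed = s)
    sum(d$trials$condition == "health")
  })
  expect_gt(mean(totals), 104)
  expect_lt(mean(totals), 117)
  expect_gt(var(totals), 0)     # jittered, not fixed
  expect_true(all(totals + (210 - totals) == 210))
})

test_that("challenge saturation works and infeasible demands error with the shortfall", {
  items <- gen_items(120, seed = 11)
  ratings <- gen_ratings(items, 1, sessions = 1, seed = 12)
  d <- build_design(ratings, subject = 1, challenge_fraction = 1, seed = 13)
  expect_true(all(d$trials$td < 0 & d$trials$hd > 0))
  # an impossible |td| cap lists how many pairs are missing
  expect_error(
    build_design(ratings, subject = 1, challenge_fraction = 1,
                 challenge_td_max = 0.001, seed = 13),
    "shortfall")
})

test_that("simulated datasets are reproducible and respect the deadline", {
  cohort <- make_cohort(3, sessions = 1, seed = 31, n_items = 100)
  tr <- cohort$trials
  expect_equal(nrow(tr), 3 * 210)
  ok <- !tr$censored
  expect_true(all(tr$rt[ok] > 0 & tr$rt[ok] <= 3))
  cohort2 <- make_cohort(3, sessions = 1, seed = 31, n_items = 100)
  expect_identical(tr, cohort2$trials)
  expect_error(simulate_dataset(cohort$designs, cohort$truth, dt = -1), "'dt'")
})

test_that("symmetric parameters yield balanced left choices in the dataset", {
  items <- gen_items(100, seed = 41)
  ratings <- gen_ratings(items, 2, sessions = 1, seed = 42)
  designs <- lapply(1:2, function(s) build_design(ratings, subject = s,
                                                  seed = 42 + s))
  null_p <- do.call(rbind, lapply(c("natural", "health"), function(cond)
    data.frame(subject_id = 1:2, condition = cond, session = 1, noise = 1,
               sp_bias = 0.5, ndt = 0.4, rst = 0, w_taste = 0, w_health = 0,
               drift_bias = 0)))
  ds <- suppressMessages(
    simulate_dataset(designs, null_p, sessions = 1, seed = 43))
  n <- sum(!ds$trials$censored)
  expect_lt(abs(mean(ds$trials$chose_left, na.rm = TRUE) - 0.5),
            3 * sqrt(0.25 / n))
})
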