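# logistic / Gaussian fixtures with known coefficients (no DDM involved)
fake_regression_trials <- function(n_subj = 12, n_per = 120, n_sess = 2,
                                   b_hd = 0, b_td = 1, b_cond = 1.2,
                                   b_hd_cond = 0, b_td_cond = 0,
                                   rt_td = 0, rt_hd = 0, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    u0 <- rnorm(n_subj, 0, 0.3)
    for (s in seq_len(n_subj)) {
      for (ss in seq_len(n_sess)) {
        for (cond in c("natural", "health")) {
          hd <- abs(rnorm(n_per, 0, 2)) + 0.05   # healthier-minus-less > 0
          td <- rnorm(n_per, 0, 2)
          ch <- as.numeric(cond == "health")
          eta <- u0[s] + b_hd * hd + b_td * td + b_cond * ch +
            b_hd_cond * hd * ch + b_td_cond * td * ch
          y <- rbinom(n_per, 1, plogis(eta))
          lrt <- -0.2 + u0[s] / 3 + rt_td * td + rt_hd * hd +
            rnorm(n_per, 0, 0.3)
          out[[length(out) + 1L]] <- data.frame(
            subject_id = s, session = ss, condition = cond, hd = hd, td = td,
            chose_healthier = y, rt = pmin(exp(lrt), 3), censored = FALSE,
            challenge = td < 0,
            left_item = 1L, right_item = 2L,
            chose_left = y)
        }
      }
    }
    do.call(rbind, out)
  })
}

test_that("the choice model has the specified structure and coding", {
  tr <- fake_regression_trials(seed = 2)
  m <- fit_choice_model(tr)
  terms <- m$coefficients$term
  # no hd:td interaction anywhere in the fixed effects
  expect_false(any(grepl("hd.*:.*td|td.*:.*hd", terms)))
  expect_true(all(c("hd", "td", "conditionhealth", "session2",
                    "hd:conditionhealth", "td:conditionhealth") %in% terms))
  # natural condition and session 1 are the reference levels
  expect_false(any(grepl("conditionnatural|session1", terms)))
  expect_true(all(m$coefficients$ci_low <= m$coefficients$ci_high))
  expect_error(fit_choice_model(tr[tr$condition == "natural", ]),
               "both cue conditions")
  expect_error(fit_choice_model(tr[tr$session == 1, ]), "2 sessions")
})

test_that("known logistic coefficients are recovered with near-nominal coverage", {
  truth <- c(hd = 0.4, td = 0.8, conditionhealth = 1.0,
             `hd:conditionhealth` = 0.6, `td:conditionhealth` = -0.5)
  covered <- 0; total <- 0; est_err <- c()
  for (s in 1:3) {
    tr <- fake_regression_trials(n_subj = 14, n_per = 160, b_hd = 0.4,
                                 b_td = 0.8, b_cond = 1.0, b_hd_cond = 0.6,
                                 b_td_cond = -0.5, seed = 2 + s)
    cf <- fit_choice_model(tr)$coefficients
    for (term in names(truth)) {
      row <- cf[cf$term == term, ]
      covered <- covered + (row$ci_low <= truth[[term]] &&
                              row$ci_high >= truth[[term]])
      total <- total + 1
      est_err <- c(est_err, row$estimate - truth[[term]])
    }
  }
  expect_gte(covered / total, 0.8)       # nominal 95%, MC slack allowed
  expect_lt(max(abs(est_err)), 0.25)     # point estimates close throughout
})

test_that("a null health effect gives an hd interval covering zero", {
  tr <- fake_regression_trials(b_hd = 0, b_td = 1, seed = 4)
  m <- fit_choice_model(tr)
  row <- m$coefficients[m$coefficients$term == "hd", ]
  expect_lt(row$ci_low, 0)
  expect_gt(row$ci_high, 0)
})

test_that("the RT model uses z-scored attributes and recovers null/nonnull effects", {
  tr <- fake_regression_trials(rt_td = -0.05, rt_hd = 0, seed = 5)
  m <- fit_rt_model(tr)
  cf <- m$coefficients
  expect_false(any(grepl("hd.*:.*td|td.*:.*hd", cf$term)))
  expect_true(any(grepl("challenge", cf$term)))
  td_row <- cf[cf$term == "td", ]
  expect_lt(td_row$ci_high, 0)     # faster RTs with larger td
  hd_row <- cf[cf$term == "hd", ]
  expect_lt(hd_row$ci_low, 0)
  expect_gt(hd_row$ci_high, 0)
  expect_error(fit_rt_model(transform(tr, rt = rt - 5)), "positive")
})

test_that("model-based prediction accuracy matches a per-trial loop oracle", {
  tr <- fake_regression_trials(n_subj = 6, n_per = 40, seed = 6)
  m <- fit_choice_model(tr)
  acc <- predict_accuracy_model(m, tr)
  # independent loop over a 50-trial subset
  sub <- tr[sample(nrow(tr), 50), ]
  acc_sub <- predict_accuracy_model(m, sub)
  d <- data.frame(hd = sub$hd, td = sub$td,
                  condition = factor(sub$condition,
                                     levels = c("natural", "health")),
                  session = factor(sub$session),
                  subject_id = factor(sub$subject_id))
  hits <- vapply(seq_len(50), function(i) {
    p <- stats::predict(m$fit, newdata = d[i, , drop = FALSE],
                        type = "response", allow.new.levels = TRUE)
    as.integer(p > 0.5) == sub$chose_healthier[i]
  }, logical(1))
  expect_equal(acc_sub$overall, mean(hits), tolerance = 1e-12)
  expect_true(acc$overall > 0.5 && acc$overall <= 1)
  expect_setequal(names(acc$by_session), c("session", "accuracy", "n"))
})

test_that("near-separable data drive model prediction accuracy toward 1", {
  tr <- fake_regression_trials(n_subj = 6, n_per = 100, b_td = 6, b_hd = 6,
                               b_cond = 0, seed = 7)
  m <- suppressMessages(fit_choice_model(tr))
  acc <- predict_accuracy_model(m, tr)
  expect_gt(acc$overall, 0.95)
})

test_that("attribute-based prediction is exact for attribute-driven choosers", {
  cohort <- make_cohort(3, sessions = 1, seed = 91, n_items = 80)
  tr <- cohort$trials
  r1 <- cohort$ratings[cohort$ratings$session == 1, ]
  rating_of <- function(att) {
    ra <- r1[r1$attribute == att, ]
    setNames(ra$value, paste(ra$subject_id, ra$item_id))
  }
  tv <- rating_of("taste"); hv <- rating_of("health")
  vl <- tv[paste(tr$subject_id, tr$left_item)]
  vr <- tv[paste(tr$subject_id, tr$right_item)]
  # force choices to follow the session-1 taste rating exactly
  tr$chose_left <- as.integer(vl > vr)
  tr$censored <- FALSE
  acc_t <- predict_accuracy_attribute(cohort$ratings, tr, "taste")
  expect_true(all(abs(acc_t$by_condition$accuracy - 1) < 1e-12))
  # health-attribute accuracy equals the pair set's taste-health agreement,
  # checked per subject x condition against a direct computation
  acc_h <- predict_accuracy_attribute(cohort$ratings, tr, "health")
  hl <- hv[paste(tr$subject_id, tr$left_item)]
  hr <- hv[paste(tr$subject_id, tr$right_item)]
  no_tie <- hl != hr
  for (i in seq_len(nrow(acc_h$per_subject))) {
    s <- acc_h$per_subject$subject_id[i]
    cond <- acc_h$per_subject$condition[i]
    sel <- no_tie & tr$subject_id == s & tr$condition == cond
    agree <- mean((hl > hr)[sel] == (tr$chose_left == 1)[sel])
    expect_equal(acc_h$per_subject$accuracy[i], agree, tolerance = 1e-12)
  }
})

test_that("accuracy operations are invariant to row order and left/right swaps", {
  cohort <- make_cohort(2, sessions = 1, seed = 101, n_items = 80)
  tr <- cohort$trials[!cohort$trials$censored, ]
  a0 <- predict_accuracy_attribute(cohort$ratings, tr, "taste")
  # permute rows
  a1 <- predict_accuracy_attribute(cohort$ratings,
                                   tr[sample(nrow(tr)), ], "taste")
  expect_equal(a1$by_condition$accuracy, a0$by_condition$accuracy)
  # swap left/right items and flip the choice coding
  sw <- tr
  sw[, c("left_item", "right_item")] <- sw[, c("right_item", "left_item")]
  sw$healthier_side <- ifelse(sw$healthier_side == "left", "right", "left")
  sw$td_lr <- -sw$td_lr; sw$hd_lr <- -sw$hd_lr
  sw$chose_left <- 1L - sw$chose_left
  a2 <- predict_accuracy_attribute(cohort$ratings, sw, "taste")
  expect_equal(a2$by_condition$accuracy, a0$by_condition$accuracy)
})

test_that("exact rating ties are excluded and tallied", {
  ratings <- data.frame(subject_id = 1, session = 1,
                        item_id = c(1, 2, 3),
                        attribute = "taste", value = c(2, 2, 4))
  trials <- data.frame(subject_id = 1, session = 1,
                       condition = c("natural", "natural"),
                       left_item = c(1, 1), right_item = c(2, 3),
                       chose_left = c(1L, 0L), censored = FALSE)
  acc <- predict_accuracy_attribute(ratings, trials, "taste")
  expect_equal(acc$excluded_ties, 1)
  expect_equal(acc$by_condition$n_trials, 1)
  expect_equal(acc$by_condition$accuracy, 1)  # chose item 3, rated higher
})
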