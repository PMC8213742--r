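test_that("icc_a1 equals the brute-force ANOVA oracle", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(5:30, 1)
      k <- sample(2:6, 1)
      m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
        rnorm(n) + rep(rnorm(k, sd = 0.3), each = n)
      a <- icc_a1(m)
      b <- icc_a1_brute(m)
      expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
      expect_equal(a$f_value, b$f_value, tolerance = 1e-12)
      expect_equal(a$df2, b$df2, tolerance = 1e-10)
      expect_equal(a$ci_low, b$ci_low, tolerance = 1e-10)
      expect_equal(a$ci_high, b$ci_high, tolerance = 1e-10)
    }
  })
})

test_that("perfect agreement and known variance ratios are recovered", {
  withr::with_seed(2, {
    rows <- rnorm(40)
    m <- matrix(rep(rows, 4), ncol = 4)       # identical columns
    r <- icc_a1(m)
    expect_equal(r$estimate, 1.0, tolerance = 1e-12)
    # row variance : error variance = 4 : 1 -> ICC 0.8
    big <- matrix(rnorm(500 * 5, sd = 1), 500, 5) + rnorm(500, sd = 2)
    expect_equal(icc_a1(big)$estimate, 0.8, tolerance = 0.05)
  })
})

test_that("icc_a1 is invariant to permutations and shared affine transforms", {
  withr::with_seed(3, {
    m <- matrix(rnorm(60), 12, 5) + rnorm(12)
    e0 <- icc_a1(m)$estimate
    expect_equal(icc_a1(m[sample(12), ])$estimate, e0, tolerance = 1e-12)
    expect_equal(icc_a1(m[, sample(5)])$estimate, e0, tolerance = 1e-12)
    expect_equal(icc_a1(m + 7)$estimate, e0, tolerance = 1e-12)
    expect_equal(icc_a1(m * 3.2)$estimate, e0, tolerance = 1e-12)
  })
})

test_that("interpretation labels use left-closed bins at the published cut points", {
  expect_equal(icc_label(c(0.39, 0.40, 0.59, 0.60, 0.74, 0.75, 1.0)),
               c("Poor", "Fair", "Fair", "Good", "Good", "Excellent",
                 "Excellent"))
  expect_true(is.na(icc_label(NA)))
})

test_that("degenerate matrices are flagged, not crashed", {
  m <- matrix(1.5, 6, 3)
  r <- icc_a1(m)
  expect_true(r$degenerate)
  expect_true(is.na(r$estimate))
  expect_error(icc_a1(matrix(1, 1, 3)), "at least 2")
})

# direct (non-DDM) trial tables with a known reliability structure
fake_choice_trials <- function(n_subj = 20, n_sess = 5, n_per = 60,
                               stable = TRUE, seed = 1) {
  withr::with_seed(seed, {
    out <- list()
    p_subj <- runif(n_subj, 0.2, 0.8)
    for (s in seq_len(n_subj)) {
      for (ss in seq_len(n_sess)) {
        p <- if (stable) p_subj[s] else runif(1, 0.2, 0.8)
        for (cond in c("natural", "health")) {
          pc <- min(p + ifelse(cond == "health", 0.15, 0), 0.95)
          out[[length(out) + 1L]] <- data.frame(
            subject_id = s, session = ss, condition = cond,
            chose_healthier = rbinom(n_per, 1, pc), censored = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
}

test_that("choice-frequency reliability separates stable from redrawn cohorts", {
  stable <- choice_frequency_reliability(fake_choice_trials(stable = TRUE))
  expect_true(all(stable$table$estimate[1:2] > 0.6))
  expect_true(stable$natural$label %in% c("Good", "Excellent"))
  unstable <- choice_frequency_reliability(fake_choice_trials(stable = FALSE,
                                                              seed = 2))
  expect_true(all(unstable$table$estimate[1:2] < 0.4))
  expect_equal(unstable$health$label, "Poor")
})

test_that("rating reliability hits the generator's implied ICC and is unit-aware", {
  items <- gen_items(100, seed = 5)
  r0 <- gen_ratings(items, 4, within_sd = 0, seed = 6)
  rr0 <- rating_reliability(r0, unit = "subject", sessions = 1:5)
  expect_true(all(abs(rr0$per_unit$estimate - 1) < 1e-9))
  # target ICC ~0.6 via the variance-ratio construction
  vl <- var(c(items$latent_taste, items$latent_health))
  wsd <- sqrt((vl + 1) * 0.4 / 0.6)   # between_sd = 1
  r1 <- gen_ratings(items, 6, between_sd = 1,
                    within_sd = c(taste = wsd, health = wsd), seed = 7)
  rr1 <- rating_reliability(r1, unit = "subject", sessions = 1:5)
  expect_true(all(abs(rr1$summary$mean - 0.6) < 0.1))
  # item-unit analysis is a different decomposition, not a silent reuse
  rr_item <- rating_reliability(r1, unit = "item", sessions = 1:5)
  expect_equal(unique(rr_item$per_unit$unit), "item")
  expect_equal(nrow(rr_item$per_unit), 2 * 60)
  expect_false(isTRUE(all.equal(sort(rr_item$summary$mean),
                                sort(rr1$summary$mean), tolerance = 1e-6)))
})

test_that("parameter reliability returns condition and difference rows", {
  withr::with_seed(8, {
    fits <- expand.grid(subject_id = 1:12, session = 1:5,
                        condition = c("natural", "health"),
                        parameter = c("w_taste", "w_health"),
                        stringsAsFactors = FALSE)
    subj_eff <- rnorm(12)
    fits$estimate <- subj_eff[fits$subject_id] +
      rnorm(nrow(fits), sd = ifelse(fits$condition == "health", 0.3, 1.5))
    tab <- parameter_reliability(fits)
    expect_setequal(unique(tab$condition),
                    c("natural", "health", "difference"))
    for (pn in c("w_taste", "w_health")) {
      e_h <- tab$estimate[tab$parameter == pn & tab$condition == "health"]
      e_n <- tab$estimate[tab$parameter == pn & tab$condition == "natural"]
      expect_gt(e_h, e_n)   # less session noise -> higher reliability
    }
    # constant estimates are a degenerate (flagged) reliability analysis
    cfits <- fits
    cfits$estimate <- 1
    expect_true(all(is.na(parameter_reliability(cfits)$estimate)))
  })
})

test_that("parameter range comparison matches a hand-coded paired t-test", {
  withr::with_seed(9, {
    fits <- expand.grid(subject_id = 1:6, session = 1:5,
                        condition = c("natural", "health"),
                        parameter = "w_taste", stringsAsFactors = FALSE)
    fits$estimate <- rnorm(nrow(fits),
                           sd = ifelse(fits$condition == "natural", 1, 0.4))
    res <- parameter_range_comparison(fits)
    rngs <- res$ranges
    h <- rngs$range[rngs$condition == "health"][order(rngs$subject_id[rngs$condition == "health"])]
    n <- rngs$range[rngs$condition == "natural"][order(rngs$subject_id[rngs$condition == "natural"])]
    d <- h - n
    t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(res$tests$t, t_manual, tolerance = 1e-12)
    expect_equal(res$tests$df, length(d) - 1)
    expect_equal(res$tests$p_value,
                 2 * pt(abs(t_manual), length(d) - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    # identical ranges in both conditions
    fits$estimate <- rep_len(rnorm(30), nrow(fits))
    same <- parameter_range_comparison(fits)
    expect_equal(same$tests$t, 0)
    expect_equal(same$tests$p_value, 1)
  })
})
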