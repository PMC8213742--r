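test_that("preconditions are enforced", {
  p <- rst_params(w_taste = 0.8, ndt = 0.5)
  tr <- make_trials(p, 10, seed = 1)
  expect_error(fit_subject(tr), "minimum")
  big <- make_trials(p, 40, seed = 1)
  expect_error(fit_hierarchical(transform(big, subject_id = 1)), "5 subjects")
})

test_that("single-subject estimates recover the generative parameters", {
  p <- rst_params(noise = 1, sp_bias = 0.5, ndt = 0.6, rst = 0.1,
                  w_taste = 0.9, w_health = 0.6, drift_bias = 0)
  tr <- make_trials(p, 500, seed = 2)
  f <- fit_subject(tr, control = fit_control(seed = 3))
  for (pn in c("w_taste", "w_health", "ndt", "noise")) {
    expect_lt(abs(f$estimates[[pn]] - p[[pn]]),
              3 * max(f$se[[pn]], 0.02, na.rm = TRUE))
  }
  expect_lt(abs(f$estimates[["ndt"]] - 0.6), 0.05)
})

test_that("the standard-DDM fit is the rstDDM constrained to rst = 0", {
  p <- rst_params(noise = 1, ndt = 0.5, rst = 0, w_taste = 0.7,
                  w_health = 0.4)
  tr <- make_trials(p, 120, seed = 4)
  f <- fit_subject(tr, model = "standard",
                   control = fit_control(n_starts = 1, maxit = 300))
  expect_identical(f$estimates[["rst"]], 0)
  # identical parameters => identical likelihood under either model label
  expect_equal(rst_loglik(f$params, tr), f$loglik, tolerance = 1e-6)
})

test_that("two-stage group summaries recover cohort means", {
  cohort <- make_cohort(6, sessions = 1, seed = 51, n_items = 80)
  tr <- cohort$trials[cohort$trials$condition == "health", ]
  hf <- fit_hierarchical(tr, mode = "two_stage",
                         control = fit_control(n_starts = 1, maxit = 300,
                                               seed = 1))
  truth <- cohort$truth[cohort$truth$condition == "health", ]
  g <- setNames(hf$group$mean, hf$group$parameter)
  expect_lt(abs(g[["w_health"]] - mean(truth$w_health)), 0.2)
  expect_lt(abs(g[["ndt"]] - mean(truth$ndt)), 0.05)
  expect_lt(abs(g[["noise"]] - mean(truth$noise)), 0.12)
  expect_true(all(hf$group$se > 0))
  expect_equal(hf$group$parameter,
               c("noise", "sp_bias", "ndt", "rst", "w_taste", "w_health",
                 "drift_bias"))
})

test_that("MCMC and two-stage modes agree on group means", {
  cohort <- make_cohort(10, sessions = 1, seed = 61, n_items = 80,
                        n_trials = 120)
  tr <- cohort$trials[cohort$trials$condition == "health", ]
  ctl <- fit_control(n_starts = 1, maxit = 300, min_trials = 25, seed = 2)
  ts <- fit_hierarchical(tr, mode = "two_stage", control = ctl)
  mc <- suppressWarnings(
    fit_hierarchical(tr, mode = "mcmc", control = ctl,
                     mcmc = mcmc_control(n_iter = 1200, burn = 600, seed = 3)))
  g_ts <- setNames(ts$group$mean, ts$group$parameter)
  g_mc <- setNames(mc$group$mean, mc$group$parameter)
  for (pn in c("w_taste", "w_health", "ndt", "noise")) {
    expect_lt(abs(g_ts[[pn]] - g_mc[[pn]]), 0.1)
  }
  expect_true(all(c("rhat", "ess") %in% names(mc$diagnostics)))
})

test_that("a weakly identified weight triggers the RST identifiability warning", {
  # cohort whose health weight is essentially zero: RST cannot be pinned down
  gp <- reference_group_params()
  gp$mean[gp$parameter == "w_health" & gp$condition == "natural"] <- 0
  gp$sd[gp$parameter == "w_health" & gp$condition == "natural"] <- 0.05
  cohort <- make_cohort(5, sessions = 1, seed = 71, n_items = 80,
                        group_params = gp)
  tr <- cohort$trials[cohort$trials$condition == "natural", ]
  expect_warning(
    fit_hierarchical(tr, mode = "two_stage",
                     control = fit_control(n_starts = 1, maxit = 300,
                                           seed = 4)),
    "weakly identified")
})

test_that("recovery_study tabulates bias, RMSE and coverage per parameter", {
  rs <- recovery_study(n_reps = 1, n_subjects = 3, n_trials = 150,
                       seed = 81,
                       control = fit_control(n_starts = 1, maxit = 250,
                                             min_trials = 20))
  expect_setequal(rs$report$parameter,
                  c("noise", "sp_bias", "ndt", "rst", "w_taste", "w_health",
                    "drift_bias"))
  expect_true(all(is.finite(rs$report$rmse)))
  expect_true(all(rs$report$coverage >= 0 & rs$report$coverage <= 1))
  expect_equal(nrow(rs$estimates), 3 * 7)
})
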