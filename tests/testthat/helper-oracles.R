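# Independent oracles used across the test files.

# Large-time series solution for the first-passage density of a constant-drift
# diffusion with absorbing bounds at -1/+1 (classical eigenfunction expansion,
# written for bounds [0, a] and mapped). Independent of the package's
# finite-difference solver.
fpt_series_lower <- function(t, v, sigma = 1, sp_bias = 0.5, n_terms = 200) {
  a <- 2
  z <- 2 * sp_bias          # start measured from the lower bound
  s2 <- sigma^2
  k <- seq_len(n_terms)
  sapply(t, function(tt) {
    (pi * s2 / a^2) * exp(-v * z / s2 - v^2 * tt / (2 * s2)) *
      sum(k * sin(pi * k * z / a) * exp(-k^2 * pi^2 * s2 * tt / (2 * a^2)))
  })
}

fpt_series_upper <- function(t, v, sigma = 1, sp_bias = 0.5, n_terms = 200) {
  # reflect: upper-bound density equals lower-bound density of the mirrored
  # process (drift -v, start 1 - sp_bias)
  fpt_series_lower(t, -v, sigma, 1 - sp_bias, n_terms)
}

# Brute-force ICC(A,1) from an explicit aov() two-way decomposition; the
# McGraw & Wong algebra is written out independently of icc_a1().
icc_a1_brute <- function(m, conf_level = 0.95) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  row = factor(rep(seq_len(n), times = k)),
                  col = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ row + col, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf_level
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  list(estimate = est,
       f_value = msr / mse,
       df2 = v,
       ci_low = n * (msr - fl * mse) /
         (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
       ci_high = n * (fu * msr - mse) /
         (k * msc + (k * n - k - n) * mse + n * fu * msr))
}

# quick trial fixture: simulate n trials of one subject at given parameters,
# with rating-difference-like attribute values
make_trials <- function(params, n, seed = 1, attr_sd = 3) {
  withr::with_seed(seed, {
    td <- pmin(pmax(rnorm(n, 0, attr_sd), -10), 10)
    hd <- pmin(pmax(rnorm(n, 0, attr_sd), -10), 10)
    sim <- simulate_trials(params, td, hd)
    data.frame(td_lr = td, hd_lr = hd, chose_left = sim$chose_left,
               rt = sim$rt, censored = sim$censored)
  })
}

# small study-shaped cohort (items -> ratings -> designs -> trials)
make_cohort <- function(n_subjects, sessions = 1, seed = 1, n_items = 120,
                        n_trials = 210, group_params = reference_group_params(),
                        stable = TRUE) {
  items <- gen_items(n_items, seed = seed)
  ratings <- gen_ratings(items, n_subjects, sessions = unique(c(1, sessions)),
                         seed = seed + 1)
  designs <- lapply(seq_len(n_subjects), function(s)
    build_design(ratings, subject = s, n_trials = n_trials,
                 seed = seed + 100 + s))
  truth <- draw_subject_params(n_subjects, group_params = group_params,
                               sessions = sessions, stable = stable,
                               seed = seed + 2)
  ds <- suppressMessages(
    simulate_dataset(designs, truth, sessions = sessions, seed = seed + 3))
  list(items = items, ratings = ratings, designs = designs, truth = truth,
       trials = ds$trials)
}
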