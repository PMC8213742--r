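#' Optimizer / likelihood settings for rstDDM fitting
#'
#' @param n_starts Number of optimizer starts (first from the heuristic or
#'   user init, the rest jittered).
#' @param maxit Nelder-Mead iteration cap per start.
#' @param jitter_sd Jitter sd on the transformed scale for extra starts.
#' @param min_trials Minimum usable (non-censored) trials per fit.
#' @param dt,dx Likelihood solver steps (seconds, evidence units).
#' @param eps Per-trial density floor.
#' @param seed Optional seed for the start jitter.
#' @return A list of control settings.
#' @export
fit_control <- function(n_starts = 3, maxit = 500, jitter_sd = 0.4,
                        min_trials = 30, dt = 0.005, dx = 0.02, eps = 1e-10,
                        seed = NULL) {
  list(n_starts = n_starts, maxit = maxit, jitter_sd = jitter_sd,
       min_trials = min_trials, dt = dt, dx = dx, eps = eps, seed = seed)
}

# --- parameter transforms (unconstrained optimizer scale <-> natural) -------
# theta: log(noise), qlogis(sp_bias), qlogis(ndt/ndt_max), rst, w_taste,
# w_health, drift_bias. ndt_max sits just below the minimum observed RT so
# the likelihood stays defined.
theta_to_params <- function(theta, ndt_max, model = "rst") {
  rst <- if (model == "standard") 0 else theta[4]
  rst_params(noise = exp(theta[1]),
             sp_bias = plogis(theta[2]),
             ndt = ndt_max * plogis(theta[3]),
             rst = rst,
             w_taste = theta[5], w_health = theta[6], drift_bias = theta[7])
}

params_to_theta <- function(p, ndt_max) {
  c(log(p$noise), qlogis(p$sp_bias),
    qlogis(min(max(p$ndt / ndt_max, 1e-6), 1 - 1e-6)),
    p$rst, p$w_taste, p$w_health, p$drift_bias)
}

# derivative of natural = g(theta) per component, for delta-method SEs
theta_jacobian <- function(theta, ndt_max) {
  sp <- plogis(theta[2]); q <- plogis(theta[3])
  c(exp(theta[1]), sp * (1 - sp), ndt_max * q * (1 - q), 1, 1, 1, 1)
}

usable_trials <- function(trials) {
  need <- c("td_lr", "hd_lr", "chose_left", "rt")
  if (!all(need %in% names(trials)))
    stop("'trials' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  trials[!is.na(trials$rt) & !is.na(trials$chose_left), , drop = FALSE]
}

# heuristic start: logistic regression of choice on attribute differences
# approximates the drift weights (P(left) is logistic in 2*drift/noise^2 for
# the standard DDM), noise 1, midpoint start, NDT below the minimum RT.
default_init <- function(trials, ndt_max) {
  w <- c(td = 0.3, hd = 0.3, b0 = 0)
  fit <- tryCatch(
    stats::glm(chose_left ~ td_lr + hd_lr, data = trials, family = binomial()),
    error = function(e) NULL, warning = function(w) suppressWarnings(
      stats::glm(chose_left ~ td_lr + hd_lr, data = trials,
                 family = binomial())))
  if (!is.null(fit)) {
    cf <- coef(fit)
    w <- c(td = unname(cf["td_lr"]) / 2, hd = unname(cf["hd_lr"]) / 2,
           b0 = unname(cf["(Intercept)"]) / 2)
    w[!is.finite(w)] <- 0
    w <- pmin(pmax(w, -3), 3)
  }
  rst_params(noise = 1, sp_bias = 0.5,
             ndt = min(0.8 * ndt_max, 0.55),
             rst = 0, w_taste = w[["td"]], w_health = w[["hd"]],
             drift_bias = w[["b0"]])
}

#' Fit the rstDDM (or standard DDM) to one subject's trials
#'
#' Maximum-likelihood fit on transformed parameters (log noise, logit start
#' point, logit-scaled NDT bounded just below the minimum observed RT,
#' unbounded RST / weights / bias) via multi-start Nelder-Mead. Standard-DDM
#' fits constrain \code{rst = 0}. Curvature-based standard errors come from
#' the numerical Hessian at the optimum, delta-method-transformed to the
#' natural scale.
#'
#' @param trials Trial data.frame (\code{td_lr}, \code{hd_lr},
#'   \code{chose_left}, \code{rt}, optional \code{censored}).
#' @param model \code{"rst"} (7 free parameters) or \code{"standard"}
#'   (\code{rst} fixed at 0).
#' @param init Optional \code{rst_params} starting point.
#' @param control See \code{\link{fit_control}}.
#' @return An object of class \code{rst_fit}: estimates and SEs per
#'   parameter, log-likelihood, convergence info.
#' @export
fit_subject <- function(trials, model = c("rst", "standard"), init = NULL,
                        control = fit_control()) {
  model <- match.arg(model)
  trials <- usable_trials(trials)
  if (nrow(trials) < control$min_trials)
    stop("only ", nrow(trials), " usable trials; minimum is ",
         control$min_trials, call. = FALSE)
  ndt_max <- min(trials$rt) - 1e-3
  if (ndt_max <= 0) stop("minimum RT too small to fit an NDT", call. = FALSE)

  nll <- function(theta) {
    p <- tryCatch(theta_to_params(theta, ndt_max, model),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- rst_loglik(p, trials, eps = control$eps, dt = control$dt,
                     dx = control$dx)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  p0 <- if (is.null(init)) default_init(trials, ndt_max) else init
  th0 <- params_to_theta(p0, ndt_max)
  starts <- list(th0)
  if (control$n_starts > 1) {
    jit <- function() th0 + rnorm(length(th0), 0, control$jitter_sd)
    extra <- if (is.null(control$seed)) {
      replicate(control$n_starts - 1, jit(), simplify = FALSE)
    } else {
      withr::with_seed(control$seed,
        replicate(control$n_starts - 1, jit(), simplify = FALSE))
    }
    starts <- c(starts, extra)
  }

  best <- NULL
  fails <- character()
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, method = "Nelder-Mead",
            control = list(maxit = control$maxit, reltol = 1e-7)),
      error = function(e) e)
    if (inherits(o, "error")) { fails <- c(fails, conditionMessage(o)); next }
    if (o$value >= 1e10) { fails <- c(fails, "non-finite likelihood"); next }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all optimizer starts failed: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)

  theta <- best$par
  est <- theta_to_params(theta, ndt_max, model)
  se <- rep(NA_real_, 7)
  hess <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  if (!is.null(hess)) {
    free <- if (model == "standard") c(1:3, 5:7) else 1:7
    vc <- tryCatch(solve(hess[free, free]), error = function(e) NULL)
    if (!is.null(vc)) {
      d <- diag(vc)
      d[d < 0] <- NA
      se_theta <- rep(NA_real_, 7)
      se_theta[free] <- sqrt(d)
      se <- se_theta * theta_jacobian(theta, ndt_max)
    }
  }
  if (model == "standard") se[4] <- 0
  names(se) <- par_names
  structure(list(params = est,
                 estimates = setNames(unlist(est)[par_names], par_names),
                 se = se, loglik = -best$value,
                 convergence = best$convergence, model = model,
                 n_trials = nrow(trials), ndt_max = ndt_max,
                 theta = theta, n_failed_starts = length(fails)),
            class = "rst_fit")
}

#' @export
print.rst_fit <- function(x, ...) {
  cat(sprintf("%s-DDM fit: %d trials, logLik = %.2f, convergence = %d\n",
              x$model, x$n_trials, x$loglik, x$convergence))
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

warn_rst_identifiability <- function(group) {
  w <- group[group$parameter %in% c("w_taste", "w_health"), ]
  covers0 <- w$ci_low <= 0 & w$ci_high >= 0
  if (any(covers0))
    warning("group-level 95% interval for ",
            paste(w$parameter[covers0], collapse = " and "),
            " covers 0: the RST estimate is weakly identified in this regime",
            call. = FALSE)
}

#' Hierarchical rstDDM estimation across subjects
#'
#' Fits the model per subject and pools across the cohort. The default
#' two-stage mode takes each subject's penalized-free MLE and summarizes the
#' cohort by moments (group mean, between-subject sd, SE of the mean). The
#' \code{"mcmc"} mode runs a Metropolis-within-Gibbs sampler with normal
#' group priors over the transformed parameters (group mean and sd estimated
#' jointly with the subject parameters); its group summaries are posterior
#' means of the cohort-average natural-scale parameters, directly comparable
#' to the two-stage summaries. When the fitted model is the rstDDM and a
#' group-level drift weight's 95% interval covers zero, a warning flags that
#' the RST parameter is weakly identified.
#'
#' @param trials Trial table including a \code{subject_id} column.
#' @param model \code{"rst"} or \code{"standard"}.
#' @param mode \code{"two_stage"} (default) or \code{"mcmc"}.
#' @param control Subject-fit settings (\code{\link{fit_control}}).
#' @param mcmc MCMC settings (\code{\link{mcmc_control}}).
#' @return An object of class \code{rst_hfit}: \code{group} (parameter, mean,
#'   se, sd, ci_low, ci_high), \code{subjects} (per-subject estimates and
#'   SEs), \code{mode}, \code{diagnostics}.
#' @export
fit_hierarchical <- function(trials, model = c("rst", "standard"),
                             mode = c("two_stage", "mcmc"),
                             control = fit_control(),
                             mcmc = mcmc_control()) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  ids <- unique(trials$subject_id)
  if (length(ids) < 5)
    stop("hierarchical fitting needs at least 5 subjects", call. = FALSE)
  if (mode == "two_stage")
    fit_two_stage(trials, ids, model, control)
  else
    fit_mcmc(trials, ids, model, control, mcmc)
}

fit_two_stage <- function(trials, ids, model, control) {
  fits <- lapply(ids, function(s) {
    fit_subject(trials[trials$subject_id == s, , drop = FALSE], model = model,
                control = control)
  })
  est <- t(sapply(fits, function(f) f$estimates))
  ses <- t(sapply(fits, function(f) f$se))
  n <- length(ids)
  group <- data.frame(
    parameter = par_names,
    mean = colMeans(est),
    sd = apply(est, 2, sd),
    se = apply(est, 2, sd) / sqrt(n)
  )
  group$ci_low <- group$mean - qnorm(0.975) * group$se
  group$ci_high <- group$mean + qnorm(0.975) * group$se
  rownames(group) <- NULL
  subjects <- data.frame(
    subject_id = rep(ids, each = length(par_names)),
    parameter = rep(par_names, times = n),
    estimate = as.vector(t(est)),
    se = as.vector(t(ses))
  )
  if (model == "rst") warn_rst_identifiability(group)
  structure(list(group = group, subjects = subjects, mode = "two_stage",
                 model = model,
                 diagnostics = list(
                   convergence = sapply(fits, `[[`, "convergence"),
                   n_trials = sapply(fits, `[[`, "n_trials"))),
            class = "rst_hfit")
}

#' MCMC settings for hierarchical fitting
#'
#' @param n_iter Total iterations (including burn-in).
#' @param burn Burn-in iterations (adaptive proposal scaling happens here).
#' @param prior_mu_sd Prior sd of the group means on the transformed scale.
#' @param prior_tau_shape,prior_tau_rate Inverse-gamma prior on the group
#'   variances.
#' @param rhat_max,min_ess Convergence thresholds; exceeding them flags (but
#'   does not discard) the result.
#' @param seed Optional seed.
#' @return A list of settings.
#' @export
mcmc_control <- function(n_iter = 1500, burn = 700, prior_mu_sd = 5,
                         prior_tau_shape = 2, prior_tau_rate = 0.1,
                         rhat_max = 1.01, min_ess = 400, seed = NULL) {
  list(n_iter = n_iter, burn = burn, prior_mu_sd = prior_mu_sd,
       prior_tau_shape = prior_tau_shape, prior_tau_rate = prior_tau_rate,
       rhat_max = rhat_max, min_ess = min_ess, seed = seed)
}

split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4) return(NA_real_)
  ch <- list(x[1:n], x[(n + 1):(2 * n)])
  w <- mean(sapply(ch, var))
  b <- n * var(sapply(ch, mean))
  if (w <= 0) return(1)
  sqrt((n - 1) / n + b / (w * n))
}

ess_crude <- function(x) {
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(50, n - 2), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) { if (r < 0.05) break; s <- s + r }
  n / (1 + 2 * s)
}

fit_mcmc <- function(trials, ids, model, control, mcmc) {
  S <- length(ids)
  sub <- lapply(ids, function(s) usable_trials(
    trials[trials$subject_id == s, , drop = FALSE]))
  ndt_max <- sapply(sub, function(d) min(d$rt) - 1e-3)
  free <- if (model == "standard") c(1:3, 5:7) else 1:7
  # initialize at quick single-start subject fits
  init_control <- modifyList(control, list(n_starts = 1, maxit = 300))
  theta0 <- t(sapply(seq_len(S), function(i) {
    f <- fit_subject(sub[[i]], model = model, control = init_control)
    f$theta
  }))
  run <- function() {
    theta <- theta0
    mu <- colMeans(theta)
    tau2 <- pmax(apply(theta, 2, var), 0.01)
    ll <- sapply(seq_len(S), function(i)
      -rst_loglik(theta_to_params(theta[i, ], ndt_max[i], model), sub[[i]],
                  eps = control$eps, dt = control$dt, dx = control$dx) * -1)
    prop_scale <- rep(0.15, S)
    n_keep <- mcmc$n_iter - mcmc$burn
    mu_draws <- matrix(NA_real_, n_keep, 7)
    nat_draws <- matrix(NA_real_, n_keep, 7)
    acc <- rep(0, S)
    base_sd <- pmax(sqrt(tau2), 0.05)
    for (it in seq_len(mcmc$n_iter)) {
      for (i in seq_len(S)) {
        prop <- theta[i, ]
        prop[free] <- prop[free] + rnorm(length(free), 0,
                                         prop_scale[i] * base_sd[free])
        p <- tryCatch(theta_to_params(prop, ndt_max[i], model),
                      error = function(e) NULL)
        if (is.null(p)) next
        ll_new <- rst_loglik(p, sub[[i]], eps = control$eps, dt = control$dt,
                             dx = control$dx)
        if (!is.finite(ll_new)) next
        lpost_new <- ll_new - sum((prop[free] - mu[free])^2 / (2 * tau2[free]))
        lpost_old <- ll[i] - sum((theta[i, free] - mu[free])^2 /
                                   (2 * tau2[free]))
        if (log(runif(1)) < lpost_new - lpost_old) {
          theta[i, ] <- prop
          ll[i] <- ll_new
          acc[i] <- acc[i] + 1
        }
      }
      if (it <= mcmc$burn && it %% 25 == 0) {
        rate <- acc / it
        prop_scale <- prop_scale * exp(0.5 * (rate - 0.25))
        prop_scale <- pmin(pmax(prop_scale, 0.01), 2)
      }
      # conjugate group updates on the free components
      for (j in free) {
        prec <- S / tau2[j] + 1 / mcmc$prior_mu_sd^2
        m <- (sum(theta[, j]) / tau2[j]) / prec
        mu[j] <- rnorm(1, m, sqrt(1 / prec))
        a <- mcmc$prior_tau_shape + S / 2
        b <- mcmc$prior_tau_rate + sum((theta[, j] - mu[j])^2) / 2
        tau2[j] <- 1 / stats::rgamma(1, a, rate = b)
      }
      if (it > mcmc$burn) {
        k <- it - mcmc$burn
        mu_draws[k, ] <- mu
        nat <- sapply(seq_len(S), function(i)
          unlist(theta_to_params(theta[i, ], ndt_max[i], model))[par_names])
        nat_draws[k, ] <- rowMeans(nat)
      }
    }
    list(mu_draws = mu_draws, nat_draws = nat_draws,
         acc_rate = acc / mcmc$n_iter)
  }
  res <- if (is.null(mcmc$seed)) run() else withr::with_seed(mcmc$seed, run())
  gmean <- colMeans(res$nat_draws)
  gse <- apply(res$nat_draws, 2, sd)
  ci <- apply(res$nat_draws, 2, quantile, probs = c(0.025, 0.975))
  group <- data.frame(parameter = par_names, mean = gmean, sd = NA_real_,
                      se = gse, ci_low = ci[1, ], ci_high = ci[2, ])
  rownames(group) <- NULL
  rhat <- apply(res$nat_draws, 2, split_rhat)
  ess <- apply(res$nat_draws, 2, ess_crude)
  converged <- all(rhat[is.finite(rhat)] < mcmc$rhat_max) &&
    all(ess >= mcmc$min_ess)
  if (!converged)
    warning("MCMC convergence diagnostics outside thresholds (max split-Rhat ",
            round(max(rhat, na.rm = TRUE), 3), ", min ESS ",
            round(min(ess)), "); result flagged", call. = FALSE)
  if (model == "rst") warn_rst_identifiability(group)
  structure(list(group = group, subjects = NULL, mode = "mcmc", model = model,
                 diagnostics = list(rhat = setNames(rhat, par_names),
                                    ess = setNames(ess, par_names),
                                    acceptance = res$acc_rate,
                                    converged = converged)),
            class = "rst_hfit")
}

#' @export
print.rst_hfit <- function(x, ...) {
  cat(sprintf("hierarchical %s-DDM fit (%s mode)\n", x$model, x$mode))
  print(transform(x$group, mean = round(mean, 4), se = round(se, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4),
                  sd = round(sd, 4)))
  invisible(x)
}

#' Parameter-recovery study
#'
#' Repeatedly simulates cohorts at known parameters, refits each subject, and
#' tabulates bias, RMSE, and 95% interval coverage per parameter. Attribute
#' differences are drawn to resemble rating differences between two foods.
#'
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param n_subjects Subjects per cohort.
#' @param n_trials Trials per subject.
#' @param group_means Named list/vector of generative group means (parameter
#'   names as in \code{\link{rst_params}}).
#' @param subject_sd Named vector of between-subject sds (0 = all subjects at
#'   the group mean).
#' @param model Fitted model.
#' @param attr_sd sd of simulated attribute differences (rating units).
#' @param seed Seed (local).
#' @param control Fit settings.
#' @return A list: \code{report} (parameter, bias, rmse, coverage,
#'   flagged_weight_rate) and \code{estimates} (per rep/subject tidy table).
#' @export
recovery_study <- function(n_reps, n_subjects = 10, n_trials = 200,
                           group_means = list(noise = 1, sp_bias = 0.5,
                                              ndt = 0.6, rst = 0.1,
                                              w_taste = 0.9, w_health = 0.5,
                                              drift_bias = 0),
                           subject_sd = NULL, model = "rst", attr_sd = 3,
                           seed = NULL, control = fit_control()) {
  stopifnot(n_reps >= 1)
  if (is.null(subject_sd))
    subject_sd <- setNames(rep(0, 7), par_names)
  run <- function() {
    rows <- list()
    for (rep_i in seq_len(n_reps)) {
      for (s in seq_len(n_subjects)) {
        truth <- sapply(par_names, function(pn)
          group_means[[pn]] + rnorm(1, 0, subject_sd[[pn]]))
        truth["noise"] <- max(truth["noise"], 0.3)
        truth["sp_bias"] <- min(max(truth["sp_bias"], 0.2), 0.8)
        truth["ndt"] <- max(truth["ndt"], 0.2)
        p <- do.call(rst_params, as.list(truth))
        td <- pmin(pmax(rnorm(n_trials, 0, attr_sd), -10), 10)
        hd <- pmin(pmax(rnorm(n_trials, 0, attr_sd), -10), 10)
        sim <- simulate_trials(p, td, hd)
        trials <- data.frame(td_lr = td, hd_lr = hd,
                             chose_left = sim$chose_left, rt = sim$rt,
                             censored = sim$censored)
        f <- tryCatch(fit_subject(trials, model = model, control = control),
                      error = function(e) NULL)
        if (is.null(f)) next
        w_flag <- any((f$estimates[c("w_taste", "w_health")] -
                         1.96 * f$se[c("w_taste", "w_health")]) <= 0 &
                        (f$estimates[c("w_taste", "w_health")] +
                           1.96 * f$se[c("w_taste", "w_health")]) >= 0,
                      na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          rep = rep_i, subject = s, parameter = par_names,
          truth = unname(truth[par_names]),
          estimate = unname(f$estimates[par_names]),
          se = unname(f$se[par_names]), weight_flagged = w_flag)
      }
    }
    do.call(rbind, rows)
  }
  est <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  err <- est$estimate - est$truth
  cover <- abs(err) <= 1.96 * est$se
  report <- do.call(rbind, lapply(split(seq_len(nrow(est)), est$parameter),
    function(ix) data.frame(
      parameter = est$parameter[ix[1]],
      bias = mean(err[ix]),
      rmse = sqrt(mean(err[ix]^2)),
      coverage = mean(cover[ix], na.rm = TRUE),
      flagged_weight_rate = mean(est$weight_flagged[ix]))))
  rownames(report) <- NULL
  list(report = report, estimates = est)
}
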