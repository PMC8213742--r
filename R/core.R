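#' Instantaneous drift rate of the rstDDM
#'
#' The drift is \code{drift_bias + w_taste * td_lr * [t >= onset_taste] +
#' w_health * hd_lr * [t >= onset_health]}, where onsets are measured within
#' decision time (after the non-decision time): the earlier attribute starts
#' at 0 and the later one at \code{|rst|}; the sign of \code{rst} selects
#' which attribute is the later one.
#'
#' @param params An \code{\link{rst_params}} object.
#' @param td_lr,hd_lr Left-minus-right taste and health rating differences.
#' @param t Time(s) since accumulation onset, seconds (>= 0).
#' @return Numeric vector of drift rates, one per element of \code{t}.
#' @export
drift_at <- function(params, td_lr, hd_lr, t) {
  stopifnot(inherits(params, "rst_params"), all(is.finite(t)), all(t >= 0))
  cpp_drift_at(par_vec(params), td_lr, hd_lr, as.numeric(t))
}

#' Simulate rstDDM trials
#'
#' Forward-simulates the accumulator with an Euler scheme whose Gaussian
#' transitions are exact under the model's piecewise-constant drift, plus a
#' Brownian-bridge correction for within-step boundary crossings. The upper
#' bound (+1) codes choosing the left option. Trials whose first passage plus
#' non-decision time exceeds \code{deadline} are returned censored with
#' \code{NA} choice and RT.
#'
#' @inheritParams drift_at
#' @param td_lr,hd_lr Numeric vectors (recycled to a common length): one trial
#'   is simulated per element.
#' @param dt Simulation step, seconds (> 0).
#' @param deadline Response deadline, seconds; must exceed \code{ndt}.
#' @param seed Optional integer seed (local to this call).
#' @return A data.frame with columns \code{chose_left}, \code{rt},
#'   \code{censored}.
#' @examples
#' p <- rst_params(w_taste = 0.9, ndt = 0.6)
#' simulate_trials(p, td_lr = c(2, -2), hd_lr = c(0, 0), seed = 1)
#' @export
simulate_trials <- function(params, td_lr, hd_lr, dt = 0.002, deadline = 3,
                            seed = NULL) {
  stopifnot(inherits(params, "rst_params"))
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (deadline <= params$ndt)
    stop("'deadline' must exceed the non-decision time", call. = FALSE)
  n <- max(length(td_lr), length(hd_lr))
  td_lr <- rep_len(as.numeric(td_lr), n)
  hd_lr <- rep_len(as.numeric(hd_lr), n)
  if (any(!is.finite(td_lr)) || any(!is.finite(hd_lr)))
    stop("attribute differences must be finite", call. = FALSE)
  run <- function() cpp_simulate_trials(par_vec(params), td_lr, hd_lr, dt,
                                        deadline)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  data.frame(chose_left = out$chose_left, rt = out$rt,
             censored = out$censored == 1L)
}

#' @rdname simulate_trials
#' @return \code{simulate_trial}: a one-row list with elements
#'   \code{chose_left}, \code{rt}, \code{censored}.
#' @export
simulate_trial <- function(params, td_lr, hd_lr, dt = 0.002, deadline = 3,
                           seed = NULL) {
  stopifnot(length(td_lr) == 1L, length(hd_lr) == 1L)
  df <- simulate_trials(params, td_lr, hd_lr, dt, deadline, seed)
  list(chose_left = df$chose_left[1], rt = df$rt[1], censored = df$censored[1])
}

#' First-passage-time density of the rstDDM
#'
#' Solves the forward Kolmogorov (Fokker-Planck) equation on \code{[-1, 1]}
#' with absorbing bounds by Crank-Nicolson finite differences (Rannacher
#' start to damp the delta initial condition; the drift switch at
#' \code{|rst|} falls on a sub-step boundary). Per time step the absorbed
#' mass is taken from the exact discrete mass balance and split between the
#' bounds in proportion to the one-sided diffusive boundary fluxes, so
#' absorbed + surviving mass equals 1 to round-off by construction; accuracy
#' of the split and of the time course is validated against simulation.
#'
#' @inheritParams drift_at
#' @param t_grid Strictly increasing vector of decision times (seconds since
#'   accumulation onset, i.e. excluding NDT) at which to return the density.
#' @param dt,dx Solver steps in time (s) and evidence space. Defaults give
#'   densities accurate to a few times 1e-2 sup-norm (peak densities near
#'   1.5) against large-n simulation; halve both for tighter agreement.
#' @return A data.frame with columns \code{t}, \code{upper}, \code{lower}
#'   (sub-probability densities of absorbing at +1 / -1 at decision time t)
#'   and attribute \code{survival}: the un-absorbed mass at
#'   \code{max(t_grid)}.
#' @export
fpt_density <- function(params, td_lr, hd_lr, t_grid, dt = 0.005, dx = 0.02) {
  stopifnot(inherits(params, "rst_params"))
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1 || any(!is.finite(t_grid)) || any(t_grid <= 0) ||
      is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing and positive", call. = FALSE)
  if (dt <= 0 || dx <= 0) stop("solver steps must be positive", call. = FALSE)
  if (dx > 0.25)
    stop("evidence grid too coarse: require dx <= 0.25 so that the ",
         "absorbing-boundary flux stencil has interior support", call. = FALSE)
  sol <- cpp_fpt_solve(par_vec(params), td_lr, hd_lr, max(t_grid), dt, dx)
  interp <- function(g) {
    stats::approx(x = c(0, sol$t), y = c(0, g), xout = t_grid, rule = 2)$y
  }
  out <- data.frame(t = t_grid, upper = interp(sol$upper),
                    lower = interp(sol$lower))
  attr(out, "survival") <- sol$survival[length(sol$survival)]
  out
}

#' Trial-wise log-likelihood of the rstDDM
#'
#' Sums the log first-passage density at (chosen boundary, rt - ndt) over the
#' non-censored trials, with the per-trial density floored at \code{eps} to
#' keep outlier RTs from producing -Inf. Censored trials are excluded by
#' default; \code{censoring = "truncate"} instead conditions each trial's
#' density on a response occurring before the deadline.
#'
#' @inheritParams fpt_density
#' @param trials A data.frame with columns \code{td_lr}, \code{hd_lr},
#'   \code{chose_left} (0/1), \code{rt} (seconds) and optionally
#'   \code{censored}.
#' @param eps Per-trial density floor.
#' @param censoring Either \code{"exclude"} (drop censored trials) or
#'   \code{"truncate"} (renormalize by the absorbed mass before the
#'   deadline).
#' @param deadline Response deadline in seconds (used by
#'   \code{censoring = "truncate"}).
#' @return The log-likelihood (scalar). An empty trial set (after exclusion)
#'   returns 0 with a warning.
#' @export
rst_loglik <- function(params, trials, eps = 1e-10,
                       censoring = c("exclude", "truncate"), deadline = 3,
                       dt = 0.005, dx = 0.02) {
  stopifnot(inherits(params, "rst_params"))
  censoring <- match.arg(censoring)
  need <- c("td_lr", "hd_lr", "chose_left", "rt")
  if (!all(need %in% names(trials)))
    stop("'trials' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, , drop = FALSE]
  trials <- trials[!is.na(trials$rt) & !is.na(trials$chose_left), , drop = FALSE]
  if (nrow(trials) == 0L) {
    warning("no usable trials after censoring exclusion; returning 0")
    return(0)
  }
  bad <- which(trials$rt <= params$ndt)
  if (length(bad))
    stop("rt <= ndt for trial(s) ", paste(head(bad, 5), collapse = ", "),
         ": non-decision time exceeds an observed RT", call. = FALSE)
  cpp_loglik(par_vec(params), trials$td_lr, trials$hd_lr,
             as.integer(trials$chose_left), trials$rt, deadline, dt, dx, eps,
             censoring == "truncate")
}

#' Closed-form constant-drift DDM choice probability and mean decision time
#'
#' Analytic results for a diffusion with constant drift \code{v}, noise
#' \code{sigma}, absorbing bounds at -1 and +1, and start point
#' \code{2 * sp_bias - 1}. These are the rstDDM with \code{rst = 0} and serve
#' as independent oracles for the simulator and solver.
#'
#' @param v Drift rate (a.u./s).
#' @param sigma Diffusion standard deviation (> 0).
#' @param sp_bias Starting point on (0, 1); 0.5 = midpoint.
#' @return \code{ddm_choice_prob}: probability of absorbing at the upper
#'   (+1) bound. \code{ddm_mean_dt}: unconditional mean decision time in
#'   seconds (excluding NDT).
#' @export
ddm_choice_prob <- function(v, sigma = 1, sp_bias = 0.5) {
  stopifnot(sigma > 0, sp_bias > 0, sp_bias < 1)
  z <- 2 * sp_bias            # start measured from the lower bound; span a = 2
  k <- 2 * v / sigma^2
  ifelse(abs(k) < 1e-10,
         z / 2,
         expm1(-k * z) / expm1(-k * 2))
}

#' @rdname ddm_choice_prob
#' @export
ddm_mean_dt <- function(v, sigma = 1, sp_bias = 0.5) {
  stopifnot(sigma > 0, sp_bias > 0, sp_bias < 1)
  z <- 2 * sp_bias
  a <- 2
  if (abs(v) < 1e-8) return(z * (a - z) / sigma^2)
  k <- 2 * v / sigma^2
  (a / v) * expm1(-k * z) / expm1(-k * a) - z / v
}
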