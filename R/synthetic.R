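#' Reference group-level rstDDM parameters for the cued-attribute task
#'
#' Group-level parameter estimates (mean and between-subject spread) for the
#' five-session cued-attribute food-choice study, by condition and session.
#' These are the generative values used throughout the synthetic study and the
#' recovery analyses. The \code{sd} column is the between-subject spread used
#' when drawing synthetic cohorts; it corresponds to the published dispersion
#' of the subject-level estimates (the published group-mean HDIs are roughly
#' \code{sd / sqrt(23)} wide, consistent with this reading).
#'
#' @return A data.frame with columns \code{condition} (\code{"natural"} or
#'   \code{"health"}), \code{session} (1-5), \code{parameter}, \code{mean},
#'   \code{sd}.
#' @export
reference_group_params <- function() {
  g <- function(condition, parameter, means, sds) {
    data.frame(condition = condition, session = 1:5, parameter = parameter,
               mean = means, sd = sds)
  }
  rbind(
    g("natural", "drift_bias", c(0.02, -0.03, 0.02, 0.08, -0.03),
      c(0.08, 0.10, 0.11, 0.17, 0.13)),
    g("natural", "w_health", c(-0.13, 0.05, 0.03, -0.01, 0.00),
      c(0.31, 0.48, 0.47, 0.62, 0.49)),
    g("natural", "w_taste", c(0.89, 0.69, 0.73, 0.72, 0.87),
      c(0.48, 0.28, 0.31, 0.39, 0.49)),
    g("natural", "rst", c(0.18, 0.14, 0.02, 0.04, 0.10),
      c(0.08, 0.13, 0.02, 0.03, 0.06)),
    g("natural", "ndt", c(0.60, 0.59, 0.58, 0.54, 0.55),
      c(0.16, 0.09, 0.15, 0.11, 0.09)),
    g("natural", "sp_bias", c(0.49, 0.50, 0.50, 0.48, 0.50),
      c(0.03, 0.04, 0.03, 0.04, 0.04)),
    g("natural", "noise", c(1.02, 1.02, 1.08, 1.08, 1.09),
      c(0.13, 0.14, 0.13, 0.16, 0.12)),
    g("health", "drift_bias", c(0.05, 0.07, 0.01, 0.08, -0.05),
      c(0.07, 0.13, 0.12, 0.07, 0.09)),
    g("health", "w_health", c(0.90, 0.82, 0.80, 0.68, 0.80),
      c(0.46, 0.55, 0.50, 0.65, 0.63)),
    g("health", "w_taste", c(0.32, 0.29, 0.30, 0.33, 0.32),
      c(0.32, 0.23, 0.29, 0.31, 0.44)),
    g("health", "rst", c(-0.03, -0.04, -0.03, -0.02, -0.05),
      c(0.02, 0.02, 0.03, 0.02, 0.04)),
    g("health", "ndt", c(0.59, 0.57, 0.53, 0.54, 0.52),
      c(0.13, 0.10, 0.15, 0.10, 0.10)),
    g("health", "sp_bias", c(0.49, 0.48, 0.49, 0.48, 0.51),
      c(0.03, 0.04, 0.04, 0.04, 0.04)),
    g("health", "noise", c(0.98, 1.01, 1.00, 1.08, 1.03),
      c(0.13, 0.12, 0.09, 0.12, 0.13))
  )
}

#' Generate latent item attributes
#'
#' Stands in for the study's 180-image food stimulus set: each item carries a
#' latent taste and health value on the -5..+5 rating scale, drawn from a
#' bivariate normal (values clipped to the scale). A mildly negative
#' taste-health correlation makes taste/health conflicts common, as in
#' realistic snack-food sets.
#'
#' @param n_items Number of items (>= 2).
#' @param seed Optional integer seed (local to this call).
#' @param taste_health_cor Latent correlation between taste and health.
#' @param latent_sd Latent standard deviation on the rating scale.
#' @return A data.frame with columns \code{item_id}, \code{latent_taste},
#'   \code{latent_health}.
#' @export
gen_items <- function(n_items, seed = NULL, taste_health_cor = -0.3,
                      latent_sd = 2.2) {
  if (!is.numeric(n_items) || n_items < 2)
    stop("invalid design: 'n_items' must be >= 2", call. = FALSE)
  stopifnot(abs(taste_health_cor) <= 1, latent_sd > 0)
  run <- function() {
    z1 <- rnorm(n_items)
    z2 <- taste_health_cor * z1 +
      sqrt(1 - taste_health_cor^2) * rnorm(n_items)
    data.frame(
      item_id = seq_len(n_items),
      latent_taste = pmin(5, pmax(-5, latent_sd * z1)),
      latent_health = pmin(5, pmax(-5, latent_sd * z2))
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# deterministic 60-item core subset spanning the taste range
core_item_subset <- function(items, n_core) {
  if (nrow(items) <= n_core) return(items$item_id)
  ord <- items$item_id[order(items$latent_taste)]
  idx <- round(seq(1, nrow(items), length.out = n_core))
  sort(ord[idx])
}

#' Generate subject-by-session attribute ratings
#'
#' Each subject's mean rating of an item is the item's latent value plus a
#' subject-by-item offset (sd \code{between_sd}); each session adds
#' independent noise (sd \code{within_sd}, settable per attribute). Values
#' are clipped to [-5, 5]. Sessions 1 and 5 rate all items; sessions 2-4
#' rate a fixed core subset (\code{n_core_items}) chosen to span the taste
#' range. The implied test-retest ICC of the unclipped ratings is
#' \code{(var_latent + between_sd^2) / (var_latent + between_sd^2 +
#' within_sd^2)}, which the function reports as attribute
#' \code{"implied_icc"}.
#'
#' @param items Item table from \code{\link{gen_items}}.
#' @param n_subjects Number of subjects.
#' @param sessions Integer vector of session numbers (subset of 1:5).
#' @param between_sd Subject-by-item offset sd (>= 0).
#' @param within_sd Session noise sd (>= 0); scalar or named vector with
#'   elements \code{taste} and \code{health}. The defaults give health
#'   ratings substantially higher test-retest reliability than taste
#'   ratings, as observed for real raters.
#' @param seed Optional integer seed (local to this call).
#' @param n_core_items Size of the sessions 2-4 rating subset.
#' @return A data.frame with columns \code{subject_id}, \code{session},
#'   \code{item_id}, \code{attribute}, \code{value}.
#' @export
gen_ratings <- function(items, n_subjects, sessions = 1:5, between_sd = 1,
                        within_sd = c(taste = 2.0, health = 1.2), seed = NULL,
                        n_core_items = 60) {
  stopifnot(n_subjects >= 1, all(sessions %in% 1:5))
  if (length(within_sd) == 1L && is.null(names(within_sd)))
    within_sd <- c(taste = unname(within_sd), health = unname(within_sd))
  if (any(between_sd < 0) || any(within_sd < 0))
    stop("rating noise sds must be >= 0", call. = FALSE)
  core <- core_item_subset(items, n_core_items)
  latent <- c(taste = "latent_taste", health = "latent_health")
  run <- function() {
    out <- vector("list", 2L * n_subjects * length(sessions))
    k <- 0L
    for (s in seq_len(n_subjects)) {
      # subject-by-item offsets persist across sessions
      off <- list(
        taste = rnorm(nrow(items), 0, between_sd),
        health = rnorm(nrow(items), 0, between_sd)
      )
      for (sess in sessions) {
        ids <- if (sess %in% c(1L, 5L)) items$item_id else core
        sel <- match(ids, items$item_id)
        for (att in c("taste", "health")) {
          mu <- items[[latent[[att]]]][sel] + off[[att]][sel]
          val <- mu + rnorm(length(sel), 0, within_sd[[att]])
          k <- k + 1L
          out[[k]] <- data.frame(subject_id = s, session = sess,
                                 item_id = ids, attribute = att,
                                 value = pmin(5, pmax(-5, val)))
        }
      }
    }
    do.call(rbind, out[seq_len(k)])
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  vl <- var(c(items$latent_taste, items$latent_health))
  attr(res, "implied_icc") <-
    (vl + between_sd^2) / (vl + between_sd^2 + within_sd^2)
  attr(res, "core_items") <- core
  res
}

#' Build a choice-session design from one subject's session-1 ratings
#'
#' Constructs the pair list and block structure of one choice session:
#' \code{n_trials} item pairs split over \code{n_health_blocks} health-cued
#' and \code{n_natural_blocks} natural-cued blocks in pseudo-random order.
#' The "healthier" item of a pair is the one with the higher session-1 health
#' rating by that subject; exact health ties are never paired. A
#' \code{challenge_fraction} of pairs are challenge trials, in which the item
#' rated tastier is strictly less healthy (optionally restricted to
#' \code{|td| <= challenge_td_max}). The same design (pairs fixed by
#' session-1 ratings) is reused for all five sessions of the study.
#'
#' @param ratings_s1 Session-1 rating rows for one subject (both attributes).
#' @param subject Subject id to select if \code{ratings_s1} holds several.
#' @param n_trials Total trials in the session.
#' @param challenge_fraction Fraction of pairs that must be challenge pairs.
#' @param challenge_td_max Optional cap on |taste difference| for a pair to
#'   count as a challenge pair ("similar ratings"); \code{Inf} disables it.
#' @param n_health_blocks,n_natural_blocks Block counts per condition.
#' @param health_trials_mean,health_trials_sd Mean/sd of the health-cued
#'   trial total; the realized total is drawn per design and the remainder is
#'   assigned to natural-cued blocks so the session always has
#'   \code{n_trials} trials. Defaults scale the full design's 110.6 +/- 5.2
#'   (out of 210) proportionally to \code{n_trials}.
#' @param seed Optional integer seed (local to this call).
#' @return An object of class \code{rst_design}: a list with \code{subject_id},
#'   \code{trials} (one row per trial: block, condition, items, attribute
#'   differences in both codings, challenge flag) and \code{blocks}.
#' @export
build_design <- function(ratings_s1, subject = NULL, n_trials = 210,
                         challenge_fraction = 0.5, challenge_td_max = Inf,
                         n_health_blocks = 9, n_natural_blocks = 8,
                         health_trials_mean = NULL, health_trials_sd = NULL,
                         seed = NULL) {
  stopifnot(n_trials >= n_health_blocks + n_natural_blocks,
            challenge_fraction >= 0, challenge_fraction <= 1)
  if (is.null(health_trials_mean))
    health_trials_mean <- n_trials * 110.6 / 210
  if (is.null(health_trials_sd))
    health_trials_sd <- n_trials * 5.2 / 210
  r <- ratings_s1[ratings_s1$session == 1L, , drop = FALSE]
  if (!is.null(subject)) r <- r[r$subject_id == subject, , drop = FALSE]
  if (length(unique(r$subject_id)) != 1L)
    stop("'ratings_s1' must contain exactly one subject (use 'subject=')",
         call. = FALSE)
  subj <- r$subject_id[1]
  taste <- r[r$attribute == "taste", c("item_id", "value")]
  health <- r[r$attribute == "health", c("item_id", "value")]
  ids <- intersect(taste$item_id, health$item_id)
  if (length(ids) < 2)
    stop("need session-1 taste and health ratings for at least 2 items",
         call. = FALSE)
  tv <- setNames(taste$value[match(ids, taste$item_id)], ids)
  hv <- setNames(health$value[match(ids, health$item_id)], ids)

  run <- function() {
    # enumerate unordered pairs; classify
    cmb <- utils::combn(length(ids), 2)
    i1 <- cmb[1, ]; i2 <- cmb[2, ]
    h1 <- hv[i1]; h2 <- hv[i2]
    keep <- h1 != h2                       # exact health ties excluded
    i1 <- i1[keep]; i2 <- i2[keep]
    healthier <- ifelse(hv[i1] >= hv[i2], i1, i2)
    lesser <- ifelse(hv[i1] >= hv[i2], i2, i1)
    hd <- hv[healthier] - hv[lesser]       # > 0 by construction
    td <- tv[healthier] - tv[lesser]
    challenge <- td < 0 & abs(td) <= challenge_td_max
    n_chal <- round(challenge_fraction * n_trials)
    n_plain <- n_trials - n_chal
    pool_c <- which(challenge)
    pool_p <- which(!challenge)
    if (length(pool_c) < n_chal)
      stop("insufficient challenge pairs: need ", n_chal, ", have ",
           length(pool_c), " (shortfall ", n_chal - length(pool_c), ")",
           call. = FALSE)
    if (length(pool_p) < n_plain)
      stop("insufficient non-challenge pairs: need ", n_plain, ", have ",
           length(pool_p), " (shortfall ", n_plain - length(pool_p), ")",
           call. = FALSE)
    sel <- c(sample(pool_c, n_chal), sample(pool_p, n_plain))
    sel <- sample(sel)                     # shuffle trial order

    # block structure: health-cued total drawn around the design mean
    lo <- n_health_blocks; hi <- n_trials - n_natural_blocks
    n_health <- round(rnorm(1, health_trials_mean, health_trials_sd))
    n_health <- min(max(n_health, lo), hi)
    n_natural <- n_trials - n_health
    split_blocks <- function(total, k) {
      base <- rep(total %/% k, k)
      extra <- sample(k, total %% k)
      base[extra] <- base[extra] + 1L
      base
    }
    bsize <- c(split_blocks(n_health, n_health_blocks),
               split_blocks(n_natural, n_natural_blocks))
    bcond <- c(rep("health", n_health_blocks),
               rep("natural", n_natural_blocks))
    ord <- sample(length(bsize))           # pseudo-random block order
    bsize <- bsize[ord]; bcond <- bcond[ord]
    blocks <- data.frame(block_index = seq_along(bsize), condition = bcond,
                         n_trials = bsize)
    block_of <- rep(blocks$block_index, blocks$n_trials)
    cond_of <- rep(blocks$condition, blocks$n_trials)

    # left/right placement randomized
    h_left <- runif(n_trials) < 0.5
    h_id <- as.integer(ids[healthier[sel]])
    l_id <- as.integer(ids[lesser[sel]])
    trials <- data.frame(
      subject_id = subj,
      trial = seq_len(n_trials),
      block_index = block_of,
      condition = cond_of,
      left_item = ifelse(h_left, h_id, l_id),
      right_item = ifelse(h_left, l_id, h_id),
      healthier_side = ifelse(h_left, "left", "right"),
      hd = unname(hd[sel]),
      td = unname(td[sel]),
      hd_lr = unname(ifelse(h_left, hd[sel], -hd[sel])),
      td_lr = unname(ifelse(h_left, td[sel], -td[sel])),
      challenge = unname(challenge[sel])
    )
    structure(list(subject_id = subj, trials = trials, blocks = blocks),
              class = "rst_design")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.rst_design <- function(x, ...) {
  cat(sprintf("rst_design: subject %s, %d trials, %d blocks (%d health / %d natural), %d challenge trials\n",
              x$subject_id, nrow(x$trials), nrow(x$blocks),
              sum(x$blocks$condition == "health"),
              sum(x$blocks$condition == "natural"),
              sum(x$trials$challenge)))
  invisible(x)
}

#' Draw a synthetic subject cohort around group parameter means
#'
#' Subject-level parameters are drawn per condition (and, when
#' \code{stable = TRUE}, held as a fixed subject deviation added to each
#' session's group mean, so a subject keeps their standing across sessions).
#' With \code{stratified = TRUE} draws use randomly permuted normal quantiles,
#' which makes the realized cohort mean equal the group mean; this isolates
#' estimator error in recovery studies. Draws are clipped to the model's
#' admissible region (\code{noise >= 0.3}, \code{sp_bias} in [0.2, 0.8],
#' \code{ndt >= 0.2}).
#'
#' @param n_subjects Number of subjects.
#' @param group_params Group mean/sd table as from
#'   \code{\link{reference_group_params}}.
#' @param sessions Sessions to cover.
#' @param conditions Conditions to cover.
#' @param subject_sd Optional named numeric vector overriding the \code{sd}
#'   column per parameter.
#' @param stable Keep each subject's deviation fixed across sessions
#'   (\code{TRUE}) or redraw it independently per session (\code{FALSE}).
#' @param stratified Use permuted-quantile draws (see above).
#' @param seed Optional integer seed (local to this call).
#' @return A data.frame: \code{subject_id}, \code{condition}, \code{session},
#'   one column per parameter.
#' @export
draw_subject_params <- function(n_subjects, group_params = reference_group_params(),
                                sessions = 1:5,
                                conditions = c("natural", "health"),
                                subject_sd = NULL, stable = TRUE,
                                stratified = TRUE, seed = NULL) {
  stopifnot(n_subjects >= 1)
  run <- function() {
    draw_dev <- function(sd) {
      if (stratified) {
        q <- qnorm((seq_len(n_subjects) - 0.5) / n_subjects, 0, sd)
        sample(q)
      } else rnorm(n_subjects, 0, sd)
    }
    out <- list()
    for (cond in conditions) {
      dev <- NULL
      for (sess in sessions) {
        gp <- group_params[group_params$condition == cond &
                             group_params$session == sess, ]
        if (nrow(gp) == 0)
          stop("no group parameters for condition ", cond, " session ", sess,
               call. = FALSE)
        if (is.null(dev) || !stable) {
          dev <- sapply(gp$parameter, function(pn) {
            s <- if (!is.null(subject_sd) && pn %in% names(subject_sd))
              subject_sd[[pn]] else gp$sd[gp$parameter == pn]
            draw_dev(s)
          })
        }
        vals <- sweep(dev, 2, setNames(gp$mean, gp$parameter)[colnames(dev)],
                      "+")
        df <- as.data.frame(vals)
        df$noise <- pmax(df$noise, 0.3)
        df$sp_bias <- pmin(pmax(df$sp_bias, 0.2), 0.8)
        df$ndt <- pmax(df$ndt, 0.2)
        df <- cbind(data.frame(subject_id = seq_len(n_subjects),
                               condition = cond, session = sess), df)
        out[[length(out) + 1L]] <- df
      }
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# internal: one row of a subject-params table -> rst_params
params_from_row <- function(row) {
  rst_params(noise = row$noise, sp_bias = row$sp_bias, ndt = row$ndt,
             rst = row$rst, w_taste = row$w_taste, w_health = row$w_health,
             drift_bias = row$drift_bias)
}

#' Simulate a full choice dataset from designs and subject parameters
#'
#' Every trial of every subject/session is forward-simulated with
#' \code{\link{simulate_trials}} under that subject's parameters for the
#' trial's cue condition, using the pair's left-minus-right attribute
#' differences. Trials whose first passage plus NDT exceeds the deadline are
#' retained with \code{censored = TRUE} (NA choice/RT).
#'
#' @param designs A single \code{rst_design} or a list of them (one per
#'   subject; subject ids must match \code{subject_params$subject_id}).
#' @param subject_params Data frame from \code{\link{draw_subject_params}}
#'   (ground truth; returned alongside the data).
#' @param sessions Sessions to simulate.
#' @param dt Simulation step (s), > 0.
#' @param deadline Response deadline (s).
#' @param seed Optional integer seed (local to this call).
#' @return A list with \code{trials} (one row per ChoiceTrial, including
#'   \code{chose_healthier}) and \code{truth} (the subject parameter table).
#' @export
simulate_dataset <- function(designs, subject_params, sessions = 1:5,
                             dt = 0.002, deadline = 3, seed = NULL) {
  if (inherits(designs, "rst_design")) designs <- list(designs)
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  run <- function() {
    out <- list()
    for (d in designs) {
      subj <- d$subject_id
      for (sess in sessions) {
        tr <- d$trials
        tr$session <- sess
        tr$chose_left <- NA_integer_
        tr$rt <- NA_real_
        tr$censored <- NA
        for (cond in unique(tr$condition)) {
          rows <- which(tr$condition == cond)
          prow <- subject_params[subject_params$subject_id == subj &
                                   subject_params$condition == cond &
                                   subject_params$session == sess, ]
          if (nrow(prow) != 1L)
            stop("missing parameters for subject ", subj, " condition ", cond,
                 " session ", sess, call. = FALSE)
          p <- params_from_row(prow)
          sim <- simulate_trials(p, tr$td_lr[rows], tr$hd_lr[rows], dt = dt,
                                 deadline = deadline)
          tr$chose_left[rows] <- sim$chose_left
          tr$rt[rows] <- sim$rt
          tr$censored[rows] <- sim$censored
        }
        out[[length(out) + 1L]] <- tr
      }
    }
    trials <- do.call(rbind, out)
    trials$chose_healthier <- as.integer(
      trials$chose_left == (trials$healthier_side == "left"))
    rownames(trials) <- NULL
    trials
  }
  trials <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  cens <- mean(trials$censored)
  if (cens > 0)
    message(sprintf("simulate_dataset: %.2f%% of trials censored at the %gs deadline",
                    100 * cens, deadline))
  list(trials = trials, truth = subject_params)
}
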