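#' Two-way agreement single-measure intraclass correlation, ICC(A,1)
#'
#' Computes the two-way random-effects, absolute-agreement, single-measure
#' ICC from the two-way ANOVA decomposition (row, column, and error mean
#' squares), with the F statistic against ICC = 0, a Satterthwaite
#' (fractional) denominator df, and a confidence interval from the standard
#' F-quantile construction for this ICC form.
#'
#' @param m Numeric matrix: rows are measurement units (subjects or items),
#'   columns are sessions/raters. At least 2 rows and 2 columns; rows with
#'   missing values are dropped (listwise) with a message.
#' @param conf_level Confidence level for the interval.
#' @return An object of class \code{icc_result}: list with \code{estimate},
#'   \code{f_value}, \code{df1}, \code{df2} (fractional), \code{p_value},
#'   \code{ci_low}, \code{ci_high}, \code{label}, \code{n}, \code{k},
#'   \code{degenerate}. A matrix with zero total variance returns
#'   \code{degenerate = TRUE} with an NA estimate rather than an error.
#' @export
icc_a1 <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("'m' must be a numeric matrix", call. = FALSE)
  cc <- complete.cases(m)
  if (!all(cc)) {
    message("icc_a1: dropping ", sum(!cc), " incomplete row(s) (listwise)")
    m <- m[cc, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop("need at least 2 complete rows and 2 columns", call. = FALSE)
  if (all(m == m[1, 1])) {
    return(structure(list(estimate = NA_real_, f_value = NA_real_,
                          df1 = n - 1, df2 = NA_real_, p_value = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          label = NA_character_, n = n, k = k,
                          degenerate = TRUE), class = "icc_result"))
  }
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  ss_r <- k * sum((rm_ - gm)^2)
  ss_c <- n * sum((cm - gm)^2)
  ss_t <- sum((m - gm)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F test against ICC = 0 with Satterthwaite df2 evaluated at the estimate
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f0 <- msr / mse
  p <- pf(f0, n - 1, v, lower.tail = FALSE)
  alpha <- 1 - conf_level
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(estimate = est, f_value = f0, df1 = n - 1, df2 = v,
                 p_value = p, ci_low = lo, ci_high = hi,
                 label = icc_label(est), n = n, k = k, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("ICC(A,1): degenerate (zero total variance)\n")
    return(invisible(x))
  }
  cat(sprintf("ICC(A,1) = %.3f (%s), F(%d, %.1f) = %.2f, p = %.3g, 95%% CI [%.3f, %.3f]\n",
              x$estimate, x$label, x$df1, x$df2, x$f_value, x$p_value,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Qualitative ICC interpretation label
#'
#' Bins: Poor (< 0.40), Fair [0.40, 0.60), Good [0.60, 0.75),
#' Excellent [0.75, 1.0]. Left-closed at the published cut points.
#'
#' @param x ICC estimate(s).
#' @return Character vector of labels.
#' @export
icc_label <- function(x) {
  ifelse(is.na(x), NA_character_,
         ifelse(x < 0.40, "Poor",
                ifelse(x < 0.60, "Fair",
                       ifelse(x < 0.75, "Good", "Excellent"))))
}

# internal: long (unit, session, value) -> units x sessions matrix
measure_matrix <- function(df, unit_col, value_col = "value") {
  w <- stats::reshape(df[, c(unit_col, "session", value_col)],
                      idvar = unit_col, timevar = "session",
                      direction = "wide")
  m <- as.matrix(w[, -1, drop = FALSE])
  rownames(m) <- w[[unit_col]]
  m[, order(as.numeric(sub(".*\\.", "", colnames(m)))), drop = FALSE]
}

icc_row <- function(measure, condition, icc) {
  data.frame(measure = measure, condition = condition,
             estimate = icc$estimate, f_value = icc$f_value, df1 = icc$df1,
             df2 = icc$df2, p_value = icc$p_value, ci_low = icc$ci_low,
             ci_high = icc$ci_high, label = ifelse(is.na(icc$label), NA,
                                                   icc$label))
}

#' Test-retest reliability of healthier-choice frequencies
#'
#' Per subject and session, the proportion of healthier choices is computed
#' within each cue condition and as the health-minus-natural difference;
#' ICC(A,1) is computed on each subjects-by-sessions matrix.
#'
#' @param trials Trial table with columns \code{subject_id}, \code{session},
#'   \code{condition}, \code{chose_healthier}, and optionally
#'   \code{censored} (censored trials are excluded).
#' @param conf_level Confidence level.
#' @return A list with elements \code{natural}, \code{health},
#'   \code{difference} (each an \code{icc_result}) and \code{table}, a tidy
#'   summary data.frame.
#' @export
choice_frequency_reliability <- function(trials, conf_level = 0.95) {
  if (length(unique(trials$session)) < 2)
    stop("need at least 2 sessions", call. = FALSE)
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  freq <- aggregate(chose_healthier ~ subject_id + session + condition,
                    data = trials, FUN = mean)
  res <- list()
  mats <- list()
  for (cond in c("natural", "health")) {
    mats[[cond]] <- measure_matrix(freq[freq$condition == cond, ],
                                   "subject_id", "chose_healthier")
    res[[cond]] <- icc_a1(mats[[cond]], conf_level)
  }
  common <- intersect(rownames(mats$natural), rownames(mats$health))
  res$difference <- icc_a1(mats$health[common, , drop = FALSE] -
                             mats$natural[common, , drop = FALSE], conf_level)
  res$table <- rbind(
    icc_row("healthy_choice_frequency", "natural", res$natural),
    icc_row("healthy_choice_frequency", "health", res$health),
    icc_row("healthy_choice_frequency", "difference", res$difference))
  res
}

#' Per-unit rating reliability
#'
#' For \code{unit = "subject"}, one ICC(A,1) per subject over the
#' items-by-sessions rating matrix (items as rows, sessions as columns); for
#' \code{unit = "item"}, one ICC per item over subjects-by-sessions. Returns
#' the mean and sd of the per-unit ICC estimates per attribute, mirroring the
#' study's rating-reliability summaries.
#'
#' @param ratings Rating table from \code{\link{gen_ratings}} (or same
#'   schema).
#' @param unit \code{"subject"} or \code{"item"}.
#' @param sessions Sessions to include; every included unit/item must be
#'   rated in all of them (e.g. the 60-item core set for five-session
#'   analyses, or the full set for sessions 1 and 5).
#' @param conf_level Confidence level for the per-unit ICCs.
#' @return A list with \code{per_unit} (attribute, unit id, ICC estimate) and
#'   \code{summary} (attribute, mean, sd, n_units).
#' @export
rating_reliability <- function(ratings, unit = c("subject", "item"),
                               sessions = 1:5, conf_level = 0.95) {
  unit <- match.arg(unit)
  r <- ratings[ratings$session %in% sessions, ]
  # items rated in all requested sessions (for every subject)
  tab <- table(r$item_id, r$session)
  ok_items <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(ok_items) < 2)
    stop("insufficient item overlap across sessions ",
         paste(sessions, collapse = ","), call. = FALSE)
  r <- r[r$item_id %in% as.numeric(ok_items), ]
  unit_col <- if (unit == "subject") "subject_id" else "item_id"
  row_col <- if (unit == "subject") "item_id" else "subject_id"
  out <- list()
  for (att in unique(r$attribute)) {
    ra <- r[r$attribute == att, ]
    for (u in unique(ra[[unit_col]])) {
      ru <- ra[ra[[unit_col]] == u, ]
      m <- measure_matrix(ru, row_col)
      icc <- icc_a1(m, conf_level)
      out[[length(out) + 1L]] <- data.frame(attribute = att, unit = unit,
                                            unit_id = u,
                                            estimate = icc$estimate)
    }
  }
  per_unit <- do.call(rbind, out)
  summ <- aggregate(estimate ~ attribute, data = per_unit,
                    FUN = function(x) c(mean = mean(x), sd = sd(x),
                                        n = length(x)))
  summ <- cbind(attribute = summ$attribute, as.data.frame(summ$estimate))
  list(per_unit = per_unit, summary = summ)
}

#' Test-retest reliability of fitted model parameters
#'
#' ICC(A,1) per parameter within each condition (subjects x sessions), and
#' for the health-minus-natural difference scores.
#'
#' @param fits Tidy fit table: columns \code{subject_id}, \code{session},
#'   \code{condition}, \code{parameter}, \code{estimate}.
#' @param conf_level Confidence level.
#' @return Tidy data.frame: one row per parameter x (condition or
#'   "difference") with the ICC estimate, F, dfs, CI and label.
#' @export
parameter_reliability <- function(fits, conf_level = 0.95) {
  out <- list()
  for (pn in unique(fits$parameter)) {
    fp <- fits[fits$parameter == pn, ]
    mats <- list()
    for (cond in c("natural", "health")) {
      fc <- fp[fp$condition == cond, ]
      if (nrow(fc) == 0) next
      mats[[cond]] <- measure_matrix(fc, "subject_id", "estimate")
      out[[length(out) + 1L]] <- icc_row(pn, cond,
                                         icc_a1(mats[[cond]], conf_level))
    }
    if (!is.null(mats$natural) && !is.null(mats$health)) {
      common <- intersect(rownames(mats$natural), rownames(mats$health))
      d <- mats$health[common, , drop = FALSE] -
        mats$natural[common, , drop = FALSE]
      out[[length(out) + 1L]] <- icc_row(pn, "difference",
                                         icc_a1(d, conf_level))
    }
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "measure"] <- "parameter"
  rownames(res) <- NULL
  res
}

#' Across-session parameter ranges and their comparison between conditions
#'
#' Per subject, condition, and parameter: the range (max - min) of the
#' session-wise estimates; then a paired two-sided t-test comparing the
#' natural-cued vs health-cued ranges across subjects.
#'
#' @param fits Tidy fit table as in \code{\link{parameter_reliability}};
#'   every subject needs estimates in all sessions for both conditions.
#' @return A list with \code{ranges} (subject, condition, parameter, range)
#'   and \code{tests} (parameter, t, df, p_value, mean_diff =
#'   health - natural).
#' @export
parameter_range_comparison <- function(fits) {
  rng <- aggregate(estimate ~ subject_id + condition + parameter, data = fits,
                   FUN = function(x) max(x) - min(x))
  names(rng)[names(rng) == "estimate"] <- "range"
  tests <- list()
  for (pn in unique(rng$parameter)) {
    rp <- rng[rng$parameter == pn, ]
    nat <- rp[rp$condition == "natural", c("subject_id", "range")]
    hea <- rp[rp$condition == "health", c("subject_id", "range")]
    common <- intersect(nat$subject_id, hea$subject_id)
    if (length(common) < 2)
      stop("need at least 2 subjects with ranges in both conditions",
           call. = FALSE)
    h <- hea$range[match(common, hea$subject_id)]
    n_ <- nat$range[match(common, nat$subject_id)]
    d <- h - n_
    if (all(d == 0)) {
      tests[[pn]] <- data.frame(parameter = pn, t = 0,
                                df = length(d) - 1, p_value = 1,
                                mean_diff = 0)
    } else {
      tt <- t.test(h, n_, paired = TRUE)
      tests[[pn]] <- data.frame(parameter = pn, t = unname(tt$statistic),
                                df = unname(tt$parameter),
                                p_value = tt$p.value,
                                mean_diff = unname(tt$estimate))
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(ranges = rng, tests = tests)
}
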