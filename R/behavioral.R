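#' Hierarchical logistic regression of healthier-choice outcomes
#'
#' Models the probability of choosing the healthier option as a function of
#' the health and taste rating differences (healthier minus less-healthy
#' item, session-1 ratings), cue condition, and session:
#' \code{chose_healthier ~ (hd + td) * condition * session} with all
#' interactions except hd-by-td, plus subject-level random effects.
#' Condition reference is natural-cued, session reference is the first
#' session. Estimated with \code{lme4::glmer}; 95% Wald intervals.
#'
#' @param trials Trial table with \code{subject_id}, \code{session},
#'   \code{condition}, \code{hd}, \code{td}, \code{chose_healthier}, optional
#'   \code{censored} (excluded).
#' @param z_score Standardize hd/td before fitting (default: raw rating
#'   units).
#' @param random \code{"reduced"} (default; random intercept + hd + td +
#'   condition slopes) or \code{"full"} (subject-level mirror of all
#'   population terms; can be very slow / degenerate at small n).
#' @param nAGQ Passed to \code{lme4::glmer}; 0 uses the faster adaptive
#'   Gauss-Hermite-free approximation, useful for large sign-pattern checks.
#' @return An object of class \code{rst_regression}: \code{coefficients}
#'   (population level: term, estimate, se, ci_low, ci_high),
#'   \code{subject_coefficients} (per-subject effects, fixed + random),
#'   \code{fit} (the merMod), \code{flagged} (TRUE if separation or
#'   non-convergence was detected).
#' @export
fit_choice_model <- function(trials, z_score = FALSE,
                             random = c("reduced", "full"), nAGQ = 1) {
  random <- match.arg(random)
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  trials <- trials[!is.na(trials$chose_healthier), ]
  if (length(unique(trials$condition)) < 2)
    stop("both cue conditions must be present", call. = FALSE)
  if (length(unique(trials$session)) < 2)
    stop("at least 2 sessions must be present", call. = FALSE)
  d <- data.frame(
    y = trials$chose_healthier,
    hd = if (z_score) as.numeric(scale(trials$hd)) else trials$hd,
    td = if (z_score) as.numeric(scale(trials$td)) else trials$td,
    condition = factor(trials$condition, levels = c("natural", "health")),
    session = factor(trials$session),
    subject_id = factor(trials$subject_id)
  )
  re <- if (random == "reduced") "(1 + hd + td + condition | subject_id)"
        else "((hd + td) * condition * session | subject_id)"
  form <- as.formula(paste("y ~ (hd + td) * condition * session +", re))
  flagged <- FALSE
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  if (any(abs(cf) > 15)) flagged <- TRUE   # quasi-separation heuristic
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se),
                      ci_low = unname(cf - qnorm(0.975) * se),
                      ci_high = unname(cf + qnorm(0.975) * se))
  structure(list(coefficients = coefs,
                 subject_coefficients = coef(fit)$subject_id,
                 fit = fit, flagged = flagged,
                 model = "choice", z_score = z_score),
            class = "rst_regression")
}

#' Hierarchical linear regression of log response times
#'
#' Models \code{log(RT)} as a function of z-scored health and taste rating
#' differences, cue condition, session, and the challenge indicator:
#' \code{log(rt) ~ (hd + td) * condition * session * challenge} (no hd-by-td
#' interaction), plus subject-level random effects. Estimated with
#' \code{lme4::lmer}; 95% Wald intervals.
#'
#' @inheritParams fit_choice_model
#' @param trials Additionally needs \code{rt} (seconds, > 0) and
#'   \code{challenge} (logical).
#' @return An \code{rst_regression} object.
#' @export
fit_rt_model <- function(trials, random = c("reduced", "full")) {
  random <- match.arg(random)
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  trials <- trials[!is.na(trials$rt), ]
  if (any(trials$rt <= 0)) stop("all RTs must be positive", call. = FALSE)
  d <- data.frame(
    lrt = log(trials$rt),
    hd = as.numeric(scale(trials$hd)),    # z-scored by specification
    td = as.numeric(scale(trials$td)),
    condition = factor(trials$condition, levels = c("natural", "health")),
    session = factor(trials$session),
    challenge = factor(trials$challenge, levels = c(FALSE, TRUE)),
    subject_id = factor(trials$subject_id)
  )
  one_level <- vapply(d[c("condition", "session", "challenge")],
                      function(x) length(unique(x)) < 2, logical(1))
  rhs <- c("hd + td",
           if (!one_level[["condition"]]) "condition",
           if (!one_level[["session"]]) "session",
           if (!one_level[["challenge"]]) "challenge")
  fixed <- paste0("(", rhs[1], ")",
                  paste0(vapply(rhs[-1], function(x) paste0(" * ", x),
                                character(1)), collapse = ""))
  re <- if (random == "reduced") "(1 + hd + td | subject_id)"
        else paste0("(", fixed, " | subject_id)")
  form <- as.formula(paste("lrt ~", fixed, "+", re))
  flagged <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se),
                      ci_low = unname(cf - qnorm(0.975) * se),
                      ci_high = unname(cf + qnorm(0.975) * se))
  structure(list(coefficients = coefs,
                 subject_coefficients = coef(fit)$subject_id,
                 fit = fit, flagged = flagged,
                 model = "rt", z_score = TRUE),
            class = "rst_regression")
}

#' @export
print.rst_regression <- function(x, ...) {
  cat(sprintf("hierarchical %s model (%s)%s\n", x$model,
              if (x$model == "choice") "logistic" else "linear, log-RT",
              if (x$flagged) " [flagged]" else ""))
  cf <- x$coefficients
  cf[, -1] <- round(cf[, -1], 3)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' Choice-prediction accuracy of a fitted choice model
#'
#' Classifies each trial by the model-predicted probability of choosing the
#' healthier option (p > 0.5 predicts the healthier choice; p <= 0.5 the
#' less-healthy choice) and returns the fraction of trials where the
#' prediction matches the observed choice.
#'
#' @param model An \code{rst_regression} from \code{\link{fit_choice_model}}.
#' @param trials Trial table sharing the fitted model's rating provenance
#'   (session-1 hd/td).
#' @return A list with \code{overall} accuracy and \code{by_session} (session,
#'   accuracy, n).
#' @export
predict_accuracy_model <- function(model, trials) {
  stopifnot(inherits(model, "rst_regression"), model$model == "choice")
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  trials <- trials[!is.na(trials$chose_healthier), ]
  d <- data.frame(
    hd = if (model$z_score) as.numeric(scale(trials$hd)) else trials$hd,
    td = if (model$z_score) as.numeric(scale(trials$td)) else trials$td,
    condition = factor(trials$condition, levels = c("natural", "health")),
    session = factor(trials$session,
                     levels = levels(model$fit@frame$session)),
    subject_id = factor(trials$subject_id)
  )
  p <- stats::predict(model$fit, newdata = d, type = "response",
                      allow.new.levels = TRUE)
  pred <- as.integer(p > 0.5)
  hit <- pred == trials$chose_healthier
  by_session <- aggregate(hit ~ trials$session, FUN = mean)
  names(by_session) <- c("session", "accuracy")
  by_session$n <- as.vector(table(trials$session)[as.character(by_session$session)])
  list(overall = mean(hit), by_session = by_session)
}

#' Choice-prediction accuracy of a single rating attribute
#'
#' Predicts that each subject chooses the item they rated higher on the named
#' attribute in session 1, and scores the prediction against the observed
#' choices, by cue condition. Trials where the two items are rated exactly
#' equal on the attribute are excluded and tallied.
#'
#' @param ratings_s1 Session-1 rating rows (all subjects).
#' @param trials Trial table (censored trials excluded).
#' @param attribute \code{"taste"} or \code{"health"}.
#' @return A list with \code{by_condition} (condition, accuracy = mean of the
#'   per-subject accuracies, se = their standard error, n_subjects,
#'   n_trials), \code{per_subject}, and \code{excluded_ties}.
#' @export
predict_accuracy_attribute <- function(ratings_s1, trials,
                                       attribute = c("taste", "health")) {
  attribute <- match.arg(attribute)
  r <- ratings_s1[ratings_s1$session == 1 & ratings_s1$attribute == attribute, ]
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  trials <- trials[!is.na(trials$chose_left), ]
  key <- paste(r$subject_id, r$item_id)
  val <- setNames(r$value, key)
  vl <- val[paste(trials$subject_id, trials$left_item)]
  vr <- val[paste(trials$subject_id, trials$right_item)]
  if (any(is.na(vl)) || any(is.na(vr)))
    stop("missing session-1 ", attribute, " ratings for some trial items",
         call. = FALSE)
  tie <- vl == vr
  excluded <- sum(tie)
  tr <- trials[!tie, ]
  hit <- as.integer(vl[!tie] > vr[!tie]) == tr$chose_left
  per <- aggregate(hit ~ tr$subject_id + tr$condition, FUN = mean)
  names(per) <- c("subject_id", "condition", "accuracy")
  by_cond <- do.call(rbind, lapply(split(per, per$condition), function(g)
    data.frame(condition = g$condition[1], accuracy = mean(g$accuracy),
               se = sd(g$accuracy) / sqrt(nrow(g)), n_subjects = nrow(g))))
  by_cond$n_trials <- as.vector(table(tr$condition)[as.character(by_cond$condition)])
  rownames(by_cond) <- NULL
  list(by_condition = by_cond, per_subject = per, excluded_ties = excluded,
       attribute = attribute)
}
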