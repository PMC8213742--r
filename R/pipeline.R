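#' Build a run configuration for the synthetic study pipeline
#'
#' Defaults reproduce the study's design constants: 23 subjects, 180 items
#' (60-item core set in sessions 2-4), five sessions, 210 trials per session
#' in 9 health-cued + 8 natural-cued blocks, a 3-s response deadline, and
#' generative rstDDM parameters from \code{\link{reference_group_params}}.
#'
#' @param seed Integer master seed; every stage derives its seed from it.
#' @param n_subjects,n_items,sessions,n_trials,challenge_fraction Design.
#' @param between_sd,within_sd Rating-noise structure (see
#'   \code{\link{gen_ratings}}).
#' @param deadline Choice deadline in seconds.
#' @param mode Fitting mode: \code{"two_stage"} or \code{"mcmc"}.
#' @param min_trials Minimum usable trials for a subject/session/condition
#'   fit; smaller cells are skipped with a log entry.
#' @param fit Subject-fit settings (\code{\link{fit_control}}).
#' @param group_params Generative group parameter table.
#' @param conservation_tol Documented mass-conservation tolerance for the
#'   first-passage solver (> 0).
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(seed = 1, n_subjects = 23, n_items = 180,
                       sessions = 1:5, n_trials = 210,
                       challenge_fraction = 0.5, between_sd = 1,
                       within_sd = c(taste = 2.0, health = 1.2),
                       deadline = 3, mode = c("two_stage", "mcmc"),
                       min_trials = 30, fit = fit_control(),
                       group_params = reference_group_params(),
                       conservation_tol = 1e-4) {
  mode <- match.arg(mode)
  cfg <- list(seed = seed, n_subjects = n_subjects, n_items = n_items,
              sessions = sessions, n_trials = n_trials,
              challenge_fraction = challenge_fraction,
              between_sd = between_sd, within_sd = within_sd,
              deadline = deadline, mode = mode, min_trials = min_trials,
              fit = fit, group_params = group_params,
              conservation_tol = conservation_tol)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

required_config_fields <- c("seed", "n_subjects", "n_items", "sessions",
                            "n_trials", "challenge_fraction", "between_sd",
                            "within_sd", "deadline", "mode", "min_trials",
                            "fit", "group_params", "conservation_tol")

validate_run_config <- function(cfg) {
  missing <- setdiff(required_config_fields, names(cfg))
  if (length(missing))
    stop("run configuration is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config field 'seed' must be a single integer", call. = FALSE)
  if (cfg$conservation_tol <= 0)
    stop("config field 'conservation_tol' must be > 0", call. = FALSE)
  invisible(cfg)
}

# polynomial rolling hash of the serialized config, for the run log
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "group_params")],
                         auto_unbox = TRUE, force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(js))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / load the study's tidy tables
#'
#' \code{write_study_tables} writes \code{trials.tsv}, \code{ratings.tsv} and
#' (optionally) \code{truth.json}; \code{load_study_tables} reads and
#' validates them, reporting schema violations with row numbers and flagging
#' RTs outside (0, deadline].
#'
#' @param trials,ratings Data frames in the package's tidy schemas.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth parameter table (written as JSON).
#' @return \code{write_study_tables}: the directory, invisibly.
#'   \code{load_study_tables}: a list with \code{trials} and \code{ratings}.
#' @export
write_study_tables <- function(trials, ratings, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(trials, file.path(dir, "trials.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(ratings, file.path(dir, "ratings.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_study_tables
#' @param path Directory containing \code{trials.tsv} and \code{ratings.tsv}.
#' @param deadline Deadline used for the RT range check.
#' @export
load_study_tables <- function(path, deadline = 3) {
  tf <- file.path(path, "trials.tsv")
  rf <- file.path(path, "ratings.tsv")
  for (f in c(tf, rf)) if (!file.exists(f)) stop("missing file: ", f,
                                                 call. = FALSE)
  trials <- read.delim(tf, stringsAsFactors = FALSE)
  ratings <- read.delim(rf, stringsAsFactors = FALSE)
  need_t <- c("subject_id", "session", "condition", "left_item", "right_item",
              "hd", "td", "hd_lr", "td_lr", "chose_left", "rt", "censored")
  need_r <- c("subject_id", "session", "item_id", "attribute", "value")
  miss_t <- setdiff(need_t, names(trials))
  if (length(miss_t))
    stop("trials.tsv schema error: missing column(s) ",
         paste(miss_t, collapse = ", "), call. = FALSE)
  miss_r <- setdiff(need_r, names(ratings))
  if (length(miss_r))
    stop("ratings.tsv schema error: missing column(s) ",
         paste(miss_r, collapse = ", "), call. = FALSE)
  bad_rt <- which(!trials$censored &
                    (is.na(trials$rt) | trials$rt <= 0 |
                       trials$rt > deadline))
  if (length(bad_rt))
    warning("trials.tsv: ", length(bad_rt), " non-censored RT(s) outside (0, ",
            deadline, "]; first rows: ",
            paste(head(bad_rt, 10), collapse = ", "), call. = FALSE)
  bad_val <- which(abs(ratings$value) > 5 | is.na(ratings$value))
  if (length(bad_val))
    stop("ratings.tsv: value outside [-5, 5] at row(s) ",
         paste(head(bad_val, 10), collapse = ", "), call. = FALSE)
  list(trials = trials, ratings = ratings)
}

#' Run the synthetic study end-to-end
#'
#' Orchestrates simulate -> fit -> regress -> reliability -> report into an
#' output directory, fully determined by \code{config$seed}. Each stage
#' writes its tables before the next starts, so a failing stage leaves the
#' earlier outputs in place and aborts with a stage-named error.
#'
#' @param config A \code{\link{run_config}} (or a plain list with the same
#'   fields, which is validated).
#' @param outdir Output directory.
#' @param stages Subset of \code{c("simulate", "fit", "regress",
#'   "reliability", "report")}; later stages load earlier outputs from
#'   \code{outdir} if not run in the same call.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory stage results and the output
#'   directory.
#' @export
run_synthetic_study <- function(config = run_config(), outdir,
                                stages = c("simulate", "fit", "regress",
                                           "reliability", "report"),
                                verbose = TRUE) {
  validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  log_line("run start: seed=%d config_hash=%s stages=%s", config$seed,
           config_hash(config), paste(stages, collapse = ","))
  state <- list()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_line("stage %s done in %.1fs", name,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  seeds <- config$seed + c(simulate = 11, fit = 23, regress = 37,
                           reliability = 53)

  state$sim <- run_stage("simulate", function() {
    items <- gen_items(config$n_items, seed = seeds[["simulate"]])
    ratings <- gen_ratings(items, config$n_subjects,
                           sessions = config$sessions,
                           between_sd = config$between_sd,
                           within_sd = config$within_sd,
                           seed = seeds[["simulate"]] + 1)
    designs <- lapply(seq_len(config$n_subjects), function(s)
      build_design(ratings, subject = s, n_trials = config$n_trials,
                   challenge_fraction = config$challenge_fraction,
                   seed = seeds[["simulate"]] + 100 + s))
    truth <- draw_subject_params(config$n_subjects,
                                 group_params = config$group_params,
                                 sessions = config$sessions,
                                 seed = seeds[["simulate"]] + 2)
    ds <- simulate_dataset(designs, truth, sessions = config$sessions,
                           deadline = config$deadline,
                           seed = seeds[["simulate"]] + 3)
    write_study_tables(ds$trials, ratings, outdir, truth = truth)
    log_line("simulated %d trials, %d ratings (censored: %.2f%%)",
             nrow(ds$trials), nrow(ratings), 100 * mean(ds$trials$censored))
    list(items = items, ratings = ratings, designs = designs,
         truth = truth, trials = ds$trials)
  })

  get_tables <- function() {
    if (!is.null(state$sim)) return(state$sim)
    load_study_tables(outdir, deadline = config$deadline)
  }

  state$fits <- run_stage("fit", function() {
    tabs <- get_tables()
    trials <- tabs$trials
    rows <- list()
    for (s in unique(trials$subject_id)) {
      for (sess in unique(trials$session)) {
        for (cond in unique(trials$condition)) {
          tr <- trials[trials$subject_id == s & trials$session == sess &
                         trials$condition == cond, ]
          tr <- usable_trials(tr)
          if (nrow(tr) < config$min_trials) {
            log_line("fit skipped: subject %s session %s %s (%d trials < %d)",
                     s, sess, cond, nrow(tr), config$min_trials)
            next
          }
          ctl <- modifyList(config$fit,
                            list(min_trials = config$min_trials,
                                 seed = seeds[["fit"]] + s))
          f <- fit_subject(tr, model = "rst", control = ctl)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = s, session = sess, condition = cond,
            parameter = par_names, estimate = unname(f$estimates),
            se = unname(f$se), loglik = f$loglik,
            convergence = f$convergence)
        }
      }
    }
    fits <- do.call(rbind, rows)
    write.table(fits, file.path(outdir, "fits.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    fits
  })

  state$regressions <- run_stage("regress", function() {
    tabs <- get_tables()
    cm <- fit_choice_model(tabs$trials)
    rm_ <- fit_rt_model(tabs$trials)
    out <- rbind(cbind(model = "choice", cm$coefficients),
                 cbind(model = "log_rt", rm_$coefficients))
    write.table(out, file.path(outdir, "regressions.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    ratings <- if (!is.null(tabs$ratings)) tabs$ratings else
      load_study_tables(outdir)$ratings
    acc_m <- predict_accuracy_model(cm, tabs$trials)
    acc_t <- predict_accuracy_attribute(ratings, tabs$trials, "taste")
    acc_h <- predict_accuracy_attribute(ratings, tabs$trials, "health")
    list(choice = cm, rt = rm_, accuracy_model = acc_m,
         accuracy_taste = acc_t, accuracy_health = acc_h)
  })

  state$reliability <- run_stage("reliability", function() {
    tabs <- get_tables()
    out <- list()
    out$choice <- choice_frequency_reliability(tabs$trials)$table
    ratings <- if (!is.null(tabs$ratings)) tabs$ratings else
      load_study_tables(outdir)$ratings
    rr <- rating_reliability(ratings, unit = "subject",
                             sessions = config$sessions)
    out$ratings_subject <- rr$summary
    fits <- state$fits
    if (is.null(fits) && file.exists(file.path(outdir, "fits.tsv")))
      fits <- read.delim(file.path(outdir, "fits.tsv"))
    if (!is.null(fits)) {
      out$parameters <- parameter_reliability(fits)
      if (length(unique(fits$session)) >= 2)
        out$ranges <- tryCatch(parameter_range_comparison(fits)$tests,
                               error = function(e) {
                                 log_line("range comparison skipped: %s",
                                          conditionMessage(e))
                                 NULL
                               })
    }
    ptab <- out$parameters
    if (!is.null(ptab)) names(ptab)[names(ptab) == "parameter"] <- "measure"
    tab <- rbind(out$choice, ptab)
    write.table(tab, file.path(outdir, "reliability.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    out
  })

  run_stage("report", function() {
    tabs <- get_tables()
    trials <- tabs$trials
    prop <- aggregate(chose_healthier ~ condition + session,
                      data = trials[!trials$censored, ], FUN = mean)
    lines <- c(
      "# Synthetic cued-attribute food-choice study report", "",
      sprintf("- master seed: %d (config hash %s)", config$seed,
              config_hash(config)),
      sprintf("- subjects: %d; sessions: %s; trials/session: %d",
              config$n_subjects, paste(range(config$sessions),
                                       collapse = "-"), config$n_trials),
      sprintf("- censored trials: %.2f%%", 100 * mean(trials$censored)), "",
      "## Healthier-choice proportion by condition and session", "",
      paste(utils::capture.output(print(prop, row.names = FALSE)),
            collapse = "\n"), "")
    if (!is.null(state$reliability$choice)) {
      lines <- c(lines, "## Choice-frequency reliability (ICC(A,1))", "",
                 paste(utils::capture.output(
                   print(state$reliability$choice, row.names = FALSE)),
                   collapse = "\n"), "")
    }
    writeLines(lines, file.path(outdir, "report.md"))
    TRUE
  })

  log_line("run complete")
  invisible(c(state, list(outdir = outdir)))
}
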