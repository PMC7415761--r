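# One-command orchestration: simulate (or read) a dataset, validate it,
# detect showings, build the observation table, fit the configured models,
# and emit tables plus a text report following the analysis order: overall
# success, distribution of showing types, success models, effort models,
# accuracy-time correlation, owner-behavior models.

.run_config_keys <- c("simulate", "events_file", "metadata_file", "window",
                      "chance", "alpha", "use_phase2_choice", "d_method",
                      "seed", "out_dir", "sim")

#' Build a pipeline run configuration
#'
#' Exactly one input mode is active: `simulate = TRUE` (a synthetic dataset
#' from `sim`) or a pair of `events_file` / `metadata_file` paths.
#'
#' @param simulate Generate data with [simulate_dataset()]?
#' @param events_file,metadata_file Long-table event file and trial-metadata
#'   CSV (used when `simulate = FALSE`).
#' @param window Detector alternation window, seconds.
#' @param chance Chance success level in percent (25 for four boxes).
#' @param alpha Two-sided significance level.
#' @param use_phase2_choice Use the phase-2 choice for both phases in the
#'   type summary's choice rate.
#' @param d_method Cohen's d flavor for paired tests (`"diff"`/`"pooled"`).
#' @param seed Integer seed controlling every random draw of the run.
#' @param out_dir Directory for CSV/report output, or `NULL` to skip
#'   writing.
#' @param sim A [sim_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = TRUE, events_file = NULL,
                       metadata_file = NULL, window = 2, chance = 25,
                       alpha = 0.05, use_phase2_choice = FALSE,
                       d_method = "diff", seed = 1L, out_dir = NULL,
                       sim = sim_config()) {
  if (window < 0) stop("window must be non-negative", call. = FALSE)
  if (chance <= 0 || chance >= 100) stop("chance must be in (0, 100)",
                                         call. = FALSE)
  if (!simulate && (is.null(events_file) || is.null(metadata_file))) {
    stop("need events_file and metadata_file when simulate = FALSE",
         call. = FALSE)
  }
  if (simulate && (!is.null(events_file) || !is.null(metadata_file))) {
    stop("exactly one of simulation and input files may be active",
         call. = FALSE)
  }
  structure(list(simulate = simulate, events_file = events_file,
                 metadata_file = metadata_file, window = window,
                 chance = chance, alpha = alpha,
                 use_phase2_choice = use_phase2_choice,
                 d_method = d_method, seed = as.integer(seed),
                 out_dir = out_dir, sim = sim),
            class = "run_config")
}

#' Load / save a run configuration (JSON)
#'
#' The file holds a flat JSON object of [run_config()] arguments; the `sim`
#' entry, if present, holds [sim_config()] arguments. Unknown keys are an
#' error that lists the valid ones.
#'
#' @param path Path to a JSON config file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .run_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(.run_config_keys, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw[["sim"]])) {
    sim_keys <- names(formals(sim_config))
    bad <- setdiff(names(raw[["sim"]]), sim_keys)
    if (length(bad)) {
      stop("unknown sim key(s): ", paste(bad, collapse = ", "),
           "; valid keys: ", paste(sim_keys, collapse = ", "), call. = FALSE)
    }
    raw[["sim"]] <- do.call(sim_config, lapply(raw[["sim"]], function(x)
      if (is.list(x)) unlist(x) else x))
  }
  do.call(run_config, raw)
}

#' @rdname load_config
#' @param config A `run_config` to serialize.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)[names(formals(sim_config))]
  out$sim <- Filter(Negate(is.null), out$sim)
  out <- Filter(Negate(is.null), out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.report_line <- function(lines, ...) c(lines, sprintf(...))

#' Run the full showing-analysis pipeline
#'
#' Stages: (1) simulate or read event logs and trial metadata; (2) dataset
#' validation (errors abort, design warnings are carried in the report);
#' (3) showing detection; (4) observation table; (5) overall success tests
#' against chance and between phases; (6) per-type summary and paired
#' condition comparison; (7) success GLMMs (correct-showing model and
#' condition model, with AIC comparison of the time-only vs +condition
#' candidates); (8) effort LMM on the nested time terms and owner-behavior
#' LMMs for correct showing and effort; (9) accuracy-time correlation.
#' Row exclusions (missing values) are counted per model in the report.
#'
#' @param config A [run_config()].
#' @return A `canishow_report` list with every intermediate (logs, contexts,
#'   showings, observation table, tests, fits, comparison, correlation,
#'   report text). If `config$out_dir` is set, CSV tables and `report.txt`
#'   are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  set.seed(config$seed)
  if (config$simulate) {
    ds <- simulate_dataset(config$sim)
    logs <- ds$logs
    contexts <- ds$contexts
  } else {
    logs <- read_event_log(config$events_file)
    contexts <- read_trial_metadata(config$metadata_file)
    ds <- NULL
  }
  if (!length(logs)) {
    stop("validation failed: dataset contains no event logs", call. = FALSE)
  }
  validation <- validate_dataset(logs, contexts)
  if (any(validation$severity == "error")) {
    stop("validation failed: ",
         paste(head(validation$message[validation$severity == "error"], 3L),
               collapse = "; "), call. = FALSE)
  }

  showings <- annotate_showings(detect_showings_all(logs, config$window),
                                contexts,
                                use_phase2_choice = config$use_phase2_choice)
  obs <- add_time_covariates(
    build_observation_table(logs, contexts, window = config$window))

  succ1 <- success_percent_by_pair(obs, 1L)
  succ2 <- success_percent_by_pair(obs, 2L)
  t_phase1 <- one_sample_t_vs_chance(succ1, chance = config$chance)
  t_phase2 <- one_sample_t_vs_chance(succ2, chance = config$chance)
  t_between <- tryCatch(
    paired_t(succ1, succ2[names(succ1)], d_method = config$d_method),
    error = function(e) NULL)

  type_summary <- summarize_types(showings, n_cells = nrow(obs))
  type_by_condition <- compare_type_frequencies(obs)

  tt <- paste(time_terms(), collapse = " + ")
  f_succ_time <- as.formula(paste("success ~", tt))
  f_succ_prop <- as.formula(paste("success ~ prop_correct_showing +", tt))
  f_succ_cond <- as.formula(paste("success ~ condition +", tt))
  succ_time_fit <- fit_success_glmm(obs, f_succ_time)
  succ_prop_fit <- fit_success_glmm(obs, f_succ_prop)
  succ_cond_fit <- fit_success_glmm(obs, f_succ_cond)
  succ_cmp <- select_model_aic(
    list(time_only = succ_time_fit, with_condition = succ_cond_fit),
    nested = list(c("time_only", "with_condition")))

  effort_fit <- fit_effort_lmm(obs, as.formula(paste("effort ~", tt)))
  owner_prop_fit <- fit_effort_lmm(
    obs, as.formula(paste(
      "prop_correct_showing ~ owner_behavior_count * condition +", tt)))
  owner_effort_fit <- fit_effort_lmm(
    obs, as.formula(paste(
      "effort ~ owner_behavior_count * condition +", tt)))

  sh <- showings
  dur1 <- contexts$dur_phase1[match(paste(sh$pair, sh$session, sh$trial),
                                    paste(contexts$pair, contexts$session,
                                          contexts$trial))]
  sh$trial_seconds <- sh$anchor + ifelse(sh$phase == 2L, dur1, 0)
  acc_time <- if (nrow(sh) >= 3L) {
    accuracy_time_correlation(sh$correct, sh$trial_seconds)
  } else NULL

  lines <- character()
  lines <- .report_line(lines, "== Showing analysis report ==")
  lines <- .report_line(lines, "observations: %d cells, %d pairs, %d showings",
                        nrow(obs), length(unique(obs$pair)), nrow(showings))
  lines <- .report_line(lines, "design warnings: %d", nrow(validation))
  lines <- .report_line(lines, "-- Overall success (vs %g%% chance) --",
                        config$chance)
  lines <- .report_line(lines,
    "phase 1: M = %.2f, SD = %.2f, t(%d) = %.2f, p = %.3g, d = %.2f [%.2f, %.2f]",
    t_phase1$mean, t_phase1$sd, t_phase1$df, t_phase1$statistic, t_phase1$p,
    t_phase1$d, t_phase1$d_ci[1], t_phase1$d_ci[2])
  lines <- .report_line(lines,
    "phase 2: M = %.2f, SD = %.2f, t(%d) = %.2f, p = %.3g, d = %.2f [%.2f, %.2f]",
    t_phase2$mean, t_phase2$sd, t_phase2$df, t_phase2$statistic, t_phase2$p,
    t_phase2$d, t_phase2$d_ci[1], t_phase2$d_ci[2])
  if (!is.null(t_between)) {
    lines <- .report_line(lines,
      "phase 1 vs 2: t(%d) = %.2f, p = %.3g, d = %.2f",
      t_between$df, t_between$statistic, t_between$p, t_between$d)
  }
  lines <- .report_line(lines, "-- Showing types --")
  for (i in seq_len(nrow(type_summary))) {
    r <- type_summary[i, ]
    lines <- .report_line(lines,
      "type %2d (%s + %s): freq %.2f, accuracy %s, choice rate %s",
      r$type_id, r$directional, r$attention, r$mean_frequency,
      ifelse(r$occurs, sprintf("%.2f", r$accuracy), "-"),
      ifelse(r$occurs, sprintf("%.2f", r$choice_rate), "-"))
  }
  fit_lines <- function(lines, label, fit) {
    lines <- .report_line(lines, "-- %s (n = %d, %d excluded%s) --", label,
                          fit$nobs, fit$n_excluded,
                          if (fit$converged) "" else ", NOT CONVERGED")
    co <- fit$coefficients
    for (i in seq_len(nrow(co))) {
      stat <- if ("z" %in% names(co)) {
        sprintf("z = %.2f", co$z[i])
      } else {
        sprintf("t(%.1f) = %.2f", co$df[i], co$t[i])
      }
      lines <- .report_line(lines, "%s: b = %.3f, SE = %.3f, %s, p = %.3g",
                            co$term[i], co$estimate[i], co$se[i], stat,
                            co$p[i])
    }
    lines
  }
  lines <- fit_lines(lines, "Success ~ correct showing + time", succ_prop_fit)
  lines <- fit_lines(lines, "Success ~ condition + time", succ_cond_fit)
  lines <- .report_line(lines, "AIC selection (success): %s selected",
                        succ_cmp$selected)
  lines <- fit_lines(lines, "Effort ~ time", effort_fit)
  lines <- fit_lines(lines, "Correct showing ~ owner behavior x condition + time",
                     owner_prop_fit)
  lines <- fit_lines(lines, "Effort ~ owner behavior x condition + time",
                     owner_effort_fit)
  if (!is.null(acc_time) && acc_time$defined) {
    lines <- .report_line(lines,
      "-- Accuracy vs seconds: r = %.3f, t(%d) = %.2f, p = %.3g [%.3f, %.3f]",
      acc_time$r, acc_time$df, acc_time$statistic, acc_time$p,
      acc_time$ci[1], acc_time$ci[2])
  }

  bundle <- structure(list(
    config = config, logs = logs, contexts = contexts,
    validation = validation, showings = showings, observations = obs,
    ground_truth = if (!is.null(ds)) ds$truth else NULL,
    success_tests = list(phase1 = t_phase1, phase2 = t_phase2,
                         between_phases = t_between),
    type_summary = type_summary, type_by_condition = type_by_condition,
    fits = list(success_time = succ_time_fit, success_prop = succ_prop_fit,
                success_condition = succ_cond_fit, effort_time = effort_fit,
                owner_prop = owner_prop_fit, owner_effort = owner_effort_fit),
    success_comparison = succ_cmp,
    accuracy_time = acc_time,
    report = paste(lines, collapse = "\n")
  ), class = "canishow_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_showings(showings, file.path(config$out_dir, "showings.csv"))
    write.csv(obs, file.path(config$out_dir, "observations.csv"),
              row.names = FALSE)
    write.csv(type_summary, file.path(config$out_dir, "type_summary.csv"),
              row.names = FALSE)
    coefs <- do.call(rbind, lapply(names(bundle$fits), function(nm) {
      co <- bundle$fits[[nm]]$coefficients
      stat_col <- if ("z" %in% names(co)) "z" else "t"
      data.frame(model = nm, term = co$term, estimate = co$estimate,
                 se = co$se, statistic = co[[stat_col]],
                 statistic_type = stat_col,
                 df = if ("df" %in% names(co)) co$df else NA_real_,
                 p = co$p, stringsAsFactors = FALSE)
    }))
    write.csv(coefs, file.path(config$out_dir, "coefficients.csv"),
              row.names = FALSE)
    writeLines(bundle$report, file.path(config$out_dir, "report.txt"))
  }
  bundle
}

#' @export
print.canishow_report <- function(x, ...) {
  cat(x$report, "\n")
  invisible(x)
}
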