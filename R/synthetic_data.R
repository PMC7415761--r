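# Synthetic dyadic event-log generator.
#
# Emulates the statistical structure of the hidden-object design: 30 pairs,
# 2 sessions (one condition each, order counterbalanced) x 4 trials x 2
# phases of 60 s, four hiding boxes with each box target twice per pair and
# never twice in consecutive trials of a session. Behavior streams are
# Poisson onsets with exponential durations snapped to the 0.20 s grid;
# box-directed events point at the target with probability p_correct, else
# uniformly at one of the other three boxes. Success is drawn from a
# logistic model on the *realized* correct-showing proportion of the cell,
# so the GLMM's estimand equals the generator slope exactly.

#' Simulation configuration
#'
#' Defaults state the study-scale world: 30 pairs, 2 sessions x 4 trials x
#' 2 phases of 60 s. Event rates (events per minute) and mean durations are
#' loosely anchored to the observed per-cell showing frequencies (gaze
#' alternation ~9 per cell, near-box showings most common, jumping and
#' box-opening rare); the success link defaults to intercept -2.2 and slope
#' 6.8 on the correct-showing proportion, reproducing a ~55% overall success
#' rate at a typical accuracy of ~0.35.
#'
#' @param n_pairs Number of dog-owner pairs.
#' @param n_trials Trials per session.
#' @param phase_duration Phase length in seconds.
#' @param rates Named events-per-minute rates for every dog code and
#'   `owner_behavior`.
#' @param dur_means Named mean event durations in seconds (exponential,
#'   snapped to the grid, minimum one frame).
#' @param p_correct Probability that a box-directed event references the
#'   target box.
#' @param cond_mult Named multipliers (`close`, `far`) applied to all rates
#'   by condition.
#' @param beta0,beta_correct Intercept and slope of the logistic success
#'   link on the realized correct-showing proportion.
#' @param p_nochoice_phase1 Probability that a failed phase-1 choice is "no
#'   box marked" (coded 0, scored incorrect) rather than a wrong box.
#' @param p_retrieve Per-phase probability that the dog retrieves the toy
#'   itself (0 by default: retrieval short-circuits the choice rule and is
#'   off in the stated world unless asked for).
#' @param window Detector window used when realizing the success link.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 30, n_trials = 4, phase_duration = 60,
                       rates = NULL, dur_means = NULL, p_correct = 0.35,
                       cond_mult = c(close = 1, far = 1),
                       beta0 = -2.2, beta_correct = 6.8,
                       p_nochoice_phase1 = 0.02, p_retrieve = 0,
                       window = 2) {
  default_rates <- c(gaze_box = 6, move_box = 3.5, near_box = 2,
                     jump_box = 0.5, open_box = 0.05,
                     gaze_owner = 6, move_owner = 4, vocalize = 0.8,
                     retrieve = 0, owner_behavior = 8)
  default_durs <- c(gaze_box = 1, move_box = 1.6, near_box = 8,
                    jump_box = 1.6, open_box = 1,
                    gaze_owner = 1, move_owner = 1.6, vocalize = 0.6,
                    retrieve = 1, owner_behavior = 1.6)
  if (!is.null(rates)) default_rates[names(rates)] <- rates
  if (!is.null(dur_means)) default_durs[names(dur_means)] <- dur_means
  cfg <- list(n_pairs = as.integer(n_pairs), n_sessions = 2L,
              n_trials = as.integer(n_trials), n_phases = 2L,
              phase_duration = phase_duration, rates = default_rates,
              dur_means = default_durs, p_correct = p_correct,
              cond_mult = cond_mult, beta0 = beta0,
              beta_correct = beta_correct,
              p_nochoice_phase1 = p_nochoice_phase1,
              p_retrieve = p_retrieve, window = window)
  if (any(cfg$rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (p_correct < 0 || p_correct > 1) stop("p_correct must be in [0,1]",
                                           call. = FALSE)
  if (cfg$phase_duration <= 0) stop("phase_duration must be positive",
                                    call. = FALSE)
  structure(cfg, class = "sim_config")
}

.snap_min_frame <- function(t) {
  pmax(snap_to_grid(t), grid_resolution())
}

# Place n events of given lengths in [0, dur] so that they are pairwise
# non-overlapping (abutting is fine): coded state events of one behavior
# cannot overlap themselves. Rejection sampling; an event that cannot be
# placed after 100 tries is dropped.
.place_nonoverlapping <- function(n, len, dur) {
  ons <- offs <- numeric(0)
  keep_on <- keep_off <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      o <- snap_to_grid(runif(1, 0, dur - grid_resolution()))
      e <- min(o + len[i], dur)
      if (e <= o) next
      if (!any(o < offs & ons < e)) {
        keep_on[i] <- o; keep_off[i] <- e
        ons <- c(ons, o); offs <- c(offs, e)
        break
      }
    }
  }
  ok <- !is.na(keep_on)
  list(onset = keep_on[ok], offset = keep_off[ok])
}

#' Simulate one phase's event log
#'
#' Draws, per behavior code, a Poisson number of events with uniform onsets
#' on the grid and exponential grid-snapped durations (minimum one frame),
#' clipped to the phase window. Box-directed referents follow the
#' `p_correct` rule. Uses the current RNG state; seed at the caller.
#'
#' @param config A [sim_config()].
#' @param context One trial-metadata row (needs `pair`, `session`,
#'   `condition`, `trial`, `target_box`).
#' @param phase Phase number (1 or 2).
#' @return An [event_log()].
#' @export
simulate_phase_log <- function(config, context, phase) {
  dur <- config$phase_duration
  mult <- config$cond_mult[[context$condition]]
  rows <- list()
  for (code in names(config$rates)) {
    rate <- config$rates[[code]] * mult
    n <- if (rate > 0) rpois(1L, rate / 60 * dur) else 0L
    if (code == "retrieve") {
      n <- if (config$p_retrieve > 0 && runif(1) < config$p_retrieve) 1L else 0L
    }
    if (n == 0L) next
    len <- .snap_min_frame(rexp(n, 1 / config$dur_means[[code]]))
    referent <- if (.box_directed(code)) {
      as.integer(ifelse(runif(n) < config$p_correct, context$target_box,
                        vapply(seq_len(n), function(i)
                          sample(setdiff(1:4, context$target_box), 1L), 1L)))
    } else rep(NA_integer_, n)
    # same-code (and, for box codes, same-referent) state events must not
    # overlap, matching the validator's coding rules
    grp <- if (.box_directed(code)) split(seq_len(n), referent)
           else list(seq_len(n))
    code_rows <- lapply(grp, function(idx) {
      pl <- .place_nonoverlapping(length(idx), len[idx], dur)
      if (!length(pl$onset)) return(NULL)
      data.frame(
        actor = if (code %in% owner_codes()) "owner" else "dog",
        code = code,
        referent = rep(referent[idx[1L]], length(pl$onset)),
        onset = pl$onset, offset = pl$offset, stringsAsFactors = FALSE)
    })
    rows[[code]] <- do.call(rbind, code_rows)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else NULL
  event_log(ev, pair = context$pair, session = context$session,
            condition = context$condition, trial = context$trial,
            phase = phase, phase_duration = dur)
}

# Balanced design: condition order alternates across pairs, the first target
# box cycles over pairs, and each session's targets are a permutation of the
# four boxes (hence no consecutive repeats within a session and each box
# target exactly twice per pair over the two sessions).
.simulate_design <- function(config) {
  if (config$n_trials != 4L) {
    stop("the balanced box design requires 4 trials per session",
         call. = FALSE)
  }
  rows <- list()
  for (p in seq_len(config$n_pairs)) {
    pair <- sprintf("P%02d", p)
    cond_order <- if (p %% 2L == 1L) c("close", "far") else c("far", "close")
    first_box <- (p - 1L) %% 4L + 1L
    for (s in 1:2) {
      rest <- sample(setdiff(1:4, first_box))
      targets <- if (s == 1L) c(first_box, rest) else sample(1:4)
      for (tr in 1:4) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pair, session = s, condition = cond_order[s], trial = tr,
          target_box = targets[tr], choice_phase1 = NA_integer_,
          choice_phase2 = NA_integer_, dog_retrieved = FALSE,
          dur_phase1 = config$phase_duration,
          dur_phase2 = config$phase_duration, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full dataset
#'
#' Generates the balanced design, one event log per pair x session x trial x
#' phase, and choices whose success follows
#' `logistic(beta0 + beta_correct * prop_correct)` with the correct-showing
#' proportion realized from the generated log itself (cells without showings
#' fall back to the chance accuracy 0.25). On success the choice is the
#' target box; on failure a uniformly drawn wrong box (or, in phase 1 with
#' probability `p_nochoice_phase1`, no box, coded 0). If the dog retrieves
#' in phase 1 the target stands as both choices.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; identical seeds give byte-identical
#'   outputs.
#' @return A list: `logs` (list of [event_log()]), `contexts` (trial
#'   metadata), `truth` (per-cell realized proportion and success
#'   probability plus the generator parameters as an attribute), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contexts <- .simulate_design(config)
  logs <- vector("list", nrow(contexts) * 2L)
  truth <- vector("list", nrow(contexts) * 2L)
  for (i in seq_len(nrow(contexts))) {
    ctx <- contexts[i, , drop = FALSE]
    cell <- list()
    retrieved <- FALSE
    for (ph in 1:2) {
      log <- simulate_phase_log(config, ctx, ph)
      sh <- detect_showings(log, window = config$window)
      n_show <- nrow(sh)
      prop <- if (n_show > 0) mean(sh$referent == ctx$target_box) else NA_real_
      p_succ <- plogis(config$beta0 +
                         config$beta_correct * (if (is.na(prop)) 0.25 else prop))
      if (ph == 1L && any(log$events$code == "retrieve")) retrieved <- TRUE
      if (retrieved) {
        choice <- ctx$target_box
      } else {
        success <- runif(1) < p_succ
        choice <- if (success) ctx$target_box else {
          if (ph == 1L && runif(1) < config$p_nochoice_phase1) 0L
          else sample(setdiff(1:4, ctx$target_box), 1L)
        }
      }
      j <- (i - 1L) * 2L + ph
      logs[[j]] <- log
      truth[[j]] <- data.frame(pair = ctx$pair, session = ctx$session,
                               condition = ctx$condition, trial = ctx$trial,
                               phase = ph, n_showings = n_show,
                               prop_correct_realized = prop,
                               p_success = p_succ, stringsAsFactors = FALSE)
      if (ph == 1L) contexts$choice_phase1[i] <- choice
      else contexts$choice_phase2[i] <- choice
    }
    contexts$dog_retrieved[i] <- retrieved
    if (retrieved) {
      contexts$choice_phase1[i] <- contexts$choice_phase2[i] <- ctx$target_box
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  attr(truth, "parameters") <- config
  list(logs = logs, contexts = contexts, truth = truth, config = config)
}

#' Simulate observation rows directly
#'
#' Row-level counterpart of [simulate_dataset()] for model-recovery studies:
#' skips the event streams and draws each cell's showing count, realized
#' correct-showing proportion (binomial around `p_correct`), success from
#' the same logistic link, and an effort score from a Gaussian pair-effect
#' model with a phase effect. The Gaussian effort model is
#' `effort = mu + b_pair + beta_phase * [phase == 2] + e`, truncated to
#' [0, 1].
#'
#' @param config A [sim_config()].
#' @param effort_mu Mean effort in phase 1.
#' @param effort_beta_phase Additive phase-2 effect on effort (effort is a
#'   proportion, so -0.05 means five points less effort in phase 2).
#' @param effort_sd_pair,effort_sd_resid Pair-intercept and residual SDs.
#' @param mean_showings Mean per-cell showing count (Poisson).
#' @param seed Optional seed.
#' @return A list: `rows` (observation table ready for the model layer,
#'   including nested time covariates) and `truth` (the generating
#'   parameters).
#' @export
simulate_observation_rows <- function(config = sim_config(),
                                      effort_mu = 0.45,
                                      effort_beta_phase = -0.05,
                                      effort_sd_pair = 0.08,
                                      effort_sd_resid = 0.15,
                                      mean_showings = 20,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contexts <- .simulate_design(config)
  b_pair <- setNames(rnorm(config$n_pairs, 0, effort_sd_pair),
                     unique(contexts$pair))
  rows <- do.call(rbind, lapply(1:2, function(ph) {
    d <- contexts[c("pair", "session", "condition", "trial")]
    d$phase <- ph
    d
  }))
  rows <- rows[order(rows$pair, rows$session, rows$trial, rows$phase), ]
  rownames(rows) <- NULL
  n <- nrow(rows)
  n_show <- rpois(n, mean_showings)
  prop <- ifelse(n_show > 0,
                 rbinom(n, n_show, config$p_correct) / pmax(n_show, 1L),
                 NA_real_)
  p_succ <- plogis(config$beta0 +
                     config$beta_correct * ifelse(is.na(prop), 0.25, prop))
  rows$n_showings <- n_show
  rows$prop_correct_showing <- prop
  rows$success <- runif(n) < p_succ
  eff <- effort_mu + b_pair[rows$pair] +
    effort_beta_phase * (rows$phase == 2) + rnorm(n, 0, effort_sd_resid)
  rows$effort <- pmin(pmax(eff, 0), 1)
  rows <- add_time_covariates(rows)
  list(rows = rows,
       truth = list(beta0 = config$beta0,
                    beta_correct = config$beta_correct,
                    p_correct = config$p_correct,
                    effort_mu = effort_mu,
                    effort_beta_phase = effort_beta_phase,
                    effort_sd_pair = effort_sd_pair,
                    effort_sd_resid = effort_sd_resid))
}

#' Hand-enumerated worked detection fixture
#'
#' A 34-event single-phase log that exercises every one of the 15 showing
#' types once (alternations and overlaps, including one attention-first
#' alternation), plus two boundary probes: a pair with a gap of exactly
#' 2.0 s (included, inclusive bound) and a pair with a 2.2 s gap (excluded).
#' The expected showing list is enumerated by hand alongside the events, not
#' derived from the detector.
#'
#' @return A list: `log` (an [event_log()], 120 s phase) and `expected`
#'   (data.frame of the 16 expected showings in canonical order:
#'   `type_id`, `directional`, `attention`, `referent`, `mode`, `anchor`).
#' @export
make_worked_fixture <- function() {
  ev <- list()
  exp <- list()
  add_ev <- function(code, referent, onset, offset) {
    ev[[length(ev) + 1L]] <<- data.frame(
      actor = "dog", code = code,
      referent = if (is.na(referent)) NA_integer_ else as.integer(referent),
      onset = onset, offset = offset, stringsAsFactors = FALSE)
  }
  add_exp <- function(d_code, a_code, referent, mode, anchor) {
    exp[[length(exp) + 1L]] <<- data.frame(
      type_id = classify_showing_type(d_code, a_code),
      directional = d_code, attention = a_code,
      referent = as.integer(referent), mode = mode, anchor = anchor,
      stringsAsFactors = FALSE)
  }
  dirs <- directional_codes()
  atts <- attention_codes()
  for (k in 0:14) {
    d_code <- dirs[k %/% 3L + 1L]
    a_code <- atts[k %% 3L + 1L]
    t0 <- 7 * k
    ref <- if (k %% 2L == 0L) 2L else 3L
    a_ref <- NA_integer_
    if (k == 4L) {
      # attention-first alternation: gap 1.0 s, anchor at the attention onset
      add_ev(a_code, a_ref, t0, t0 + 0.6)
      add_ev(d_code, ref, t0 + 1.6, t0 + 2.6)
      add_exp(d_code, a_code, ref, "alternation", t0)
    } else if (k %% 2L == 0L) {
      # directional-first alternation with a 1.0 s gap
      add_ev(d_code, ref, t0, t0 + 1)
      add_ev(a_code, a_ref, t0 + 2, t0 + 2.6)
      add_exp(d_code, a_code, ref, "alternation", t0)
    } else {
      # attention event nested inside the directional state event
      add_ev(d_code, ref, t0, t0 + 2)
      add_ev(a_code, a_ref, t0 + 1, t0 + 1.6)
      add_exp(d_code, a_code, ref, "overlap", t0)
    }
  }
  # boundary probe 1: gap exactly 2.0 s -> included (inclusive bound)
  add_ev("gaze_box", 1L, 105, 106)
  add_ev("vocalize", NA, 108, 108.2)
  add_exp("gaze_box", "vocalize", 1L, "alternation", 105)
  # boundary probe 2: gap 2.2 s -> excluded
  add_ev("gaze_box", 4L, 112, 113)
  add_ev("gaze_owner", NA, 115.2, 115.4)
  log <- event_log(do.call(rbind, ev), pair = "FIX", session = 1L,
                   condition = "close", trial = 1L, phase = 1L,
                   phase_duration = 120)
  expected <- do.call(rbind, exp)
  o <- order(expected$anchor, expected$type_id, expected$referent)
  expected <- expected[o, , drop = FALSE]
  rownames(expected) <- NULL
  list(log = log, expected = expected)
}
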