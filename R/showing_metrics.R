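# Derived observation-level quantities.
#
# The unit of analysis (one "observation cell") is one pair x session x
# trial x phase. From the showings detected in that cell and the trial
# metadata we derive: showing counts by type, the correct-showing proportion
# (share of showings whose referent is the target box), the effort score,
# the owner-behavior count, the phase's choice and its success.

#' Effort class of a showing type
#'
#' Gaze alternation (gaze at box + gaze at owner, type 1) is the least
#' effortful strategy; the high-effort set comprises the three
#' jumping/standing-upright pairings plus move-towards-box +
#' move-towards-owner. Everything else is "other" and does not enter the
#' effort score.
#'
#' @param type_id Integer vector of showing type ids (1-15).
#' @return Character vector: `"low"`, `"high"` or `"other"`.
#' @export
classify_effort <- function(type_id) {
  if (any(is.na(type_id)) || any(!type_id %in% 1:15)) {
    stop("type_id must be in 1..15", call. = FALSE)
  }
  low_id <- classify_showing_type("gaze_box", "gaze_owner")
  high_id <- c(classify_showing_type("move_box", "move_owner"),
               classify_showing_type(rep("jump_box", 3L), attention_codes()))
  out <- rep("other", length(type_id))
  out[type_id %in% low_id] <- "low"
  out[type_id %in% high_id] <- "high"
  out
}

#' Showing effort score
#'
#' Frequency of high-effort showings relative to the summed frequencies of
#' high- and low-effort showings. Undefined (`NA`) when the cell contains
#' neither, in which case the row is excluded from effort models.
#'
#' @param showings Showings data.frame from one observation cell.
#' @return A single ratio in `[0, 1]`, or `NA` when no low- or high-effort
#'   showing occurred.
#' @export
effort_score <- function(showings) {
  cls <- if (nrow(showings)) classify_effort(showings$type_id) else character()
  n_high <- sum(cls == "high")
  n_low <- sum(cls == "low")
  if (n_high + n_low == 0L) return(NA_real_)
  n_high / (n_high + n_low)
}

.context_row <- function(contexts, pair, session, trial) {
  hit <- contexts$pair == pair & contexts$session == session &
    contexts$trial == trial
  if (sum(hit) != 1L) {
    stop(sprintf("no unique metadata row for pair %s session %s trial %s",
                 pair, session, trial), call. = FALSE)
  }
  contexts[hit, , drop = FALSE]
}

#' Score one observation cell
#'
#' @param showings Showings of one pair x session x trial x phase cell
#'   (possibly zero rows).
#' @param context One trial-metadata row (see [read_trial_metadata()]).
#' @param phase Phase of the cell, 1 or 2.
#' @param owner_behavior_count Number of owner-behavior events coded in the
#'   cell.
#' @return A one-row data.frame: identifiers, `n_type_1` .. `n_type_15`,
#'   `n_showings`, `n_correct_showings`, `prop_correct_showing` (`NA` when
#'   the cell has no showings), `n_low_effort`, `n_high_effort`, `effort`
#'   (`NA` when undefined), `owner_behavior_count`, `choice`, `success`.
#'   A choice of 0 (no box marked) is always scored as failure.
#' @export
score_showings <- function(showings, context, phase,
                           owner_behavior_count = 0L) {
  stopifnot(phase %in% 1:2)
  choice <- if (phase == 1L) context$choice_phase1 else context$choice_phase2
  if (is.na(choice)) {
    stop("missing choice for phase ", phase, call. = FALSE)
  }
  counts <- tabulate(showings$type_id, nbins = 15L)
  n_show <- sum(counts)
  n_correct <- sum(showings$referent == context$target_box)
  cls <- if (nrow(showings)) classify_effort(showings$type_id) else character()
  n_low <- sum(cls == "low"); n_high <- sum(cls == "high")
  out <- data.frame(pair = context$pair, session = context$session,
                    condition = context$condition, trial = context$trial,
                    phase = as.integer(phase), stringsAsFactors = FALSE)
  out[paste0("n_type_", 1:15)] <- as.list(counts)
  out$n_showings <- n_show
  out$n_correct_showings <- n_correct
  out$prop_correct_showing <- if (n_show > 0L) n_correct / n_show else NA_real_
  out$n_low_effort <- n_low
  out$n_high_effort <- n_high
  out$effort <- if (n_low + n_high > 0L) n_high / (n_high + n_low) else NA_real_
  out$owner_behavior_count <- as.integer(owner_behavior_count)
  out$choice <- as.integer(choice)
  out$success <- choice != 0L & choice == context$target_box
  out
}

#' Build the observation table from logs and metadata
#'
#' Runs [detect_showings()] on every log, counts owner-behavior events, and
#' scores each pair x session x trial x phase cell. The result is the single
#' input of the model layer.
#'
#' @param logs List of [event_log()] objects (both phases of every trial).
#' @param contexts Trial-metadata data.frame.
#' @param window Detector alternation window in seconds.
#' @return A data.frame with one [score_showings()] row per log.
#' @export
build_observation_table <- function(logs, contexts, window = 2) {
  rows <- lapply(logs, function(log) {
    sh <- detect_showings(log, window = window)
    ctx <- .context_row(contexts, log$pair, log$session, log$trial)
    n_owner <- sum(log$events$actor == "owner")
    score_showings(sh, ctx, log$phase, owner_behavior_count = n_owner)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach target, choice and correctness to each showing
#'
#' @param showings Combined showings data.frame.
#' @param contexts Trial-metadata data.frame.
#' @param use_phase2_choice If `TRUE`, the phase-2 opened box is used as the
#'   choice for showings of both phases; default is the phase-matched choice.
#' @return `showings` with added columns `target_box`, `choice`, `correct`
#'   (referent equals target) and `chosen` (referent equals choice).
#' @export
annotate_showings <- function(showings, contexts, use_phase2_choice = FALSE) {
  key_s <- paste(showings$pair, showings$session, showings$trial)
  key_c <- paste(contexts$pair, contexts$session, contexts$trial)
  idx <- match(key_s, key_c)
  if (any(is.na(idx))) {
    stop("showings reference trials absent from the metadata", call. = FALSE)
  }
  showings$target_box <- contexts$target_box[idx]
  ch1 <- contexts$choice_phase1[idx]
  ch2 <- contexts$choice_phase2[idx]
  showings$choice <- if (use_phase2_choice) ch2 else
    ifelse(showings$phase == 1L, ch1, ch2)
  showings$correct <- showings$referent == showings$target_box
  showings$chosen <- showings$choice != 0L & showings$referent == showings$choice
  showings
}

#' Per-type frequency, accuracy and choice rate
#'
#' Summary in the layout of a 15-type table: per showing type the mean
#' frequency per observation cell, the accuracy (share of that type's
#' showings directed at the target box) and the choice rate (share directed
#' at the box the owner chose in that phase). Types that never occur get
#' `NA` accuracy/choice rate and `occurs = FALSE`, the table's dash
#' convention.
#'
#' @param showings Annotated showings (see [annotate_showings()]).
#' @param n_cells Total number of observation cells the frequencies are
#'   averaged over (e.g. pairs x sessions x trials x phases).
#' @return A 15-row data.frame: `type_id`, `directional`, `attention`,
#'   `mean_frequency`, `accuracy`, `choice_rate`, `occurs`.
#' @export
summarize_types <- function(showings, n_cells) {
  stopifnot(n_cells > 0)
  tt <- showing_types()
  counts <- tabulate(showings$type_id, nbins = 15L)
  acc <- ch <- rep(NA_real_, 15L)
  for (k in 1:15) {
    sub <- showings[showings$type_id == k, , drop = FALSE]
    if (nrow(sub)) {
      acc[k] <- mean(sub$correct)
      ch[k] <- mean(sub$chosen)
    }
  }
  data.frame(tt,
             mean_frequency = counts / n_cells,
             accuracy = acc,
             choice_rate = ch,
             occurs = counts > 0L,
             stringsAsFactors = FALSE)
}

#' Cicchetti reliability band
#'
#' Conventional interpretation bands for correlation-based agreement:
#' below 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good, 0.75 and above
#' excellent.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Character vector of band labels (`NA` in, `NA` out).
#' @export
cicchetti_band <- function(r) {
  out <- rep(NA_character_, length(r))
  ok <- !is.na(r)
  out[ok] <- as.character(cut(r[ok], c(-Inf, 0.4, 0.6, 0.75, Inf),
                              labels = c("poor", "fair", "good", "excellent"),
                              right = FALSE))
  out
}

#' Inter-coder reliability by Spearman rank correlation
#'
#' Agreement between two observers who coded the same videos, one rank
#' correlation per behavior column (typically frequency and duration totals
#' per video), labelled with its Cicchetti band. A behavior that one coder
#' scored as constant across videos has an undefined rank correlation and is
#' flagged rather than dropped.
#'
#' @param coder_a,coder_b Numeric matrices or data.frames, videos in rows and
#'   behaviors in columns, identically laid out.
#' @return A data.frame with columns `behavior`, `rho`, `band`, `defined`.
#' @export
intercoder_reliability <- function(coder_a, coder_b) {
  a <- as.matrix(coder_a); b <- as.matrix(coder_b)
  if (!all(dim(a) == dim(b))) {
    stop("coder tables must have identical dimensions", call. = FALSE)
  }
  beh <- colnames(a)
  if (is.null(beh)) beh <- paste0("behavior_", seq_len(ncol(a)))
  rho <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }, numeric(1))
  data.frame(behavior = beh, rho = rho, band = cicchetti_band(rho),
             defined = !is.na(rho), stringsAsFactors = FALSE)
}

#' Per-pair success percentages
#'
#' Percentage of correct choices per pair within one phase, the input of the
#' one-sample test against the 25% chance level of a four-box choice.
#'
#' @param obs Observation table from [build_observation_table()].
#' @param phase Phase to score (1 or 2).
#' @return Named numeric vector, one percentage per pair.
#' @export
success_percent_by_pair <- function(obs, phase) {
  sub <- obs[obs$phase == phase, , drop = FALSE]
  100 * vapply(split(sub$success, as.character(sub$pair)), mean, numeric(1))
}
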