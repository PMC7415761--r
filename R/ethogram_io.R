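# Behavioral-coding event-log I/O and validation.
#
# Event logs are Solomon-Coder-style exports flattened to one long delimited
# table. Times are seconds from phase start on a 0.20 s grid; intervals are
# half-open [onset, offset), so abutting events do not overlap. A point event
# occupies exactly one frame (offset = onset + 0.20).

#' @importFrom stats aggregate as.formula coef cor logLik model.matrix na.omit
#'   optimize pchisq plogis pnorm pt qnorm quantile rbinom rexp rnorm rpois
#'   runif sd setNames t.test uniroot update var vcov AIC
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Behavior code sets
#'
#' The coded dog behaviors split into box-directed ("directional") components
#' and owner-directed ("attention-getting") components; all owner behaviors
#' collapse into the single composite code `owner_behavior`, counted by
#' frequency downstream. `retrieve` marks the dog fetching the toy itself and
#' terminates the analyzable window of its phase.
#'
#' @return A character vector of behavior codes.
#' @export
directional_codes <- function() {
  c("gaze_box", "move_box", "near_box", "jump_box", "open_box")
}

#' @rdname directional_codes
#' @export
attention_codes <- function() {
  c("gaze_owner", "move_owner", "vocalize")
}

#' @rdname directional_codes
#' @export
dog_codes <- function() {
  c(directional_codes(), attention_codes(), "retrieve")
}

#' @rdname directional_codes
#' @export
owner_codes <- function() "owner_behavior"

#' Coding-grid resolution in seconds
#' @export
grid_resolution <- function() 0.2

.box_directed <- function(code) code %in% directional_codes()

#' Snap a time to the coding grid
#'
#' Rounds a time in seconds to the nearest multiple of the coder's temporal
#' resolution (0.20 s by default). Exact midpoints round half up, so
#' `snap_to_grid(0.5)` is 0.6. Idempotent: snapping a snapped time is a
#' no-op.
#'
#' @param t Numeric vector of times in seconds, all non-negative.
#' @param resolution Grid resolution in seconds (> 0).
#' @return `t` rounded to the grid.
#' @examples
#' snap_to_grid(1.03)  # 1.0
#' snap_to_grid(0.50)  # 0.6 (tie rounds up)
#' @export
snap_to_grid <- function(t, resolution = grid_resolution()) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("snap_to_grid: times must be finite and non-negative", call. = FALSE)
  }
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0) {
    stop("snap_to_grid: resolution must be a single positive number", call. = FALSE)
  }
  # epsilon guards against 0.3/0.2 = 1.4999... style float droop at midpoints
  floor(t / resolution + 0.5 + 1e-9) * resolution
}

.on_grid <- function(t, resolution = grid_resolution()) {
  abs(t / resolution - round(t / resolution)) < 1e-6
}

#' Construct an event log for one pair x session x trial x phase
#'
#' @param events A data.frame with columns `actor`, `code`, `referent`
#'   (box id 1-4 or `NA`), `onset`, `offset` (seconds from phase start).
#'   Rows with `offset == onset` are treated as point events and expanded to
#'   one grid frame.
#' @param pair,session,condition,trial,phase Cell identifiers. `condition`
#'   is `"close"` or `"far"`; `phase` is 1 or 2.
#' @param phase_duration Length of the phase in seconds (60 in the standard
#'   procedure).
#' @param validate If `TRUE` (default), enforce the event invariants and
#'   error on the first violating row.
#' @return An object of class `event_log`: a list with the identifiers, the
#'   duration, and the canonically ordered `events` data.frame (by onset,
#'   then offset, then code).
#' @export
event_log <- function(events, pair, session, condition, trial, phase,
                      phase_duration = 60, validate = TRUE) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(actor = character(), code = character(),
                         referent = integer(), onset = numeric(),
                         offset = numeric(), stringsAsFactors = FALSE)
  }
  needed <- c("actor", "code", "referent", "onset", "offset")
  miss <- setdiff(needed, names(events))
  if (length(miss)) {
    stop("event_log: missing event columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  events <- events[needed]
  events$referent <- suppressWarnings(as.integer(events$referent))
  # canonicalize to the nearest decimal double so that identical coded times
  # compare exactly regardless of how they were computed (k * 0.2 vs parsed)
  events$onset <- round(as.numeric(events$onset), 6)
  events$offset <- round(as.numeric(events$offset), 6)
  pt <- !is.na(events$offset) & !is.na(events$onset) &
    abs(events$offset - events$onset) < 1e-9
  events$offset[pt] <- events$onset[pt] + grid_resolution()
  if (validate) .check_events(events, phase_duration)
  o <- order(events$onset, events$offset, events$code)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  structure(
    list(pair = pair, session = as.integer(session),
         condition = as.character(condition), trial = as.integer(trial),
         phase = as.integer(phase), phase_duration = phase_duration,
         events = events),
    class = "event_log"
  )
}

.check_events <- function(events, phase_duration) {
  fail <- function(i, what) {
    stop(sprintf("%s in event row %d (%s %s)", what, i,
                 events$actor[i], events$code[i]), call. = FALSE)
  }
  first <- function(bad) if (any(bad)) which(bad)[1L] else 0L
  i <- first(!events$actor %in% c("dog", "owner"))
  if (i) fail(i, "unknown actor")
  ok_code <- (events$actor == "dog" & events$code %in% dog_codes()) |
    (events$actor == "owner" & events$code %in% owner_codes())
  i <- first(!ok_code)
  if (i) fail(i, "unknown behavior code")
  i <- first(is.na(events$onset) | is.na(events$offset) |
               events$onset < 0 | events$offset < events$onset)
  if (i) fail(i, "invalid interval")
  i <- first(!.on_grid(events$onset) | !.on_grid(events$offset))
  if (i) fail(i, "timestamp not on 0.20 s grid (use snap_to_grid or snap = TRUE)")
  boxy <- .box_directed(events$code)
  i <- first(boxy & (is.na(events$referent) | !events$referent %in% 1:4))
  if (i) fail(i, "box-directed code needs referent 1-4")
  i <- first(!boxy & !is.na(events$referent))
  if (i) fail(i, "non-box code must have empty referent")
  invisible(TRUE)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> pair %s session %d %s trial %d phase %d (%.1f s, %d events)\n",
              as.character(x$pair), x$session, x$condition, x$trial, x$phase,
              x$phase_duration, nrow(x$events)))
  invisible(x)
}

.log_key <- function(log) {
  sprintf("%s.%d.%d.%d", as.character(log$pair), log$session, log$trial, log$phase)
}

#' Read a long-table behavioral event file
#'
#' Ingests the long-table dialect: one row per coded behavior occurrence with
#' columns `pair, session, condition, trial, phase, actor, code, referent,
#' onset, offset` (CSV, or TSV if the path ends in `.tsv`). Rows are grouped
#' into one [event_log] per pair x session x trial x phase.
#'
#' @param path Path to the delimited file.
#' @param phase_duration Phase length in seconds, recycled to every log.
#' @param snap If `TRUE`, snap off-grid timestamps to the 0.20 s grid instead
#'   of erroring.
#' @return A list of `event_log` objects, ordered by pair, session, trial,
#'   phase.
#' @export
read_event_log <- function(path, phase_duration = 60, snap = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("pair", "session", "condition", "trial", "phase",
              "actor", "code", "referent", "onset", "offset")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop("event file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) return(list())
  tab$onset <- as.numeric(tab$onset)
  tab$offset <- as.numeric(tab$offset)
  if (snap) {
    tab$onset <- snap_to_grid(tab$onset)
    tab$offset <- snap_to_grid(tab$offset)
  } else {
    bad <- which(!.on_grid(tab$onset) | !.on_grid(tab$offset))
    if (length(bad)) {
      stop(sprintf("row %d: timestamp not on 0.20 s grid", bad[1L]),
           call. = FALSE)
    }
  }
  key <- interaction(tab$pair, tab$session, tab$trial, tab$phase, drop = TRUE)
  pieces <- split(tab, key)
  logs <- lapply(pieces, function(p) {
    event_log(p[c("actor", "code", "referent", "onset", "offset")],
              pair = p$pair[1L], session = p$session[1L],
              condition = p$condition[1L], trial = p$trial[1L],
              phase = p$phase[1L], phase_duration = phase_duration)
  })
  ord <- order(vapply(logs, function(l) as.character(l$pair), ""),
               vapply(logs, function(l) l$session, 1L),
               vapply(logs, function(l) l$trial, 1L),
               vapply(logs, function(l) l$phase, 1L))
  unname(logs[ord])
}

#' Write event logs back to the long-table dialect
#'
#' Inverse of [read_event_log()]; times are printed with two decimals, which
#' is exact on the 0.20 s grid, so a write/read round trip reproduces every
#' field.
#'
#' @param logs A list of `event_log` objects.
#' @param path Output path (`.tsv` selects tab separation).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(logs, path) {
  rows <- lapply(logs, function(log) {
    ev <- log$events
    if (nrow(ev) == 0L) return(NULL)
    data.frame(pair = log$pair, session = log$session,
               condition = log$condition, trial = log$trial,
               phase = log$phase, actor = ev$actor, code = ev$code,
               referent = ev$referent,
               onset = sprintf("%.2f", ev$onset),
               offset = sprintf("%.2f", ev$offset),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pair = character(), session = integer(),
                      condition = character(), trial = integer(),
                      phase = integer(), actor = character(),
                      code = character(), referent = integer(),
                      onset = character(), offset = character())
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

#' Trial metadata constructor and I/O
#'
#' One metadata row per pair x session x trial: condition, target box, the
#' phase-1 questionnaire choice (0 = no box marked, scored incorrect), the
#' phase-2 opened box, whether the dog retrieved the toy itself, and the two
#' phase durations. If the dog retrieved in phase 1 the retrieved (target)
#' box stands as the choice for both phases.
#'
#' @param path Path to a CSV with columns `pair, session, condition, trial,
#'   target_box, choice_phase1, choice_phase2, dog_retrieved, dur_phase1,
#'   dur_phase2`.
#' @return A data.frame of trial contexts.
#' @export
read_trial_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("pair", "session", "condition", "trial", "target_box",
              "choice_phase1", "choice_phase2", "dog_retrieved",
              "dur_phase1", "dur_phase2")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop("metadata file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$dog_retrieved <- as.logical(tab$dog_retrieved)
  tab
}

#' @rdname read_trial_metadata
#' @param contexts Data.frame of trial contexts.
#' @export
write_trial_metadata <- function(contexts, path) {
  write.csv(contexts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a full dataset of event logs against the design
#'
#' Report-only dataset audit. Per log it flags events outside the phase
#' window and overlapping state events of the same code and referent; at the
#' design level it flags the same box being target in two consecutive trials
#' of a session and any box that is not target exactly twice for a pair.
#' Design flags are warnings, not errors, mirroring coding practice where an
#' imperfectly balanced session is analysed anyway.
#'
#' @param logs List of `event_log` objects.
#' @param contexts Optional trial-metadata data.frame for the design checks.
#' @return A data.frame with columns `pair, session, trial, phase, severity,
#'   message`; zero rows when the dataset is clean.
#' @export
validate_dataset <- function(logs, contexts = NULL) {
  out <- list()
  note <- function(pair, session, trial, phase, severity, message) {
    out[[length(out) + 1L]] <<- data.frame(
      pair = as.character(pair), session = session, trial = trial,
      phase = phase, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  for (log in logs) {
    ev <- log$events
    outside <- which(ev$onset < 0 | ev$offset > log$phase_duration + 1e-9)
    for (i in outside) {
      note(log$pair, log$session, log$trial, log$phase, "error",
           sprintf("event %s [%.2f,%.2f) outside phase window [0,%.2f]",
                   ev$code[i], ev$onset[i], ev$offset[i], log$phase_duration))
    }
    grp <- split(seq_len(nrow(ev)),
                 paste(ev$code, ifelse(is.na(ev$referent), 0L, ev$referent)))
    for (idx in grp) {
      if (length(idx) < 2L) next
      on <- ev$onset[idx]; off <- ev$offset[idx]
      o <- order(on, off)
      on <- on[o]; off <- off[o]
      if (any(on[-1L] < cummax(off[-length(off)]) - 1e-9)) {
        note(log$pair, log$session, log$trial, log$phase, "error",
             sprintf("overlapping state events of code %s", ev$code[idx[1L]]))
      }
    }
  }
  if (!is.null(contexts)) {
    for (p in unique(contexts$pair)) {
      sub <- contexts[contexts$pair == p, ]
      for (s in unique(sub$session)) {
        tr <- sub[sub$session == s, ]
        tr <- tr[order(tr$trial), ]
        rep_idx <- which(diff(tr$target_box) == 0)
        for (i in rep_idx) {
          note(p, s, tr$trial[i + 1L], NA_integer_, "warning",
               "same box target in two consecutive trials of a session")
        }
      }
      tb <- table(factor(sub$target_box, levels = 1:4))
      if (any(tb != nrow(sub) / 4)) {
        note(p, NA_integer_, NA_integer_, NA_integer_, "warning",
             "boxes are not each target equally often for this pair")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pair = character(), session = integer(),
                      trial = integer(), phase = integer(),
                      severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
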