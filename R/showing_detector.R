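# Showing detection.
#
# A showing is one directional (box-referencing) dog behavior paired with one
# attention-getting (owner-directed) dog behavior, either overlapping in time
# or alternating with a gap of at most two seconds. Every qualifying
# (directional, attention) event pair counts once; one event may take part in
# several showings with different partners. Component order never matters.

#' The 15 showing types
#'
#' Row-major crossing of the five directional components with the three
#' attention-getting components: type 1 is gaze-at-box + gaze-at-owner
#' (classic gaze alternation), type 15 is open-box + vocalize.
#'
#' @return A data.frame with columns `type_id`, `directional`, `attention`.
#' @export
showing_types <- function() {
  data.frame(
    type_id = 1:15,
    directional = rep(directional_codes(), each = 3L),
    attention = rep(attention_codes(), times = 5L),
    stringsAsFactors = FALSE
  )
}

#' Classify a (directional, attention) combination into its showing type
#'
#' @param directional_code Code(s) from [directional_codes()].
#' @param attention_code Code(s) from [attention_codes()].
#' @return Integer type id(s) in 1-15.
#' @examples
#' classify_showing_type("gaze_box", "gaze_owner")  # 1
#' classify_showing_type("open_box", "vocalize")    # 15
#' @export
classify_showing_type <- function(directional_code, attention_code) {
  di <- match(directional_code, directional_codes())
  ai <- match(attention_code, attention_codes())
  if (any(is.na(di))) {
    stop("not a directional component: ",
         paste(unique(directional_code[is.na(di)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ai))) {
    stop("not an attention-getting component: ",
         paste(unique(attention_code[is.na(ai)]), collapse = ", "),
         call. = FALSE)
  }
  as.integer((di - 1L) * 3L + ai)
}

# Vectorized qualification of interval pairs; intervals are half-open
# [onset, offset) in seconds. The 2 s alternation bound is inclusive
# (gap <= window qualifies); a pair that both overlaps and alternates is
# reported once, as "overlap".
.qualify_vec <- function(d_on, d_off, a_on, a_off, window) {
  overlap <- pmax(d_on, a_on) < pmin(d_off, a_off)
  gap <- ifelse(d_off <= a_on, a_on - d_off, d_on - a_off)
  out <- rep("none", length(d_on))
  out[!overlap & gap <= window + 1e-9] <- "alternation"
  out[overlap] <- "overlap"
  out
}

#' Does a directional/attention interval pair qualify as showing?
#'
#' @param d,a Numeric length-2 vectors `c(onset, offset)` in seconds for the
#'   directional and the attention-getting component. Order of arguments is
#'   immaterial.
#' @param window Maximum alternation gap in seconds (inclusive bound;
#'   default 2).
#' @return `"overlap"` if the half-open intervals intersect, `"alternation"`
#'   if they are disjoint with a gap of at most `window` seconds, else
#'   `"none"`.
#' @examples
#' intervals_qualify(c(1, 2), c(2.5, 3))    # alternation (gap 0.5 s)
#' intervals_qualify(c(1, 2), c(1.5, 3))    # overlap
#' intervals_qualify(c(1, 2), c(4.2, 4.4))  # none (gap 2.2 s)
#' @export
intervals_qualify <- function(d, a, window = 2) {
  if (length(window) != 1L || !is.finite(window) || window < 0) {
    stop("window must be a single non-negative number", call. = FALSE)
  }
  if (length(d) != 2L || length(a) != 2L || !all(is.finite(d)) ||
      !all(is.finite(a)) || d[2L] < d[1L] || a[2L] < a[1L]) {
    stop("interval must be c(onset, offset) with onset <= offset",
         call. = FALSE)
  }
  if (max(d[1L], a[1L]) < min(d[2L], a[2L])) return("overlap")
  gap <- if (d[2L] <= a[1L]) a[1L] - d[2L] else d[1L] - a[2L]
  if (gap <= window + 1e-9) "alternation" else "none"
}

# Drop/truncate events at the onset of the first retrieve: once the dog has
# fetched the toy the trial outcome is fixed and later behavior is not
# communication about the hiding place.
.truncate_at_retrieve <- function(ev) {
  ret <- ev$actor == "dog" & ev$code == "retrieve"
  if (!any(ret)) return(ev)
  tcut <- min(ev$onset[ret])
  ev <- ev[ev$onset < tcut - 1e-9, , drop = FALSE]
  ev$offset <- pmin(ev$offset, tcut)
  ev[ev$offset > ev$onset + 1e-9, , drop = FALSE]
}

.showing_frame <- function(log, di, ai, mode, dev, aev) {
  out <- data.frame(
    pair = if (is.null(log$pair)) NA else log$pair,
    session = if (is.null(log$session)) NA_integer_ else log$session,
    condition = if (is.null(log$condition)) NA_character_ else log$condition,
    trial = if (is.null(log$trial)) NA_integer_ else log$trial,
    phase = if (is.null(log$phase)) NA_integer_ else log$phase,
    type_id = classify_showing_type(dev$code[di], aev$code[ai]),
    directional = dev$code[di],
    attention = aev$code[ai],
    referent = dev$referent[di],
    mode = mode,
    anchor = pmin(dev$onset[di], aev$onset[ai]),
    directional_id = dev$.id[di],
    attention_id = aev$.id[ai],
    stringsAsFactors = FALSE
  )
  o <- order(out$anchor, out$type_id, out$referent,
             out$directional_id, out$attention_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_showings <- function() {
  data.frame(pair = character(), session = integer(), condition = character(),
             trial = integer(), phase = integer(), type_id = integer(),
             directional = character(), attention = character(),
             referent = integer(), mode = character(), anchor = numeric(),
             directional_id = integer(), attention_id = integer(),
             stringsAsFactors = FALSE)
}

.split_components <- function(log) {
  ev <- log$events
  ev$.id <- seq_len(nrow(ev))
  ev <- .truncate_at_retrieve(ev[ev$actor == "dog", , drop = FALSE])
  list(d = ev[ev$code %in% directional_codes(), , drop = FALSE],
       a = ev[ev$code %in% attention_codes(), , drop = FALSE])
}

#' Detect showing events in one event log
#'
#' Pairs every directional dog event with every attention-getting dog event
#' that overlaps it or alternates with it within `window` seconds. Each
#' qualifying pair is one showing; a long state event (e.g. staying near a
#' box) can therefore anchor several showings with successive attention
#' events. Owner events are ignored; everything from the first `retrieve`
#' onset onward is cut away before pairing. Output is in canonical order
#' (anchor, type id, referent), so repeated runs are byte-identical.
#'
#' @param log An [event_log()].
#' @param window Alternation window in seconds (inclusive; default 2).
#' @return A data.frame of showings: cell identifiers, `type_id`,
#'   `directional`, `attention`, `referent` (the directional event's box),
#'   `mode` (`"overlap"`/`"alternation"`), `anchor` (onset of the earlier
#'   component) and the two source event row ids.
#' @export
detect_showings <- function(log, window = 2) {
  if (length(window) != 1L || !is.finite(window) || window < 0) {
    stop("window must be a single non-negative number", call. = FALSE)
  }
  comp <- .split_components(log)
  dev <- comp$d; aev <- comp$a
  if (nrow(dev) == 0L || nrow(aev) == 0L) return(.empty_showings())
  di <- rep(seq_len(nrow(dev)), each = nrow(aev))
  ai <- rep(seq_len(nrow(aev)), times = nrow(dev))
  mode <- .qualify_vec(dev$onset[di], dev$offset[di],
                       aev$onset[ai], aev$offset[ai], window)
  keep <- mode != "none"
  if (!any(keep)) return(.empty_showings())
  .showing_frame(log, di[keep], ai[keep], mode[keep], dev, aev)
}

#' Literal all-pairs reference detector
#'
#' Quadratic scan that applies [intervals_qualify()] to every
#' (directional, attention) event pair one at a time, with the same
#' truncation and canonical ordering as [detect_showings()]. Kept as an
#' independent route for equivalence testing; use [detect_showings()] in
#' analyses.
#'
#' @inheritParams detect_showings
#' @return Same shape as [detect_showings()].
#' @export
brute_force_detect <- function(log, window = 2) {
  comp <- .split_components(log)
  dev <- comp$d; aev <- comp$a
  di <- integer(); ai <- integer(); mode <- character()
  if (nrow(dev) && nrow(aev)) {
    for (i in seq_len(nrow(dev))) {
      for (j in seq_len(nrow(aev))) {
        q <- intervals_qualify(c(dev$onset[i], dev$offset[i]),
                               c(aev$onset[j], aev$offset[j]), window)
        if (q != "none") {
          di <- c(di, i); ai <- c(ai, j); mode <- c(mode, q)
        }
      }
    }
  }
  if (!length(di)) return(.empty_showings())
  .showing_frame(log, di, ai, mode, dev, aev)
}

#' Detect showings across a list of logs
#'
#' @param logs List of [event_log()] objects.
#' @inheritParams detect_showings
#' @return One combined showings data.frame.
#' @export
detect_showings_all <- function(logs, window = 2) {
  parts <- lapply(logs, detect_showings, window = window)
  out <- do.call(rbind, c(list(.empty_showings()), parts))
  rownames(out) <- NULL
  out
}

#' Write a showings table
#'
#' @param showings Data.frame from [detect_showings_all()].
#' @param path Output CSV path.
#' @export
write_showings <- function(showings, path) {
  out <- showings
  out$anchor <- sprintf("%.2f", out$anchor)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
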