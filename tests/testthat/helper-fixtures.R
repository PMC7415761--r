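# Shared fixture builders; everything is generated in code under a seed the
# caller controls.

# Random single-phase log: mostly directional and attention dog events, a
# sprinkling of owner events (which detection must ignore) and, optionally,
# retrieve events. `grid` may be finer than the coding grid to stress the
# detectors off the 0.20 s lattice; validation is skipped in that case.
random_log <- function(n_events, t_max = 60, grid = 0.2,
                       p_retrieve_event = 0) {
  codes <- c(directional_codes(), attention_codes())
  code <- sample(codes, n_events, replace = TRUE)
  actor <- rep("dog", n_events)
  owner <- runif(n_events) < 0.1
  code[owner] <- "owner_behavior"
  actor[owner] <- "owner"
  if (p_retrieve_event > 0) {
    ret <- !owner & runif(n_events) < p_retrieve_event
    code[ret] <- "retrieve"
  }
  onset <- sample.int(round(t_max / grid) - 1L, n_events, replace = TRUE) * grid
  len <- sample.int(25L, n_events, replace = TRUE) * grid
  offset <- pmin(onset + len, t_max)
  referent <- ifelse(code %in% directional_codes(),
                     sample(1:4, n_events, replace = TRUE), NA_integer_)
  ev <- data.frame(actor = actor, code = code, referent = referent,
                   onset = onset, offset = offset, stringsAsFactors = FALSE)
  event_log(ev, pair = "R1", session = 1L, condition = "close", trial = 1L,
            phase = 1L, phase_duration = t_max,
            validate = abs(grid - 0.2) < 1e-9)
}

# Minimal one-trial metadata row.
one_context <- function(target = 2L, choice1 = 2L, choice2 = 2L,
                        pair = "P01", session = 1L, condition = "close",
                        trial = 1L) {
  data.frame(pair = pair, session = session, condition = condition,
             trial = trial, target_box = target, choice_phase1 = choice1,
             choice_phase2 = choice2, dog_retrieved = FALSE,
             dur_phase1 = 60, dur_phase2 = 60, stringsAsFactors = FALSE)
}

# Columns on which detector outputs are compared as multisets.
showing_cols <- c("type_id", "directional", "attention", "referent",
                  "mode", "anchor", "directional_id", "attention_id")

expect_same_showings <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a[showing_cols], b[showing_cols],
               ignore_attr = TRUE)
}
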