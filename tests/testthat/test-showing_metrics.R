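test_that("effort classes follow the low/high definitions", {
  expect_equal(classify_effort(classify_showing_type("gaze_box", "gaze_owner")),
               "low")
  expect_equal(classify_effort(classify_showing_type("jump_box", "vocalize")),
               "high")
  expect_equal(classify_effort(classify_showing_type("move_box", "move_owner")),
               "high")
  expect_equal(classify_effort(classify_showing_type("near_box", "gaze_owner")),
               "other")
  # exactly one low and four high types among the 15
  cls <- classify_effort(1:15)
  expect_equal(sum(cls == "low"), 1L)
  expect_equal(sum(cls == "high"), 4L)
  expect_error(classify_effort(16L), "1..15")
})

test_that("effort score is high / (high + low), undefined on empty denominator", {
  mk <- function(type_ids) data.frame(type_id = type_ids)
  jump <- classify_showing_type("jump_box", "gaze_owner")
  gaze <- classify_showing_type("gaze_box", "gaze_owner")
  other <- classify_showing_type("near_box", "gaze_owner")
  expect_equal(effort_score(mk(c(rep(jump, 3), gaze))), 0.75)
  expect_equal(effort_score(mk(rep(gaze, 5))), 0)
  expect_true(is.na(effort_score(mk(rep(other, 4)))))
  expect_true(is.na(effort_score(mk(integer(0)))))
})

test_that("score_showings fills the observation row", {
  ctx <- one_context(target = 2L, choice1 = 2L, choice2 = 3L)
  sh <- data.frame(type_id = c(1L, 1L, 1L, 4L),
                   referent = c(2L, 2L, 2L, 3L))
  row <- score_showings(sh, ctx, phase = 1)
  expect_equal(row$n_showings, 4L)
  expect_equal(row$prop_correct_showing, 0.75)
  expect_equal(row$n_type_1, 3L)
  expect_true(row$success)
  expect_equal(sum(as.numeric(row[paste0("n_type_", 1:15)])), row$n_showings)

  # phase 2 choice differs
  row2 <- score_showings(sh, ctx, phase = 2)
  expect_false(row2$success)

  # zero showings: proportion missing, success still computable
  empty <- sh[0, ]
  row3 <- score_showings(empty, ctx, phase = 1)
  expect_true(is.na(row3$prop_correct_showing))
  expect_true(is.na(row3$effort))
  expect_true(row3$success)

  # a choice of 0 is always a failure
  ctx0 <- one_context(target = 2L, choice1 = 0L)
  expect_false(score_showings(sh, ctx0, phase = 1)$success)
  ctxna <- one_context(choice1 = NA_integer_)
  expect_error(score_showings(sh, ctxna, phase = 1), "missing choice")
})

test_that("summarize_types reproduces accuracy/choice rate from raw showings", {
  ctx <- one_context(target = 2L, choice1 = 3L, choice2 = 3L)
  sh <- data.frame(pair = "P01", session = 1L, condition = "close",
                   trial = 1L, phase = 1L,
                   type_id = c(1L, 1L, 4L, 4L, 4L),
                   referent = c(2L, 3L, 2L, 2L, 3L))
  ann <- annotate_showings(sh, ctx)
  ts <- summarize_types(ann, n_cells = 2)
  expect_equal(ts$accuracy[1], 0.5)          # type 1: one of two at target
  expect_equal(ts$choice_rate[1], 0.5)       # ... and one at the chosen box
  expect_equal(ts$accuracy[4], 2 / 3)
  expect_equal(ts$mean_frequency[1], 1)      # 2 showings over 2 cells
  expect_false(ts$occurs[15])
  expect_true(is.na(ts$accuracy[15]))        # never-occurring type flagged
  # direct recount oracle for every type
  for (k in 1:15) {
    sub <- ann[ann$type_id == k, ]
    if (nrow(sub)) expect_equal(ts$accuracy[k], mean(sub$referent == 2L))
  }
})

test_that("consistent box relabeling leaves derived scores invariant", {
  set.seed(31)
  perm <- c(3L, 1L, 4L, 2L)  # box relabeling
  log <- random_log(80)
  ctx <- one_context(target = 2L, choice1 = 2L, choice2 = 4L,
                     pair = "R1")
  row <- score_showings(detect_showings(log), ctx, 1)

  plog <- log
  box <- plog$events$code %in% directional_codes()
  plog$events$referent[box] <- perm[plog$events$referent[box]]
  pctx <- ctx
  pctx$target_box <- perm[ctx$target_box]
  pctx$choice_phase1 <- perm[ctx$choice_phase1]
  pctx$choice_phase2 <- perm[ctx$choice_phase2]
  prow <- score_showings(detect_showings(plog), pctx, 1)

  expect_equal(prow$prop_correct_showing, row$prop_correct_showing)
  expect_equal(prow$effort, row$effort)
  expect_equal(prow$success, row$success)
  expect_equal(prow$n_showings, row$n_showings)
})

test_that("intercoder reliability gives Spearman rho with Cicchetti bands", {
  a <- data.frame(gazes = c(3, 7, 2, 9, 5, 1), moves = c(1, 2, 3, 4, 5, 6))
  r_same <- intercoder_reliability(a, a)
  expect_equal(r_same$rho, c(1, 1))
  expect_equal(r_same$band, c("excellent", "excellent"))

  rev <- data.frame(gazes = -a$gazes, moves = -a$moves)
  expect_equal(intercoder_reliability(a, rev)$rho, c(-1, -1))

  expect_equal(cicchetti_band(c(0.74, 0.75, 0.39, 0.40, 0.60)),
               c("good", "excellent", "poor", "fair", "good"))

  const <- data.frame(gazes = rep(2, 6), moves = 1:6)
  r_const <- intercoder_reliability(const, a)
  expect_false(r_const$defined[1])
  expect_true(is.na(r_const$rho[1]))

  expect_error(intercoder_reliability(a, a[1:3, ]), "identical dimensions")
})

test_that("success_percent_by_pair aggregates per pair and phase", {
  obs <- data.frame(pair = rep(c("A", "B"), each = 4),
                    phase = rep(c(1, 2), 4),
                    success = c(TRUE, TRUE, FALSE, TRUE,
                                TRUE, FALSE, TRUE, FALSE))
  s1 <- success_percent_by_pair(obs, 1)
  expect_equal(unname(s1), c(50, 100))
  expect_equal(names(s1), c("A", "B"))
})
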