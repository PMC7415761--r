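test_that("snap_to_grid rounds to the 0.20 s grid with half-up ties", {
  expect_equal(snap_to_grid(1.03), 1.0)
  expect_equal(snap_to_grid(0), 0)
  expect_equal(snap_to_grid(0.50), 0.6)
  expect_equal(snap_to_grid(0.30), 0.4)
  expect_equal(snap_to_grid(c(1.03, 2.49, 2.51)), c(1.0, 2.4, 2.6))
  expect_error(snap_to_grid(-0.1), "non-negative")
  expect_error(snap_to_grid(1, resolution = 0), "positive")
})

test_that("snap_to_grid is idempotent over a dense sweep", {
  t <- seq(0, 30, by = 0.01)
  once <- snap_to_grid(t)
  expect_equal(snap_to_grid(once), once)
  expect_true(all(abs(once / 0.2 - round(once / 0.2)) < 1e-9))
})

test_that("event_log enforces the event invariants", {
  ev <- data.frame(actor = "dog", code = "gaze_box", referent = 2L,
                   onset = 1.0, offset = 2.0)
  log <- event_log(ev, "P01", 1, "close", 1, 1)
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log$events), 1L)

  bad_grid <- transform(ev, onset = 1.03)
  expect_error(event_log(bad_grid, "P01", 1, "close", 1, 1), "grid")
  bad_code <- transform(ev, code = "wag_tail")
  expect_error(event_log(bad_code, "P01", 1, "close", 1, 1), "unknown behavior")
  bad_ref <- transform(ev, referent = NA_integer_)
  expect_error(event_log(bad_ref, "P01", 1, "close", 1, 1), "referent")
  bad_ref2 <- data.frame(actor = "dog", code = "vocalize", referent = 1L,
                         onset = 1.0, offset = 1.4)
  expect_error(event_log(bad_ref2, "P01", 1, "close", 1, 1), "empty referent")

  # a point event occupies one frame
  pt <- data.frame(actor = "dog", code = "vocalize", referent = NA_integer_,
                   onset = 1.0, offset = 1.0)
  log <- event_log(pt, "P01", 1, "close", 1, 1)
  expect_equal(log$events$offset, 1.2)
})

test_that("read_event_log handles single rows, empty files and bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair,session,condition,trial,phase,actor,code,referent,onset,offset",
               "P01,1,close,1,1,dog,gaze_box,2,1.0,2.0"), path)
  logs <- read_event_log(path)
  expect_length(logs, 1L)
  expect_equal(logs[[1]]$events$code, "gaze_box")
  expect_equal(logs[[1]]$events$referent, 2L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("pair,session,condition,trial,phase,actor,code,referent,onset,offset",
             empty)
  expect_identical(read_event_log(empty), list())

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair,session,trial,phase,actor,code,referent,onset,offset",
               "P01,1,1,1,dog,gaze_box,2,1.0,2.0"), nocol)
  expect_error(read_event_log(nocol), "lacks column")

  offgrid <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair,session,condition,trial,phase,actor,code,referent,onset,offset",
               "P01,1,close,1,1,dog,gaze_box,2,1.03,2.0"), offgrid)
  expect_error(read_event_log(offgrid), "grid")
  snapped <- read_event_log(offgrid, snap = TRUE)
  expect_equal(snapped[[1]]$events$onset, 1.0)
})

test_that("write/read round trip reproduces events exactly and stays sorted", {
  set.seed(11)
  logs <- lapply(1:4, function(i) {
    log <- random_log(40)
    log$pair <- sprintf("P%02d", i)
    log
  })
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(logs, path)
  back <- read_event_log(path)
  expect_length(back, 4L)
  for (i in 1:4) {
    expect_identical(back[[i]]$events, logs[[i]]$events)
    ev <- back[[i]]$events
    expect_true(!is.unsorted(ev$onset))
  }
  # re-serialization is stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_event_log(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("validate_dataset flags window, overlap and design violations", {
  ok <- event_log(data.frame(actor = "dog", code = "gaze_box", referent = 1L,
                             onset = 1, offset = 2),
                  "P01", 1, "close", 1, 1, phase_duration = 60)
  expect_equal(nrow(validate_dataset(list(ok))), 0L)

  outside <- event_log(data.frame(actor = "dog", code = "gaze_box",
                                  referent = 1L, onset = 58, offset = 61),
                       "P01", 1, "close", 1, 1, phase_duration = 60)
  rep1 <- validate_dataset(list(outside))
  expect_equal(nrow(rep1), 1L)
  expect_match(rep1$message, "outside phase window")

  twice <- event_log(data.frame(actor = "dog", code = "near_box",
                                referent = c(1L, 1L), onset = c(0, 3),
                                offset = c(5, 8)),
                     "P01", 1, "close", 1, 1)
  rep2 <- validate_dataset(list(twice))
  expect_match(rep2$message, "overlapping state events")

  ctx <- rbind(one_context(trial = 1L, target = 3L),
               one_context(trial = 2L, target = 2L),
               one_context(trial = 3L, target = 2L),
               one_context(trial = 4L, target = 4L))
  rep3 <- validate_dataset(list(), ctx)
  expect_true(any(grepl("consecutive trials", rep3$message)))
  expect_true(all(rep3$severity == "warning"))
})
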