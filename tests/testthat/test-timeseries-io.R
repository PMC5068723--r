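test_that("zeitgeber time is anchored to lights-on", {
  sch <- ld6()
  expect_equal(zt_of(T0, sch), 0)                       # lights-on -> ZT 0
  expect_equal(zt_of(T0 + 18 * 3600, sch), 18)          # midnight -> ZT 18
  expect_equal(zt_of(T0 + 12 * 3600, sch), 12)          # dark onset
  # mid-dark = ZT 18 under 12:12 with ZT0 at lights-on
  pp <- sch$segments$photoperiod[1]
  expect_identical(pp + (24 - pp) / 2, 18)
  # periodic within a segment
  tq <- T0 + c(5, 29, 53) * 3600
  expect_equal(zt_of(tq, sch), rep(5, 3))
  expect_error(zt_of(T0 - 1, sch), "outside")
})

test_that("ZT follows the new schedule after a phase advance and extrapolates in DD", {
  pa <- phase_advance_schedule(T0, pre_days = 3, post_days = 4)
  # new lights-on clock is 00:00; a 06:00 query in the shifted segment -> ZT 6
  q <- as.POSIXct("2020-01-05 06:00:00", tz = "UTC")
  expect_equal(zt_of(q, pa), 6)
  dd <- dd_after_ld()
  # 2 days into DD, 18:00 clock is still subjective ZT 12
  expect_equal(zt_of(T0 + 2 * 86400 + 12 * 3600, dd), 12)
  expect_equal(regime_of(T0 + 2 * 86400, dd), "DD")
})

test_that("dark onsets enumerate cycles", {
  sch <- ld6()
  dk <- dark_onsets(sch)
  expect_length(dk, 6)
  expect_equal(zt_of(dk, sch), rep(12, 6))
})

test_that("event files round-trip and malformed rows are dropped with a report", {
  sch <- ld6()
  set.seed(1)
  ts <- T0 + sort(stats::runif(100, 0, 86400))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(event_stream("m1", ts, 1:4), f)
  rt <- read_events(f)
  expect_named(rt, "m1")
  expect_length(rt$m1$timestamp, 100)
  expect_equal(as.numeric(rt$m1$timestamp), as.numeric(ts), tolerance = 1e-3)

  # corrupt one timestamp among 100 -> 99 events and a logged drop
  df <- utils::read.csv(f)
  df$timestamp[50] <- "not-a-time"
  utils::write.csv(df, f, row.names = FALSE)
  expect_message(rt2 <- read_events(f), "dropped 1 row")
  expect_length(rt2$m1$timestamp, 99)

  # all timestamps bad -> format error naming the first failing row
  df$timestamp <- "nope"
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_events(f), "row 1")
  writeLines("animal_id,timestamp,antenna_id", f)
  expect_error(read_events(f), "no data rows")
})

test_that("streams split per animal and collapse exact duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,timestamp,antenna_id",
               "a,2020-01-01T10:00:00,1",
               "b,2020-01-01T11:00:00,2",
               "a,2020-01-01T12:00:00,1"), f)
  st <- read_events(f)
  expect_named(st, c("a", "b"))
  expect_length(st$a$timestamp, 2)
  expect_length(st$b$timestamp, 1)
  dup <- event_stream("x", T0 + c(10, 10, 20), c(1, 1, 1))
  expect_length(dup$timestamp, 2)
})

test_that("binning is half-open on epoch boundaries and conserves events", {
  sch <- ld6()
  st <- event_stream("m", T0 + c(0, 299, 300, 86399))
  b <- bin_events(st, sch, T0, T0 + 86400)
  expect_equal(b$counts[1], 2)   # t = 0 s and t = 299 s share epoch 0
  expect_equal(b$counts[2], 1)   # t = 300 s opens epoch 1
  expect_equal(sum(b$counts), 4)
  expect_equal(length(b$counts), 288)
  # 72-h window at 5-min epochs
  b72 <- bin_events(st, sch, T0, T0 + 72 * 3600)
  expect_length(b72$counts, 864)
  # empty window -> all zeros of expected length
  b0 <- bin_events(event_stream("m", T0[0]), sch, T0, T0 + 86400)
  expect_equal(sum(b0$counts), 0)
  expect_length(b0$counts, 288)
  expect_error(bin_events(st, sch, T0 - 86400, T0), "outside")
  expect_error(bin_events(st, sch, T0, T0 + 450), "whole number")
})

test_that("rebinning at a multiple epoch equals direct binning at that epoch", {
  sch <- ld6()
  set.seed(2)
  st <- event_stream("m", T0 + sort(stats::runif(500, 0, 2 * 86400)))
  fine <- bin_events(st, sch, T0, T0 + 2 * 86400, epoch_seconds = 300)
  coarse <- bin_events(st, sch, T0, T0 + 2 * 86400, epoch_seconds = 900)
  agg <- colSums(matrix(fine$counts, nrow = 3))
  expect_identical(as.integer(agg), coarse$counts)
})
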