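test_that("recording validation enforces the container invariants", {
  m <- matrix(1:6, 2, 3)
  expect_s3_class(nirs_recording(m, 1.81, "hbo"), "nirs_recording")
  expect_error(nirs_recording(m, 0, "hbo"), "positive")
  expect_error(nirs_recording(matrix(c(1, NA, 3, 4), 2), 1, "hbo"), "rejected")
  expect_error(nirs_recording(m, 1, "hbo", channel_labels = c("a", "a")),
               "unique")
  expect_error(nirs_recording(m, 1, "hbo", wavelengths_nm = c(760, 830)),
               "optical_density")
  expect_error(nirs_recording(m, 1, "optical_density"), "wavelengths")
  od <- nirs_recording(matrix(0, 4, 3), 1, "optical_density",
                       wavelengths_nm = c(760, 830))
  expect_equal(od$wavelengths_nm, c(760, 830))
})

test_that("paradigm validation rejects gaps, overlaps and bad labels", {
  expect_error(nirs_paradigm(data.frame(label = "walk", onset_s = 0,
                                        duration_s = 10)), "unknown block label")
  expect_error(nirs_paradigm(data.frame(label = c("rest", "task"),
                                        onset_s = c(0, 15),
                                        duration_s = c(10, 5))), "contiguous")
  expect_error(nirs_paradigm(data.frame(label = "rest", onset_s = 5,
                                        duration_s = 10)), "start at 0")
  p <- default_paradigm()
  expect_equal(p$total_duration_s, 360)
  expect_equal(nrow(p$blocks), 22)   # lead-in + 10 x (task, rest) + baseline
})

test_that("per-sample labels follow the half-open block convention", {
  p <- nirs_paradigm(data.frame(label = c("rest", "task", "rest"),
                                onset_s = c(0, 10, 20),
                                duration_s = c(10, 10, 10)))
  lab <- paradigm_labels(p, fs = 1, n_samples = 30)
  expect_length(lab, 30)
  # sample at exactly t = 10 belongs to the task block
  expect_equal(lab[11], "task")
  expect_equal(lab[20], "task")   # t = 19
  expect_equal(lab[21], "rest")   # t = 20 starts the next block
  # single-block paradigm: everything labelled rest
  p1 <- nirs_paradigm(data.frame(label = "rest", onset_s = 0, duration_s = 10))
  expect_equal(unique(paradigm_labels(p1, 1, 10)), "rest")
  expect_error(paradigm_labels(p1, 1, 12), "beyond")
})

test_that("default paradigm task fraction matches the block arithmetic", {
  p <- default_paradigm()
  n <- floor(360 * 1.81)
  lab <- paradigm_labels(p, 1.81, n)
  # 10 x 10 s task out of 360 s total
  expect_equal(sum(lab == "task") / n, 100 / 360, tolerance = 0.01)
  expect_equal(sum(lab == "baseline"), sum((0:(n - 1)) / 1.81 >= 330))
})

test_that("labels are invariant to splitting a block with the same label", {
  p1 <- nirs_paradigm(data.frame(label = c("rest", "task"),
                                 onset_s = c(0, 20), duration_s = c(20, 10)))
  p2 <- nirs_paradigm(data.frame(label = c("rest", "rest", "task"),
                                 onset_s = c(0, 8, 20),
                                 duration_s = c(8, 12, 10)))
  for (fs in c(1, 1.81, 3.7))
    expect_identical(paradigm_labels(p1, fs, floor(30 * fs)),
                     paradigm_labels(p2, fs, floor(30 * fs)))
})

test_that("timeseries files round-trip exactly", {
  rec <- toy_recording(n_ch = 3, n = 5, fs = 1.81)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(rec, f)
  back <- read_timeseries(f)
  expect_equal(dim(back$values), c(3, 5))
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_lt(max(abs(back$values - rec$values)), 1e-12)

  od <- nirs_recording(matrix(rnorm(8), 4), 2, "optical_density",
                       wavelengths_nm = c(760, 830))
  write_timeseries(od, f)
  back <- read_timeseries(f, "optical_density")
  expect_equal(back$wavelengths_nm, c(760, 830))
  expect_lt(max(abs(back$values - od$values)), 1e-12)
})

test_that("malformed timeseries files fail with the offending line", {
  rec <- toy_recording(n_ch = 12, n = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(rec, f)
  lines <- readLines(f)

  # row with one field missing
  bad <- lines
  bad[5] <- sub(",[^,]*$", "", bad[5])
  writeLines(bad, f)
  expect_error(read_timeseries(f), "line 5")

  # non-numeric cell
  bad <- lines
  bad[6] <- sub("^([^,]*),[^,]*", "\\1,abc", bad[6])
  writeLines(bad, f)
  expect_error(read_timeseries(f), "line 6")

  # duplicate channel labels
  bad <- lines
  bad[3] <- "time,CH1,CH1,CH3,CH4,CH5,CH6,CH7,CH8,CH9,CH10,CH11,CH12"
  writeLines(bad, f)
  expect_error(read_timeseries(f), "duplicate")

  # broken fs header
  bad <- lines
  bad[1] <- "# sampling=1.81"
  writeLines(bad, f)
  expect_error(read_timeseries(f), "line 1")

  # kind mismatch on request
  writeLines(lines, f)
  expect_error(read_timeseries(f, "hbr"), "declares kind")
})

test_that("degenerate writes are refused and paradigms round-trip", {
  rec <- toy_recording()
  rec$values <- rec$values[integer(0), , drop = FALSE]
  rec$channel_labels <- character(0)
  expect_error(write_timeseries(rec, tempfile()), "zero-channel")

  p <- default_paradigm()
  f <- withr::local_tempfile(fileext = ".csv")
  write_paradigm(p, f)
  expect_equal(read_paradigm(f)$blocks, p$blocks)
})
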