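# Readers/writers: EDF, HDF5 session container, channel/event TSVs,
# result tables.

test_that("EDF round trip preserves shape, labels and amplitudes", {
  rec <- generate_background(2, 2, fs = 1024, seed = 5)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, "edf")
  expect_equal(dim(back$signal), c(2, 2048))
  expect_equal(back$fs, 1024)
  expect_equal(back$channels$label, rec$channels$label)
  # 16-bit quantisation: error bounded by one digital step
  step <- (max(rec$signal[1, ]) - min(rec$signal[1, ])) / 65535
  expect_lt(max(abs(back$signal - rec$signal)), 1.01 * step)
  expect_error(read_edf(withr::local_tempfile(fileext = ".edf")), "not found")
})

test_that("HDF5 session container round-trips signal and events exactly", {
  rec <- generate_background(3, 3, seed = 6)
  ev <- event_table(c(0.5, 1.5), c(1, 1), c("palatable", "neutral"),
                    c("cue", "cue"))
  path <- withr::local_tempfile(fileext = ".h5")
  write_recording(rec, path, events = ev)
  back <- read_recording(path, "hdf5")
  expect_identical(back$signal, rec$signal)
  expect_equal(back$fs, rec$fs)
  expect_equal(attr(back, "events")$onset, ev$onset)
  expect_equal(back$channels$label, rec$channels$label)
})

test_that("channel-count mismatch between file and metadata is an integrity error", {
  rec <- generate_background(3, 2, seed = 7)
  path <- withr::local_tempfile(fileext = ".h5")
  write_recording(rec, path)
  four <- channel_table(paste0("X", 1:4), "X", 1:4)
  expect_error(read_recording(path, "hdf5", channels = four), "4")
})

test_that("channels.tsv parsing validates enums and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tshaft\tindex\tregion\themisphere\tx\ty\tz",
               "LPI1\tLPI\t1\tposterior_insula\tL\t-38\t-10\t4",
               "LPI2\tLPI\t2\tinsula???\tL\t-40\t-12\t4"), path)
  expect_warning(ch <- read_channels(path), "other")
  expect_equal(ch$region, c("posterior_insula", "other"))
  expect_equal(ch$x[1], -38)

  writeLines(c("name\tshaft\tindex\tregion\themisphere\tx\ty\tz",
               "LPI1\tLPI\t1\tposterior_insula\tL\t0\t0\t0",
               "LPI1b\tLPI\t1\tposterior_insula\tL\t0\t0\t0"), path)
  expect_error(read_channels(path), "shaft")
})

test_that("events.tsv parsing sorts, accepts empty, rejects garbage", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tduration\tcondition\tphase",
               "10\t1\tneutral\tcue", "1\t1\tpalatable\tcue",
               "28\t1\tneutral\tcue", "19\t1\tpalatable\tcue"), path)
  ev <- read_events(path)
  expect_equal(ev$onset, c(1, 10, 19, 28))

  writeLines("onset\tduration\tcondition\tphase", path)
  expect_equal(nrow(read_events(path)), 0)

  writeLines(c("onset\tduration\tcondition\tphase", "abc\t1\tneutral\tcue"), path)
  expect_error(read_events(path), "numeric")

  writeLines(c("onset\tduration\tcondition\tphase",
               "5\t1\tneutral\tcue", "5\t1\tpalatable\tcue"), path)
  expect_error(read_events(path), "increasing")
})

test_that("site labels and ROL summaries write and re-read losslessly", {
  sim <- small_task_session()
  lab <- classify_task_site(sim$epochs, "C1", "anticipation",
                            config = fc_config(n_perm = 200), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(lab, path)
  back <- read_site_labels(path)
  expect_equal(names(back)[1:4], c("channel", "phase", "category", "d"))
  expect_equal(back$category, lab$category)
  expect_equal(back$d, lab$d, tolerance = 1e-6)
  expect_spans_equal(back$specific_spans[[1]], lab$specific_spans[[1]], 1e-6)

  rol <- rol_summary(rol_by_trial(sim$epochs, c(0, 3)), seed = 3)
  rpath <- withr::local_tempfile(fileext = ".tsv")
  write_results(rol, rpath)
  back_r <- utils::read.delim(rpath)
  expect_equal(names(back_r),
               c("region", "median_ms", "ci_lo_ms", "ci_hi_ms", "n_trials"))
  expect_equal(back_r$median_ms, rol$regions$median_ms, tolerance = 1e-6)
})
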