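test_that("multi-read FAST5 round-trips signals and calibration", {
  d <- withr::local_tempdir()
  sim <- fix_sim(5, len = 25)
  p <- file.path(d, "r.fast5")
  expect_equal(write_fast5(sim$reads, p), 5L)
  f5 <- read_fast5(p)
  expect_length(f5$errors, 0L)
  expect_length(f5$reads, 5L)
  got <- f5$reads[order(read_ids_of(f5$reads))]
  for (i in seq_along(sim$reads)) {
    expect_identical(got[[i]]$raw_signal, sim$reads[[i]]$raw_signal)
    expect_equal(got[[i]]$digitisation, sim$reads[[i]]$digitisation)
    expect_equal(got[[i]]$offset, sim$reads[[i]]$offset)
    expect_equal(got[[i]]$range, sim$reads[[i]]$range)
    expect_equal(got[[i]]$sampling_rate, sim$reads[[i]]$sampling_rate)
  }
})

test_that("an empty container yields zero reads", {
  d <- withr::local_tempdir()
  p <- file.path(d, "empty.fast5")
  write_fast5(list(), p)
  f5 <- read_fast5(p)
  expect_length(f5$reads, 0L)
  expect_length(f5$errors, 0L)
})

test_that("a read missing calibration errors alone; others are returned", {
  d <- withr::local_tempdir()
  sim <- fix_sim(5, len = 20)
  p <- file.path(d, "partial.fast5")
  write_fast5(sim$reads, p, omit_calibration_for = "sim_000002")
  f5 <- read_fast5(p)
  expect_length(f5$reads, 4L)
  expect_length(f5$errors, 1L)
  expect_match(names(f5$errors), "read_sim_000002")
  expect_match(unname(f5$errors), "digitisation")
})

test_that("conversion to BLOW5 preserves every signal bit-exactly", {
  d <- withr::local_tempdir()
  s1 <- fix_sim(3, len = 20, seed = 21)
  s2 <- generate_reads(3, 20, mock_model(seed = 22))
  # distinct ids across the two input files
  for (i in seq_along(s2$reads)) {
    s2$reads[[i]]$read_id <- sub("^sim_", "simb_", s2$reads[[i]]$read_id)
  }
  f1 <- file.path(d, "a.fast5"); f2 <- file.path(d, "b.fast5")
  write_fast5(s1$reads, f1)
  write_fast5(s2$reads, f2)
  out <- file.path(d, "all.blow5")
  expect_equal(convert_fast5_to_blow5(c(f1, f2), out), 6L)

  rt <- read_slow5(out)
  expect_equal(rt$header$num_read_groups, 2L)
  by_id <- setNames(rt$reads, read_ids_of(rt$reads))
  for (r in c(s1$reads, s2$reads))
    expect_identical(by_id[[r$read_id]]$raw_signal, r$raw_signal)
  groups <- vapply(rt$reads, function(r) r$read_group, 0L)
  expect_setequal(groups[startsWith(names(by_id), "sim_")], 0L)
  expect_setequal(groups[startsWith(names(by_id), "simb_")], 1L)

  # streaming the converted file agrees with reading the FAST5s directly
  streamed <- collect_reads(out, slow5_batchsize = 4)
  expect_identical(lapply(streamed, function(r) r$raw_signal),
                   lapply(rt$reads, function(r) r$raw_signal))

  # re-running the conversion is byte-identical
  out2 <- file.path(d, "all2.blow5")
  convert_fast5_to_blow5(c(f1, f2), out2)
  expect_identical(unname(tools::md5sum(out)), unname(tools::md5sum(out2)))
})

test_that("read_id collisions across inputs are rejected by name", {
  d <- withr::local_tempdir()
  sim <- fix_sim(2, len = 10)
  f1 <- file.path(d, "a.fast5"); f2 <- file.path(d, "b.fast5")
  write_fast5(sim$reads, f1)
  write_fast5(sim$reads, f2)
  expect_error(convert_fast5_to_blow5(c(f1, f2), file.path(d, "o.blow5")),
               "sim_000000")
})
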