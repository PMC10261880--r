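test_that("headers round-trip through both dialects", {
  d <- withr::local_tempdir()
  h1 <- run_header(attributes = c(flow_cell_id = "FAK1", run_id = "r0"))
  h2 <- run_header(num_read_groups = 2,
                   attributes = list(c(run_id = "a", device = "p2"),
                                     c(run_id = "b")),
                   aux_schema = data.frame(name = c("channel", "mux"),
                                           type = c("int", "int")),
                   record_codec = "zstd", signal_codec = "none")
  for (h in list(h1, h2)) {
    for (binary in c(TRUE, FALSE)) {
      p <- file.path(d, paste0("h", binary, ".x5"))
      write_slow5(p, h, list(), binary = binary)
      expect_identical(read_header(p), h)
    }
  }
})

test_that("corrupt magic, bad version and truncation give distinct errors", {
  d <- withr::local_tempdir()
  p <- file.path(d, "x.blow5")
  write_slow5(p, run_header(), list(), binary = TRUE)
  bytes <- readBin(p, "raw", file.size(p))

  corrupt <- bytes; corrupt[2] <- as.raw(0xFF)
  writeBin(corrupt, file.path(d, "bad.blow5"))
  expect_error(read_header(file.path(d, "bad.blow5")), "magic")

  vers <- bytes; vers[5] <- as.raw(9)
  writeBin(vers, file.path(d, "v9.blow5"))
  expect_error(read_header(file.path(d, "v9.blow5")), "version")

  writeBin(bytes[1:10], file.path(d, "trunc.blow5"))
  expect_error(read_header(file.path(d, "trunc.blow5")), "truncated")
})

test_that("an empty file round-trips to an empty record set", {
  d <- withr::local_tempdir()
  for (binary in c(TRUE, FALSE)) {
    p <- file.path(d, paste0("empty", binary, ".x5"))
    expect_equal(write_slow5(p, run_header(), list(), binary = binary), 0L)
    rt <- read_slow5(p)
    expect_length(rt$reads, 0L)
  }
})

test_that("records round-trip bit-identically and across dialects", {
  d <- withr::local_tempdir()
  sim <- fix_sim(3, len = 40)
  pb <- file.path(d, "r.blow5"); pa <- file.path(d, "r.slow5")
  expect_equal(write_slow5(pb, sim$header, sim$reads, binary = TRUE), 3L)
  expect_equal(write_slow5(pa, sim$header, sim$reads, binary = FALSE), 3L)
  rb <- read_slow5(pb); ra <- read_slow5(pa)
  expect_same_reads(rb$reads, sim$reads)
  expect_same_reads(ra$reads, rb$reads)
  expect_identical(ra$header, rb$header)
})

test_that("writers reject duplicate read ids and schema violations", {
  d <- withr::local_tempdir()
  sim <- fix_sim(2, len = 10)
  dup <- c(sim$reads, sim$reads[1])
  expect_error(write_slow5(file.path(d, "dup.blow5"), sim$header, dup),
               "duplicate")
  naked <- signal_read("extra", 1:5)  # aux fields missing entirely
  expect_error(write_slow5(file.path(d, "bad.blow5"), sim$header,
                           c(sim$reads, list(naked))),
               "aux")
})

test_that("append extends a file without touching existing bytes", {
  d <- withr::local_tempdir()
  sim <- fix_sim(5, len = 20)
  for (binary in c(TRUE, FALSE)) {
    p <- file.path(d, paste0("a", binary, ".x5"))
    write_slow5(p, sim$header, sim$reads[1:2], binary = binary)
    before <- readBin(p, "raw", file.size(p))

    # appending nothing is a bitwise no-op
    expect_equal(append_slow5(p, list()), 2L)
    expect_identical(readBin(p, "raw", file.size(p)), before)

    expect_equal(append_slow5(p, sim$reads[3:5]), 5L)
    after <- readBin(p, "raw", file.size(p))
    expect_identical(after[seq_along(before)], before)
    rt <- read_slow5(p)
    expect_same_reads(rt$reads, sim$reads)
  }
})

test_that("append rejects id collisions and schema-violating reads", {
  d <- withr::local_tempdir()
  sim <- fix_sim(3, len = 10)
  p <- file.path(d, "a.blow5")
  write_slow5(p, sim$header, sim$reads[1:2])
  expect_error(append_slow5(p, sim$reads[1]), "collision")
  incomplete <- signal_read("new", 1:4,
                            aux = list(channel_number = 1L))  # omits a field
  expect_error(append_slow5(p, list(incomplete)), "aux")
  expect_error(append_slow5(file.path(d, "nope.blow5"), sim$reads), "exist")
})

test_that("the index agrees with a sequential scan", {
  d <- withr::local_tempdir()
  one <- fix_blow5(d, 1, len = 15, name = "one")
  idx1 <- build_index(one$path)
  expect_equal(nrow(idx1$entries), 1L)
  seq1 <- read_slow5(one$path)$reads[[1]]
  expect_identical(unclass(get_read(one$path, seq1$read_id, idx1)),
                   unclass(seq1))

  p0 <- file.path(d, "zero.blow5")
  write_slow5(p0, run_header(), list())
  expect_equal(nrow(build_index(p0)$entries), 0L)

  many <- fix_blow5(d, 300, len = 15, seed = 5, name = "many")
  idx <- build_index(many$path)
  seq_reads <- read_slow5(many$path)$reads
  expect_setequal(idx$entries$read_id, read_ids_of(seq_reads))
  expect_true(all(diff(idx$entries$offset) > 0))
  expect_true(all(diff(idx$entries$offset) >= head(idx$entries$length, -1)))
})

test_that("get_read is stateless and errors on unknown ids", {
  d <- withr::local_tempdir()
  fx <- fix_blow5(d, 20, len = 15, seed = 6)
  idx <- build_index(fx$path)
  seq_reads <- read_slow5(fx$path)$reads
  for (i in c(1L, 10L, 20L)) {
    got <- get_read(fx$path, seq_reads[[i]]$read_id, idx)
    expect_identical(unclass(got), unclass(seq_reads[[i]]))
  }
  again <- get_read(fx$path, seq_reads[[10]]$read_id, idx)
  expect_identical(again, get_read(fx$path, seq_reads[[10]]$read_id, idx))
  expect_error(get_read(fx$path, "missing", idx), "not found")
})

test_that("the side-car index reloads and detects staleness", {
  d <- withr::local_tempdir()
  fx <- fix_blow5(d, 10, len = 15, seed = 7)
  built <- build_index(fx$path)
  loaded <- load_index(fx$path)
  expect_equal(loaded$entries, built$entries)
  extra <- fix_sim(11, len = 15, seed = 8)
  append_slow5(fx$path, extra$reads[11])
  expect_error(load_index(fx$path), "stale")
  expect_error(load_index(file.path(d, "unindexed.blow5")), "build_index")
})

test_that("truncated data files are reported with the last good offset", {
  d <- withr::local_tempdir()
  fx <- fix_blow5(d, 4, len = 15, seed = 9)
  bytes <- readBin(fx$path, "raw", file.size(fx$path))
  pt <- file.path(d, "trunc.blow5")
  writeBin(bytes[1:(length(bytes) - 5L)], pt)
  expect_error(build_index(pt), "last good offset")
})
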