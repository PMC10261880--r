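test_that("n = 0 yields an empty, well-formed simulation", {
  sim <- generate_reads(0, 50, fix_model())
  expect_length(sim$reads, 0L)
  expect_length(sim$sequences, 0L)
  expect_s3_class(sim$header, "run_header")
})

test_that("noiseless signals are constant runs at the base levels", {
  m <- mock_model(noise_sd = 0, dwell = 2L, seed = 3)
  sim <- generate_reads(1, 4, m)
  r <- sim$reads[[1]]
  expect_length(r$raw_signal, 8L)
  # each base contributes dwell identical samples at its level
  runs <- matrix(r$raw_signal, nrow = 2)
  expect_true(all(runs[1, ] == runs[2, ]))
  bases <- strsplit(sim$sequences[[1]], "")[[1]]
  expected_raw <- round(m$level_pA[bases] * m$digitisation / m$range - m$offset)
  expect_equal(unname(runs[1, ]), unname(expected_raw))
})

test_that("the seed fully determines the simulation", {
  a <- generate_reads(5, 30, mock_model(seed = 10))
  b <- generate_reads(5, 30, mock_model(seed = 10))
  c <- generate_reads(5, 30, mock_model(seed = 11))
  expect_identical(a$sequences, b$sequences)
  expect_identical(lapply(a$reads, unclass), lapply(b$reads, unclass))
  expect_false(identical(a$sequences, c$sequences))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(runif(1))
  invisible(generate_reads(2, 10, fix_model()))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("length distributions may be functions", {
  sim <- generate_reads(4, function(n) rep(c(10L, 20L), length.out = n),
                        fix_model())
  expect_equal(unname(nchar(sim$sequences)), c(10L, 20L, 10L, 20L))
  expect_equal(vapply(sim$reads, function(r) length(r$raw_signal), 0L),
               c(10L, 20L, 10L, 20L) * 10L)
})

test_that("fixtures are written in all formats with matching ground truth", {
  d <- withr::local_tempdir()
  sim <- fix_sim(10, len = 20)
  paths <- write_fixture(sim, d)
  expect_setequal(names(paths), c("slow5", "blow5", "fast5", "fasta"))
  expect_true(all(file.exists(paths)))
  streamed <- collect_reads(paths[["blow5"]])
  fasta <- readLines(paths[["fasta"]])
  headers <- sub("^>", "", fasta[startsWith(fasta, ">")])
  expect_identical(read_ids_of(streamed), headers)
  expect_identical(fasta[!startsWith(fasta, ">")], unname(sim$sequences))
})

test_that("regenerated fixtures are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture(fix_sim(8, len = 15), d1)
  p2 <- write_fixture(fix_sim(8, len = 15), d2)
  for (fmt in c("slow5", "blow5", "fast5", "fasta"))
    expect_identical(unname(tools::md5sum(p1[[fmt]])),
                     unname(tools::md5sum(p2[[fmt]])))
})

test_that("a model level outside the raw range is a generation error", {
  m <- mock_model(level_pA = c(A = 80, C = 100, G = 120, T = 20000),
                  digitisation = 8192, range = 1402.882)
  expect_error(generate_reads(1, 10, m), "generation error")
})

test_that("noise-free recovery is exact over many reads", {
  m0 <- mock_model(noise_sd = 0, seed = 17)
  sim <- generate_reads(20, 100, m0)
  bc <- lapply(sim$reads, mock_basecall, model = m0)
  called <- setNames(vapply(bc, function(r) r$sequence, ""),
                     vapply(bc, function(r) r$read_id, ""))
  expect_identical(called, sim$sequences)
})
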