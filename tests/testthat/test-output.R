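test_that("FASTQ encodes phred+33 qualities", {
  d <- withr::local_tempdir()
  p <- file.path(d, "one.fastq")
  write_fastq(list(basecall_result("r1", "ACGT", rep(10L, 4))), p)
  lines <- readLines(p)
  expect_identical(lines, c("@r1", "ACGT", "+", "++++"))
})

test_that("empty result sets give an empty FASTQ and a header-only SAM", {
  d <- withr::local_tempdir()
  pf <- file.path(d, "e.fastq"); ps <- file.path(d, "e.sam")
  expect_equal(write_fastq(list(), pf), 0L)
  expect_equal(file.size(pf), 0)
  expect_equal(write_sam(list(), ps), 0L)
  expect_true(all(startsWith(readLines(ps), "@")))
})

test_that("FASTQ and SAM carry identical sequence/quality content", {
  d <- withr::local_tempdir()
  sim <- fix_sim(15, len = 40)
  results <- lapply(sim$reads, mock_basecall, model = fix_model())
  pf <- file.path(d, "c.fastq"); ps <- file.path(d, "c.sam")
  write_fastq(results, pf)
  write_sam(results, ps)
  fq <- read_fastq(pf)$results
  sm <- read_sam(ps)$results
  expect_identical(lapply(fq, unclass), lapply(sm, unclass))
  expect_identical(lapply(fq, unclass), lapply(results, unclass))
})

test_that("emitted FASTQ parses with an independent reader", {
  skip_if_not_installed("Biostrings")
  d <- withr::local_tempdir()
  sim <- fix_sim(10, len = 25)
  results <- lapply(sim$reads, mock_basecall, model = fix_model())
  p <- file.path(d, "x.fastq")
  write_fastq(results, p)
  dna <- Biostrings::readDNAStringSet(p, format = "fastq")
  expect_identical(names(dna), vapply(results, function(r) r$read_id, ""))
  expect_identical(as.character(dna, use.names = FALSE),
                   vapply(results, function(r) r$sequence, ""))
})

test_that("emitted SAM is accepted by samtools", {
  d <- withr::local_tempdir()
  sim <- fix_sim(8, len = 25)
  results <- lapply(sim$reads, mock_basecall, model = fix_model())
  p <- file.path(d, "x.sam")
  write_sam(results, p)
  out <- suppressWarnings(system2("samtools", c("view", "-c", p),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(as.integer(tail(out, 1)), 8L)
})

test_that("out-of-range qualities are clamped with a logged count", {
  d <- withr::local_tempdir()
  p <- file.path(d, "clamp.fastq")
  r <- basecall_result("hot", "AC", c(40L, 40L))
  r$qualities <- c(95L, 40L)  # forced past the encodable ceiling
  expect_message(write_fastq(list(r), p), "clamped 1")
  expect_identical(read_fastq(p)$results[[1]]$qualities, c(93L, 40L))
})

test_that("phred+33 encoding round-trips the full encodable range", {
  q <- 0:93
  expect_identical(phred33_decode(phred33_encode(q)), q)
})

test_that("split_by_qscore partitions with an inclusive pass boundary", {
  mk <- function(id, q) basecall_result(id, "A", as.integer(q))
  rs <- list(mk("low", 6), mk("edge", 7), mk("high", 8))
  parts <- split_by_qscore(rs, 7)
  expect_identical(read_ids_of(parts$fail), "low")
  expect_setequal(read_ids_of(parts$pass), c("edge", "high"))  # 7.0 passes
  expect_length(split_by_qscore(rs, 0)$fail, 0L)
  expect_length(split_by_qscore(rs, Inf)$pass, 0L)
  expect_equal(length(parts$pass) + length(parts$fail), length(rs))
})

test_that("the splitting tool routes records byte-identically", {
  d <- withr::local_tempdir()
  sim <- fix_sim(10, len = 30, noise_sd = 6, seed = 13)
  results <- lapply(sim$reads, mock_basecall, model = fix_model(noise_sd = 6,
                                                               seed = 13))
  mq <- vapply(results, function(r) r$mean_qscore, 0)
  thr <- median(mq)  # threshold between observed values
  p <- file.path(d, "mix.fastq")
  write_fastq(results, p)
  counts <- split_qscore_tool(p, thr)
  expect_equal(sum(counts), 10L)
  pass_recs <- read_fastq(file.path(d, "mix.pass.fastq"))$records
  fail_recs <- read_fastq(file.path(d, "mix.fail.fastq"))$records
  expect_setequal(c(pass_recs, fail_recs), read_fastq(p)$records)

  # idempotence: re-splitting the pass file keeps everything in pass
  counts2 <- split_qscore_tool(file.path(d, "mix.pass.fastq"), thr,
                               output_prefix = file.path(d, "again"))
  expect_equal(unname(counts2), c(counts[["pass"]], 0L))
})

test_that("all-'+' qualities give mean q 10, passing a threshold of 10", {
  d <- withr::local_tempdir()
  p <- file.path(d, "plus.fastq")
  writeLines(c("@q10", "ACGTA", "+", "+++++"), p)
  counts <- split_qscore_tool(p, 10)
  expect_equal(unname(counts), c(1L, 0L))
})

test_that("SAM splitting trusts the stored tag unless told to recompute", {
  d <- withr::local_tempdir()
  # qualities say q=20 but the tag claims 5: tag routes to fail by default
  rec <- paste("r1", 4L, "*", 0L, 0L, "*", "*", 0L, 0L, "ACGT", "5555",
               "qs:i:5", "mq:f:5", sep = "\t")
  p <- file.path(d, "t.sam")
  writeLines(c("@HD\tVN:1.6", rec), p)
  trusted <- split_qscore_tool(p, 10, output_prefix = file.path(d, "trust"))
  expect_equal(unname(trusted), c(0L, 1L))
  recomputed <- split_qscore_tool(p, 10, output_prefix = file.path(d, "re"),
                                  recompute = TRUE)
  expect_equal(unname(recomputed), c(1L, 0L))
  # header lines are replicated into both outputs; the record is untouched
  pass_lines <- readLines(file.path(d, "re.pass.sam"))
  expect_identical(pass_lines, c("@HD\tVN:1.6", rec))
})

test_that("malformed input aborts the split and removes partial outputs", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+"), p)  # 3 lines, not a multiple of 4
  expect_error(split_qscore_tool(p, 7), "multiple of 4")
  expect_false(file.exists(file.path(d, "bad.pass.fastq")))
  expect_false(file.exists(file.path(d, "bad.fail.fastq")))
})
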