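test_that("to_pA applies the calibration formula", {
  expect_equal(to_pA(signal_read("r", c(0L, 0L), digitisation = 1000,
                                 offset = 0, range = 1000)),
               c(0, 0))
  # (100 + 10) * 1200 / 600 = 220
  expect_equal(to_pA(signal_read("r", 100L, digitisation = 600, offset = 10,
                                 range = 1200)),
               220)
  # offset exactly cancels the raw value
  expect_equal(to_pA(signal_read("r", -5L, digitisation = 100, offset = 5,
                                 range = 100)),
               0)
})

test_that("to_pA is affine in the raw signal", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    a <- signal_read("a", sample(-2000:2000, n, replace = TRUE),
                     digitisation = 8192, offset = 10, range = 1402.882)
    b <- signal_read("b", sample(-2000:2000, n, replace = TRUE),
                     digitisation = 8192, offset = 10, range = 1402.882)
    expect_equal(to_pA(a) - to_pA(b),
                 (a$raw_signal - b$raw_signal) * 1402.882 / 8192)
  }
})

test_that("signal_read enforces its invariants at construction", {
  expect_error(signal_read("", 1L), "read_id")
  expect_error(signal_read("has space", 1L), "read_id")
  expect_error(signal_read("r", 1L, digitisation = 0), "calibration")
  expect_error(signal_read("r", 1L, digitisation = -5), "calibration")
  expect_error(signal_read("r", 40000L), "16-bit")
  expect_error(signal_read("r", 1L, range = 0), "range")
  expect_error(signal_read("r", 1L, read_group = -1L), "read_group")
  # zero-length signal is allowed
  expect_equal(length(signal_read("r", integer())$raw_signal), 0L)
})

test_that("run_header enforces read-group and aux-schema invariants", {
  expect_error(run_header(num_read_groups = 0), "num_read_groups")
  expect_error(run_header(attributes = c("v")), "named")
  expect_error(run_header(attributes = c(`k\tk` = "v")), "tab")
  expect_error(
    run_header(aux_schema = data.frame(name = c("a", "a"),
                                       type = c("int", "int"))),
    "unique")
  expect_error(
    run_header(aux_schema = data.frame(name = "a", type = "float128")),
    "type")
  h <- run_header(num_read_groups = 2,
                  attributes = list(c(k = "v"), character()))
  expect_length(h$attributes, 2L)
})

test_that("pipeline_config requires guppy_batchsize <= max_queued_reads", {
  expect_error(pipeline_config(guppy_batchsize = 100, max_queued_reads = 50),
               "max_queued_reads")
  expect_error(pipeline_config(procs = 0), "positive")
  cfg <- pipeline_config(guppy_batchsize = 50, max_queued_reads = 50)
  expect_s3_class(cfg, "pipeline_config")
})

test_that("basecall_result keeps qualities and mean qscore consistent", {
  expect_error(basecall_result("r", "ACGT", c(10L, 10L)), "one entry per base")
  expect_error(basecall_result("r", "ACGX", rep(10L, 4)), "A, C, G, T")
  r <- basecall_result("r", "ACGT", c(20L, 30L, 40L, 20L))
  expect_equal(r$mean_qscore, mean_qscore(c(20, 30, 40, 20)))
  empty <- basecall_result("r", "", integer())
  expect_true(is.nan(empty$mean_qscore))
})

test_that("reads are validated against the header schema", {
  h <- run_header(aux_schema = data.frame(name = "channel", type = "int"))
  ok <- signal_read("r", 1L, aux = list(channel = 3L))
  expect_true(validate_read_against_header(ok, h))
  expect_error(validate_read_against_header(signal_read("r", 1L), h), "aux")
  bad_type <- signal_read("r", 1L, aux = list(channel = "three"))
  expect_error(validate_read_against_header(bad_type, h), "conform")
  wrong_group <- signal_read("r", 1L, read_group = 1L,
                             aux = list(channel = 3L))
  expect_error(validate_read_against_header(wrong_group, h), "read_group")
})
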