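# Shared fixture builders. Everything is generated in code from fixed seeds;
# no data files are shipped.

fix_model <- function(noise_sd = 2, seed = 42L, dwell = 10L)
  mock_model(noise_sd = noise_sd, seed = seed, dwell = dwell)

fix_sim <- function(n, len = 60L, noise_sd = 2, seed = 42L)
  generate_reads(n, length_distribution = len,
                 model = fix_model(noise_sd = noise_sd, seed = seed))

fix_blow5 <- function(dir, n, len = 60L, noise_sd = 2, seed = 42L,
                      name = "reads") {
  sim <- fix_sim(n, len = len, noise_sd = noise_sd, seed = seed)
  p <- file.path(dir, paste0(name, ".blow5"))
  write_slow5(p, sim$header, sim$reads, binary = TRUE)
  list(path = p, sim = sim)
}

read_ids_of <- function(reads) vapply(reads, function(r) r$read_id, "")

# identical-by-content comparison for lists of signal_read objects
expect_same_reads <- function(a, b) {
  expect_equal(length(a), length(b))
  expect_identical(lapply(a, unclass), lapply(b, unclass))
}

# fraction of matching bases between equal-length called/truth sequences
base_identity <- function(called, truth) {
  stopifnot(identical(names(called), names(truth)),
            all(nchar(called) == nchar(truth)))
  mean(unlist(strsplit(called, "", fixed = TRUE)) ==
         unlist(strsplit(truth, "", fixed = TRUE)))
}

# a signal_read whose pA trace equals its raw values (identity calibration)
identity_read <- function(id, pA_values)
  signal_read(id, raw_signal = as.integer(pA_values),
              digitisation = 100, offset = 0, range = 100,
              sampling_rate = 4000)

# mock model under identity calibration, for hand-built signals
identity_model <- function(noise_sd = 0, dwell = 10L)
  mock_model(noise_sd = noise_sd, dwell = dwell,
             digitisation = 100, offset = 0, range = 100)
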