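# Synthetic raw-signal generator with known ground-truth sequences. The
# emulation is intentionally simpler than a real pore — uniform base
# composition, fixed dwell, no k-mer context — so that the mock
# basecaller's recovery behaviour is analytically predictable and every
# other module is testable without downloads.

# run the body with the RNG seeded from `seed`, restoring the caller's state
with_sim_seed <- function(seed, body) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  body()
}

#' Generate synthetic signal reads with ground truth
#'
#' For each read, a sequence is drawn uniformly over A/C/G/T with length
#' from `length_distribution`; the signal emits `dwell` samples per base at
#' that base's model current level plus Gaussian noise, converted to raw ADC
#' integers by inverting the picoamp calibration, rounding, and clipping to
#' the 16-bit range. Read ids are `sim_000000`, `sim_000001`, ...
#' (sequential), and the whole draw is reproducible from `model$seed`.
#'
#' @param n Number of reads (>= 0).
#' @param length_distribution Either a single read length in bases, or a
#'   function `f(n)` returning `n` integer lengths.
#' @param model A [mock_model()]; supplies levels, dwell, noise, calibration
#'   and seed.
#' @return An object of class `sim_reads`: a list with `reads` (list of
#'   [signal_read()]), `sequences` (named character, ground truth keyed by
#'   read id), `header` (a [run_header()] whose aux schema matches the
#'   generated aux fields), and `model`.
#' @examples
#' sim <- generate_reads(3, length_distribution = 50, model = mock_model())
#' names(sim$sequences)
#' @export
generate_reads <- function(n, length_distribution = 500L,
                           model = mock_model()) {
  stopifnot(inherits(model, "mock_model"), n >= 0)
  n <- as.integer(n)
  header <- sim_header(model)
  if (n == 0L)
    return(structure(list(reads = list(),
                          sequences = setNames(character(), character()),
                          header = header, model = model),
                     class = "sim_reads"))
  # levels must be representable as raw ADC units before noise is added
  centre_raw <- pA_to_raw(model$level_pA, model$digitisation, model$offset,
                          model$range)
  if (any(centre_raw < INT16_MIN | centre_raw > INT16_MAX))
    stop("generation error: a model level falls outside the representable ",
         "raw range after calibration")

  with_sim_seed(model$seed, function() {
    lens <- if (is.function(length_distribution))
      as.integer(length_distribution(n))
    else rep(as.integer(length_distribution), n)
    stopifnot(length(lens) == n, all(lens >= 1L))
    bases <- c("A", "C", "G", "T")
    all_b <- sample.int(4L, sum(lens), replace = TRUE)
    pA <- rep(model$level_pA[all_b], each = model$dwell) +
      rnorm(sum(lens) * model$dwell, 0, model$noise_sd)
    raw_all <- as.integer(pmin(pmax(
      round(pA_to_raw(pA, model$digitisation, model$offset, model$range)),
      INT16_MIN), INT16_MAX))
    read_of_base <- rep.int(seq_len(n), lens)
    seq_split <- split(bases[all_b], read_of_base)
    sig_split <- split(raw_all, rep.int(seq_len(n), lens * model$dwell))
    ids <- sprintf("sim_%06d", seq_len(n) - 1L)
    channels <- as.integer((seq_len(n) - 1L) %% 512L + 1L)
    median_before <- round(250 + rnorm(n, 0, 5), 3)
    reads <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      reads[[i]] <- signal_read(
        ids[i], raw_signal = sig_split[[i]],
        digitisation = model$digitisation, offset = model$offset,
        range = model$range, sampling_rate = model$sampling_rate,
        aux = list(channel_number = channels[i],
                   median_before = median_before[i]))
      seqs[i] <- paste(seq_split[[i]], collapse = "")
    }
    structure(list(reads = reads, sequences = setNames(seqs, ids),
                   header = header, model = model),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d read(s), %d ground-truth bases, seed %d\n",
              length(x$reads), sum(nchar(x$sequences)), x$model$seed))
  invisible(x)
}

# the header matching what generate_reads() emits
sim_header <- function(model, record_codec = "zlib",
                       signal_codec = "delta_zigzag_varint") {
  run_header(
    num_read_groups = 1L,
    attributes = list(c(run_id = sprintf("sim_seed_%d", model$seed),
                        experiment_type = "genomic_dna")),
    aux_schema = data.frame(name = c("channel_number", "median_before"),
                            type = c("int", "double"),
                            stringsAsFactors = FALSE),
    record_codec = record_codec, signal_codec = signal_codec)
}

#' Write a simulated read set to disk in one or more formats
#'
#' Writes the reads as SLOW5 and/or BLOW5 and/or multi-read FAST5, plus a
#' FASTA of the ground-truth sequences (headers = read ids) for recovery
#' scoring. SLOW5/BLOW5 outputs are byte-deterministic given the same
#' simulation.
#'
#' @param sim A [generate_reads()] result.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("slow5", "blow5", "fast5")`.
#' @param name Basename for the output files.
#' @return Named character vector of file paths (formats plus `"fasta"`).
#' @export
write_fixture <- function(sim, dir, formats = c("slow5", "blow5", "fast5"),
                          name = "reads") {
  stopifnot(inherits(sim, "sim_reads"),
            all(formats %in% c("slow5", "blow5", "fast5")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (fmt in formats) {
    p <- file.path(dir, paste0(name, ".", fmt))
    switch(fmt,
           slow5 = write_slow5(p, sim$header, sim$reads, binary = FALSE),
           blow5 = write_slow5(p, sim$header, sim$reads, binary = TRUE),
           fast5 = write_fast5(sim$reads, p))
    paths[fmt] <- p
  }
  fa <- file.path(dir, paste0(name, ".fasta"))
  con <- file(fa, "wb")
  if (length(sim$sequences))
    writeLines(paste0(">", names(sim$sequences), "\n", sim$sequences), con,
               sep = "\n")
  close(con)
  paths["fasta"] <- fa
  paths
}
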