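#' @useDynLib slow5pipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm median setNames dist
NULL

RECORD_CODECS <- c("none", "zlib", "zstd")
SIGNAL_CODECS <- c("none", "delta_zigzag_varint")
AUX_TYPES <- c("int", "double", "string")
INT16_MIN <- -32768L
INT16_MAX <- 32767L

#' Construct a run header
#'
#' A run header carries the per-file metadata of a SLOW5/BLOW5 file: the
#' number of read groups, one ordered attribute map (name -> string) per read
#' group, the auxiliary-field schema shared by all records, and the codecs
#' used by the binary dialect.
#'
#' @param num_read_groups Number of read groups in the file (>= 1). Each read
#'   group is a set of reads sharing acquisition metadata.
#' @param attributes A list with one named character vector per read group
#'   (may be empty). A single named character vector is accepted when
#'   `num_read_groups == 1`. `NULL` means all groups have empty maps.
#' @param aux_schema A data frame with columns `name` and `type` describing
#'   the auxiliary columns every record carries. Types are one of
#'   `"int"`, `"double"`, `"string"`. `NULL` means no auxiliary fields.
#' @param record_codec Whole-record compression for the binary dialect:
#'   `"zlib"` (default), `"zstd"`, or `"none"`.
#' @param signal_codec Signal-sample codec for the binary dialect:
#'   `"delta_zigzag_varint"` (default) or `"none"` (plain little-endian
#'   16-bit integers).
#' @return An object of class `run_header`.
#' @examples
#' hdr <- run_header(attributes = c(flow_cell_id = "FAK00000"))
#' hdr
#' @export
run_header <- function(num_read_groups = 1L,
                       attributes = NULL,
                       aux_schema = NULL,
                       record_codec = c("zlib", "zstd", "none"),
                       signal_codec = c("delta_zigzag_varint", "none")) {
  record_codec <- match.arg(record_codec)
  signal_codec <- match.arg(signal_codec)
  num_read_groups <- as.integer(num_read_groups)
  if (length(num_read_groups) != 1L || is.na(num_read_groups) || num_read_groups < 1L)
    stop("num_read_groups must be a single integer >= 1")

  if (is.null(attributes)) attributes <- rep(list(character()), num_read_groups)
  if (is.character(attributes)) attributes <- list(attributes)
  if (!is.list(attributes) || length(attributes) != num_read_groups)
    stop("attributes must be a list with one named character vector per read group")
  attributes <- lapply(attributes, function(a) {
    a <- as.character(a) |> setNames(names(a))
    if (length(a) && (is.null(names(a)) || anyNA(names(a)) || any(names(a) == "")))
      stop("every header attribute must be named")
    if (anyDuplicated(names(a))) stop("duplicate attribute name within a read group")
    if (length(a) && any(grepl("[\t\n]", c(names(a), a))))
      stop("header attributes must not contain tab or newline characters")
    a
  })

  if (is.null(aux_schema))
    aux_schema <- data.frame(name = character(), type = character(),
                             stringsAsFactors = FALSE)
  if (!is.data.frame(aux_schema) || !all(c("name", "type") %in% names(aux_schema)))
    stop("aux_schema must be a data frame with columns 'name' and 'type'")
  aux_schema <- data.frame(name = as.character(aux_schema$name),
                           type = as.character(aux_schema$type),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(aux_schema$name)) stop("aux_schema field names must be unique")
  if (any(grepl("[\t\n]", aux_schema$name)))
    stop("aux_schema field names must not contain tab or newline characters")
  if (!all(aux_schema$type %in% AUX_TYPES))
    stop("aux_schema types must be one of: ", paste(AUX_TYPES, collapse = ", "))

  structure(
    list(num_read_groups = num_read_groups,
         attributes = attributes,
         aux_schema = aux_schema,
         record_codec = record_codec,
         signal_codec = signal_codec),
    class = "run_header"
  )
}

#' @export
print.run_header <- function(x, ...) {
  cat(sprintf("<run_header> %d read group(s); codecs: record=%s signal=%s\n",
              x$num_read_groups, x$record_codec, x$signal_codec))
  for (g in seq_len(x$num_read_groups)) {
    a <- x$attributes[[g]]
    cat(sprintf("  group %d: %d attribute(s)%s\n", g - 1L, length(a),
                if (length(a)) paste0(" [", paste(names(a), collapse = ", "), "]") else ""))
  }
  if (nrow(x$aux_schema))
    cat("  aux fields:", paste(sprintf("%s<%s>", x$aux_schema$name, x$aux_schema$type),
                               collapse = " "), "\n")
  invisible(x)
}

#' Construct a raw-signal read
#'
#' One nanopore read: an identifier, the calibration quartet used to convert
#' raw ADC samples to picoamps, the integer signal itself, and optional
#' auxiliary fields conforming to the file header's `aux_schema`.
#'
#' @param read_id Read identifier; non-empty, no whitespace, unique within a
#'   file.
#' @param raw_signal Integer vector of ADC samples; every value must fit a
#'   16-bit signed integer.
#' @param read_group Zero-based read-group index.
#' @param digitisation Number of ADC quantisation levels (> 0).
#' @param offset ADC offset added to the raw value before scaling.
#' @param range Current span in picoamps covered by the digitisation (> 0).
#' @param sampling_rate Samples per second (> 0).
#' @param aux Named list of auxiliary values matching the header schema.
#' @return An object of class `signal_read`.
#' @examples
#' r <- signal_read("read1", raw_signal = c(430L, 431L, 429L))
#' to_pA(r)
#' @export
signal_read <- function(read_id, raw_signal, read_group = 0L,
                        digitisation = 8192, offset = 10, range = 1402.882,
                        sampling_rate = 4000, aux = list()) {
  if (!is.character(read_id) || length(read_id) != 1L || is.na(read_id) ||
      !nzchar(read_id) || grepl("[[:space:]]", read_id))
    stop("read_id must be a single non-empty string without whitespace")
  read_group <- as.integer(read_group)
  if (length(read_group) != 1L || is.na(read_group) || read_group < 0L)
    stop("read_group must be a single non-negative integer")
  if (!is.numeric(digitisation) || length(digitisation) != 1L || !(digitisation > 0))
    stop("calibration error: digitisation must be a single positive number")
  if (!is.numeric(range) || length(range) != 1L || !(range > 0))
    stop("range must be a single positive number")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || !(sampling_rate > 0))
    stop("sampling_rate must be a single positive number")
  raw_signal <- as.integer(raw_signal)
  if (anyNA(raw_signal)) stop("raw_signal must not contain NA")
  if (length(raw_signal) &&
      (min(raw_signal) < INT16_MIN || max(raw_signal) > INT16_MAX))
    stop("raw_signal values must fit a 16-bit signed integer")
  if (!is.list(aux) || (length(aux) && is.null(names(aux))))
    stop("aux must be a named list")

  structure(
    list(read_id = read_id, read_group = read_group,
         digitisation = as.numeric(digitisation), offset = as.numeric(offset),
         range = as.numeric(range), sampling_rate = as.numeric(sampling_rate),
         raw_signal = raw_signal, aux = aux),
    class = "signal_read"
  )
}

#' @export
print.signal_read <- function(x, ...) {
  cat(sprintf("<signal_read> %s: %d samples @ %g Hz (group %d)\n",
              x$read_id, length(x$raw_signal), x$sampling_rate, x$read_group))
  invisible(x)
}

#' Convert raw ADC samples to picoamps
#'
#' Applies the standard nanopore calibration
#' `pA = (raw + offset) * range / digitisation` to a read's signal.
#'
#' @param read A [signal_read()].
#' @return Numeric vector of picoamp values, same length as the raw signal.
#' @export
to_pA <- function(read) {
  stopifnot(inherits(read, "signal_read"))
  if (!(read$digitisation > 0)) stop("calibration error: digitisation must be positive")
  (read$raw_signal + read$offset) * read$range / read$digitisation
}

# inverse calibration: picoamps back to (unrounded) raw ADC units
pA_to_raw <- function(pA, digitisation, offset, range) {
  pA * digitisation / range - offset
}

# check a read's aux fields and group index against a header; used by writers
# and re-applied after deserialization
validate_read_against_header <- function(read, header) {
  if (read$read_group >= header$num_read_groups)
    stop(sprintf("read '%s': read_group %d out of range for %d group(s)",
                 read$read_id, read$read_group, header$num_read_groups))
  schema <- header$aux_schema
  if (!setequal(names(read$aux), schema$name) ||
      length(read$aux) != nrow(schema))
    stop(sprintf("read '%s': aux fields {%s} do not match schema {%s}",
                 read$read_id, paste(names(read$aux), collapse = ","),
                 paste(schema$name, collapse = ",")))
  for (i in seq_len(nrow(schema))) {
    v <- read$aux[[schema$name[i]]]
    ok <- switch(schema$type[i],
                 int = is.numeric(v) && length(v) == 1L && !is.na(v) && v == as.integer(v),
                 double = is.numeric(v) && length(v) == 1L && !is.na(v),
                 string = is.character(v) && length(v) == 1L && !is.na(v))
    if (!ok)
      stop(sprintf("read '%s': aux field '%s' does not conform to type '%s'",
                   read$read_id, schema$name[i], schema$type[i]))
  }
  invisible(TRUE)
}

#' Construct a basecall result
#'
#' The unit returned by any basecaller backend: the called sequence, per-base
#' phred qualities, and the read-level mean qscore (the phred transform of
#' the mean per-base error probability, recomputed here so the stored value
#' always agrees with [mean_qscore()]).
#'
#' @param read_id Originating read identifier.
#' @param sequence Called sequence over `A`, `C`, `G`, `T` (may be empty).
#' @param qualities Integer phred scores, one per base.
#' @return An object of class `basecall_result`. `mean_qscore` is `NaN` for
#'   an empty sequence.
#' @export
basecall_result <- function(read_id, sequence, qualities) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  if (nzchar(sequence) && grepl("[^ACGT]", sequence))
    stop("sequence must only contain A, C, G, T")
  qualities <- as.integer(qualities)
  if (anyNA(qualities) || any(qualities < 0))
    stop("qualities must be non-negative integers")
  if (length(qualities) != nchar(sequence))
    stop("qualities must have one entry per base")
  mq <- if (length(qualities)) mean_qscore(qualities) else NaN
  structure(
    list(read_id = read_id, sequence = sequence, qualities = qualities,
         mean_qscore = mq),
    class = "basecall_result"
  )
}

#' @export
print.basecall_result <- function(x, ...) {
  cat(sprintf("<basecall_result> %s: %d bases, mean qscore %.2f\n",
              x$read_id, nchar(x$sequence), x$mean_qscore))
  invisible(x)
}

#' Pipeline configuration
#'
#' Batching, queueing and worker parameters of the basecall-dispatch
#' pipeline. The names mirror the command-line flags of server/client
#' basecalling wrappers.
#'
#' @param guppy_batchsize Number of reads submitted to the basecall server at
#'   a time.
#' @param max_queued_reads Capacity of the server queue (pending plus
#'   in-flight reads); must be at least `guppy_batchsize`.
#' @param slow5_threads Workers used to decompress and parse records of a
#'   fetched batch.
#' @param slow5_batchsize Number of records fetched from the signal file at a
#'   time.
#' @param procs Worker processes used to send/receive data to/from the
#'   basecall server.
#' @param qscore_threshold If non-`NULL`, output is split into pass/fail
#'   files at this mean qscore (inclusive pass boundary).
#' @param output_format `"fastq"` or `"sam"` (unaligned).
#' @param sorted Canonicalize output order by `read_id` for reproducible
#'   diffs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(guppy_batchsize = 200L, max_queued_reads = 400L,
                            slow5_threads = 1L, slow5_batchsize = 4096L,
                            procs = 1L, qscore_threshold = NULL,
                            output_format = c("fastq", "sam"), sorted = FALSE) {
  output_format <- match.arg(output_format)
  ints <- c(guppy_batchsize = guppy_batchsize, max_queued_reads = max_queued_reads,
            slow5_threads = slow5_threads, slow5_batchsize = slow5_batchsize,
            procs = procs)
  ints <- vapply(ints, as.integer, integer(1))
  if (anyNA(ints) || any(ints < 1L))
    stop("all batching/queue/worker parameters must be positive integers")
  if (ints[["guppy_batchsize"]] > ints[["max_queued_reads"]])
    stop("guppy_batchsize must not exceed max_queued_reads")
  if (!is.null(qscore_threshold)) {
    stopifnot(is.numeric(qscore_threshold), length(qscore_threshold) == 1L,
              qscore_threshold >= 0)
    qscore_threshold <- as.numeric(qscore_threshold)
  }
  structure(
    c(as.list(ints),
      list(qscore_threshold = qscore_threshold, output_format = output_format,
           sorted = isTRUE(sorted))),
    class = "pipeline_config"
  )
}
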