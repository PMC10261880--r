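# Sequential, batched, parallel-decode streaming — the access pattern that
# makes basecalling I/O scale. Raw bytes are always fetched in a single
# forward pass; only the decompress/parse step of a fetched batch is farmed
# out to workers, so the worker count is unobservable in the output.

#' Stream a signal file as ordered read batches
#'
#' Opens a SLOW5/BLOW5 file for sequential streaming. Records are fetched in
#' file order in batches of `slow5_batchsize`; decompression and parsing of
#' a fetched batch may be distributed over up to `slow5_threads` forked
#' workers, which never changes the output, only the speed. Advance the
#' stream with [next_batch()]; every record of the file is yielded exactly
#' once, in file order.
#'
#' @param path A SLOW5/BLOW5 file.
#' @param slow5_batchsize Records fetched from the file at a time (>= 1).
#' @param slow5_threads Workers for decompressing/parsing a batch (>= 1).
#' @return An object of class `read_batch_stream`.
#' @examples
#' \dontrun{
#' s <- stream_batches("reads.blow5", slow5_batchsize = 4096, slow5_threads = 4)
#' while (!is.null(b <- next_batch(s))) message(length(b$reads), " reads")
#' close(s)
#' }
#' @export
stream_batches <- function(path, slow5_batchsize = 4096L, slow5_threads = 1L) {
  slow5_batchsize <- as.integer(slow5_batchsize)
  slow5_threads <- as.integer(slow5_threads)
  stopifnot(slow5_batchsize >= 1L, slow5_threads >= 1L)
  s <- new.env(parent = emptyenv())
  s$batchsize <- slow5_batchsize
  s$threads <- slow5_threads
  s$batch_index <- 0L
  s$done <- FALSE
  if (is_blow5(path)) {
    s$kind <- "binary"
    s$st <- blow5_open(path)
    st_buf_init(s$st)
    s$header <- s$st$header
  } else {
    s$kind <- "ascii"
    s$con <- file(path, "rt")
    lines <- character()
    repeat {
      l <- readLines(s$con, n = 1L, warn = FALSE)
      if (!length(l)) break
      if (!startsWith(l, "#")) { s$pushback <- l; break }
      lines <- c(lines, l)
    }
    s$header <- parse_header_ascii(lines)$header
  }
  class(s) <- "read_batch_stream"
  s
}

#' @export
print.read_batch_stream <- function(x, ...) {
  cat(sprintf("<read_batch_stream> %s dialect, batchsize %d, %d worker(s), next batch %d\n",
              x$kind, x$batchsize, x$threads, x$batch_index))
  invisible(x)
}

decode_batch <- function(items, decode_fun, threads) {
  if (threads > 1L && length(items) > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(items, decode_fun, mc.cores = threads)
  else
    lapply(items, decode_fun)
}

#' Fetch the next batch from a stream
#'
#' @param stream A [stream_batches()] object.
#' @return A list of class `read_batch` with `batch_index` (zero-based) and
#'   `reads` (list of [signal_read()], at most `slow5_batchsize` long), or
#'   `NULL` when the file is exhausted. All batches except possibly the last
#'   are full.
#' @export
next_batch <- function(stream) {
  stopifnot(inherits(stream, "read_batch_stream"))
  if (stream$done) return(NULL)
  bi <- stream$batch_index
  if (stream$kind == "binary") {
    payloads <- vector("list", stream$batchsize)
    n <- 0L
    repeat {
      rec <- tryCatch(st_next_payload_buffered(stream$st), error = function(e)
        stop("corrupt record in batch ", bi, " near offset ",
             stream$st$offset, ": ", conditionMessage(e), call. = FALSE))
      if (is.null(rec)) { stream$done <- TRUE; break }
      n <- n + 1L
      payloads[[n]] <- rec$payload
      if (n == stream$batchsize) break
    }
    if (n == 0L) return(NULL)
    header <- stream$header
    reads <- decode_batch(payloads[seq_len(n)],
                          function(p) decode_payload(p, header),
                          stream$threads)
  } else {
    lines <- character()
    if (!is.null(stream$pushback)) { lines <- stream$pushback; stream$pushback <- NULL }
    while (length(lines) < stream$batchsize) {
      more <- readLines(stream$con, n = stream$batchsize - length(lines),
                        warn = FALSE)
      if (!length(more)) { stream$done <- TRUE; break }
      lines <- c(lines, more[nzchar(more)])
    }
    if (!length(lines)) return(NULL)
    header <- stream$header
    reads <- tryCatch(
      decode_batch(lines, function(l) record_from_ascii(l, header),
                   stream$threads),
      error = function(e) stop("corrupt record in batch ", bi, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  err <- vapply(reads, inherits, TRUE, what = "try-error")
  if (any(err)) stop("corrupt record in batch ", bi)
  stream$batch_index <- bi + 1L
  structure(list(batch_index = bi, reads = reads), class = "read_batch")
}

#' @export
close.read_batch_stream <- function(con, ...) {
  if (con$kind == "binary") st_close(con$st) else close(con$con)
  invisible(NULL)
}

#' Collect every read of a file through the batch streamer
#'
#' Convenience wrapper that drains [stream_batches()] and concatenates the
#' batches, preserving file order.
#'
#' @inheritParams stream_batches
#' @return List of [signal_read()].
#' @export
collect_reads <- function(path, slow5_batchsize = 4096L, slow5_threads = 1L) {
  s <- stream_batches(path, slow5_batchsize, slow5_threads)
  on.exit(close(s))
  out <- list()
  while (!is.null(b <- next_batch(s))) out <- c(out, b$reads)
  out
}
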