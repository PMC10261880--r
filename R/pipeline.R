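# The basecall-dispatch workflow: start a basecall server with a bounded
# queue, connect a client, stream read batches from the signal file, submit
# them in chunks, and collect/write results. The server is realized
# in-process with an explicit bounded queue — the transport used by real
# server/client basecallers is incidental to the algorithmic contract, and
# an in-process queue makes the capacity invariant directly instrumentable.

server_new <- function(backend, capacity) {
  s <- new.env(parent = emptyenv())
  s$backend <- backend
  s$capacity <- capacity
  s$pending <- list()      # reads accepted but not yet dispatched
  s$in_flight <- 0L
  s$submitted <- 0L
  s$completed <- 0L
  s$max_load <- 0L
  s$results <- list()
  s$dispatches <- 0L
  s
}

server_load <- function(s) length(s$pending) + s$in_flight

# dispatch up to chunk reads to the backend; procs workers split the batch
server_dispatch <- function(s, chunk, procs) {
  n <- min(chunk, length(s$pending))
  if (n == 0L) return(invisible(s))
  batch <- s$pending[seq_len(n)]
  s$pending <- s$pending[-seq_len(n)]
  s$in_flight <- n
  bi <- s$dispatches
  res <- tryCatch({
    if (procs > 1L && n > 1L && .Platform$OS.type == "unix") {
      splits <- split(batch, cut(seq_len(n), min(procs, n), labels = FALSE))
      parts <- parallel::mclapply(splits, s$backend$call, mc.cores = procs)
      if (any(vapply(parts, inherits, TRUE, what = "try-error")))
        stop("worker failure")
      do.call(c, unname(parts))
    } else {
      s$backend$call(batch)
    }
  }, error = function(e)
    stop(sprintf("backend '%s' failed on batch %d (%d completed reads drained): %s",
                 s$backend$name, bi, s$completed, conditionMessage(e)),
         call. = FALSE))
  if (length(res) != n)
    stop(sprintf("backend '%s' returned %d results for %d reads in batch %d",
                 s$backend$name, length(res), n, bi))
  s$results <- c(s$results, res)
  s$in_flight <- 0L
  s$completed <- s$completed + n
  s$dispatches <- bi + 1L
  invisible(s)
}

server_submit <- function(s, reads, chunk, procs) {
  # submission blocks while the queue is full; in-process, "blocking" means
  # dispatching queued work until there is room
  while (server_load(s) + length(reads) > s$capacity)
    server_dispatch(s, chunk, procs)
  s$pending <- c(s$pending, reads)
  s$submitted <- s$submitted + length(reads)
  s$max_load <- max(s$max_load, server_load(s))
  invisible(s)
}

#' Run the basecall-dispatch pipeline
#'
#' The five-step workflow: (1) start the basecall server with a queue of
#' capacity `max_queued_reads`; (2) connect the client; (3) stream the
#' signal file sequentially in batches of `slow5_batchsize` using
#' `slow5_threads` decode workers; (4) submit reads to the server in chunks
#' of `guppy_batchsize`, blocking while the queue is full; (5) collect
#' results with `procs` workers and write FASTQ or unaligned SAM, optionally
#' split into pass/fail files at `qscore_threshold`. Every input read
#' appears exactly once in the output.
#'
#' @param input_path SLOW5/BLOW5 file to basecall.
#' @param output_path Output file (`.fastq` or `.sam` per
#'   `config$output_format`). With a qscore threshold, `.pass`/`.fail` are
#'   inserted before the extension.
#' @param config A [pipeline_config()].
#' @param backend A [basecaller_backend()]; defaults to the bundled mock.
#' @return A list of class `pipeline_summary`: `reads_in`, `reads_out`,
#'   `mean_qscore` (mean over reads of their mean qscores; `NaN` for an
#'   empty run), `max_queue_load`, `dispatches`, and `output_files`.
#' @export
run_pipeline <- function(input_path, output_path,
                         config = pipeline_config(),
                         backend = mock_backend()) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(backend, "basecaller_backend"))
  if (!file.exists(input_path)) stop("no such input file: ", input_path)
  # fail on unwritable output before the server starts
  probe <- tryCatch(suppressWarnings(file(output_path, "ab")), error = function(e)
    stop("output path not writable: ", output_path, call. = FALSE))
  close(probe)

  srv <- server_new(backend, config$max_queued_reads)          # 1. server up
  # 2. client connect (in-process: the submit/dispatch interface)
  stream <- stream_batches(input_path,                          # 3. stream
                           slow5_batchsize = config$slow5_batchsize,
                           slow5_threads = config$slow5_threads)
  on.exit(close(stream), add = TRUE)
  input_ids <- character()
  while (!is.null(b <- next_batch(stream))) {
    input_ids <- c(input_ids, vapply(b$reads, function(r) r$read_id, ""))
    reads <- b$reads
    while (length(reads)) {                                     # 4. submit
      take <- min(config$guppy_batchsize, length(reads))
      server_submit(srv, reads[seq_len(take)], config$guppy_batchsize,
                    config$procs)
      reads <- reads[-seq_len(take)]
    }
  }
  while (length(srv$pending))                                   # drain
    server_dispatch(srv, config$guppy_batchsize, config$procs)

  results <- srv$results                                        # 5. write
  if (config$sorted && length(results)) {
    ord <- order(vapply(results, function(r) r$read_id, ""), method = "radix")
    results <- results[ord]
  }
  writer <- if (config$output_format == "fastq") write_fastq else write_sam
  if (is.null(config$qscore_threshold)) {
    writer(results, output_path)
    outputs <- output_path
  } else {
    parts <- split_by_qscore(results, config$qscore_threshold)
    outputs <- c(pass = splice_suffix(output_path, "pass"),
                 fail = splice_suffix(output_path, "fail"))
    writer(parts$pass, outputs[["pass"]])
    writer(parts$fail, outputs[["fail"]])
  }

  mq <- vapply(results, function(r) r$mean_qscore, 0)
  structure(
    list(reads_in = length(input_ids),
         reads_out = length(results),
         mean_qscore = if (length(mq)) mean(mq) else NaN,
         max_queue_load = srv$max_load,
         dispatches = srv$dispatches,
         output_files = outputs),
    class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(sprintf("<pipeline_summary> %d reads in, %d out; mean qscore %.2f; peak queue load %d across %d dispatch(es)\n",
              x$reads_in, x$reads_out, x$mean_qscore, x$max_queue_load,
              x$dispatches))
  invisible(x)
}

splice_suffix <- function(path, tag) {
  ext <- tools::file_ext(path)
  if (nzchar(ext))
    sub(paste0("\\.", ext, "$"), paste0(".", tag, ".", ext), path)
  else paste0(path, ".", tag)
}
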