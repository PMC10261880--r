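# Access-pattern benchmarks. The scientific claim under test is a
# mechanism, not a wall-clock number: sequential streaming touches the file
# in one forward pass (O(1) seeks), while random access pays one seek per
# record, and on contended storage that asymmetry dominates. The
# instrumented reader counts logical seeks and bytes regardless of OS
# caching, so the mechanism is machine-independent; throughputs are
# reported but never asserted.

#' Benchmark sequential vs random access on a BLOW5 file
#'
#' Both modes decode every record exactly once. `"sequential"` drains
#' [stream_batches()] in a single forward pass; `"random"` shuffles the
#' indexed read ids (seeded) and fetches each via its byte offset. Reports
#' throughput together with instrumented I/O counters.
#'
#' @param path An indexed BLOW5 file.
#' @param mode `"sequential"` or `"random"`.
#' @param batchsize Batch size for sequential streaming.
#' @param threads Decode workers for sequential streaming.
#' @param seed Seed for the random-access shuffle.
#' @param index Optional index for random mode; when `NULL` the side-car is
#'   loaded. Random mode without any index is an error (build one with
#'   [build_index()] or the CLI `index` command).
#' @return A list of class `bench_result`: `mode`, `n_reads`,
#'   `total_samples`, `seeks`, `bytes_read`, `elapsed_s`, `reads_per_sec`,
#'   and `read_ids` (decode order).
#' @export
bench_access <- function(path, mode = c("sequential", "random"),
                         batchsize = 4096L, threads = 1L, seed = 1L,
                         index = NULL) {
  mode <- match.arg(mode)
  t0 <- proc.time()[["elapsed"]]
  if (mode == "sequential") {
    s <- stream_batches(path, slow5_batchsize = batchsize,
                        slow5_threads = threads)
    on.exit(close(s))
    if (s$kind != "binary") stop("bench_access requires a BLOW5 binary file")
    ids <- character(); nsamp <- 0
    while (!is.null(b <- next_batch(s))) {
      ids <- c(ids, vapply(b$reads, function(r) r$read_id, ""))
      nsamp <- nsamp + sum(vapply(b$reads, function(r) length(r$raw_signal), 0L))
    }
    seeks <- s$st$seeks
    bytes <- s$st$bytes_read
  } else {
    if (is.null(index)) {
      if (!file.exists(index_path(path)))
        stop("random access needs an index for ", path,
             ": run build_index() (CLI: slow5pipe index)")
      index <- load_index(path)
    }
    st <- blow5_open(path)
    on.exit(st_close(st))
    ord <- with_sim_seed(seed, function() sample.int(nrow(index$entries)))
    ids <- character(nrow(index$entries)); nsamp <- 0
    for (k in seq_along(ord)) {
      i <- ord[k]
      r <- fetch_at(st, index$entries$offset[i], index$entries$length[i])
      ids[k] <- r$read_id
      nsamp <- nsamp + length(r$raw_signal)
    }
    seeks <- st$seeks
    bytes <- st$bytes_read
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(
    list(mode = mode, n_reads = length(ids), total_samples = nsamp,
         seeks = seeks, bytes_read = bytes, elapsed_s = elapsed,
         reads_per_sec = if (elapsed > 0) length(ids) / elapsed else NA_real_,
         read_ids = ids),
    class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> %s: %d reads in %.2fs (%.0f reads/s); %d seek(s), %.0f bytes read\n",
              x$mode, x$n_reads, x$elapsed_s, x$reads_per_sec, x$seeks,
              x$bytes_read))
  invisible(x)
}

#' Benchmark identical jobs running in parallel
#'
#' Launches `jobs` concurrent [bench_access()] runs, one per independent
#' file copy (separate copies avoid cache sharing between jobs, mirroring
#' how parallel basecalling jobs each own their data), and reports per-job
#' timings plus the contention ratio `job_time(k) / job_time(1)`. With
#' `jobs = 1` the ratio is 1 by definition.
#'
#' @param paths Character vector of independent copies of the data file; at
#'   least `jobs` long.
#' @param mode,batchsize,threads,seed Passed to [bench_access()].
#' @param jobs Number of concurrent jobs.
#' @return A list of class `bench_parallel_result` with `per_job` (data
#'   frame: job, n_reads, seeks, elapsed_s, reads_per_sec), `baseline_s`
#'   (single-job time), and `ratio`.
#' @export
bench_parallel <- function(paths, mode = c("sequential", "random"),
                           jobs = length(paths), batchsize = 4096L,
                           threads = 1L, seed = 1L) {
  mode <- match.arg(mode)
  jobs <- as.integer(jobs)
  if (length(paths) < jobs)
    stop("fewer file copies (", length(paths), ") than jobs (", jobs, ")")
  run1 <- function(p) bench_access(p, mode = mode, batchsize = batchsize,
                                   threads = threads, seed = seed)
  if (jobs == 1L) {
    r <- run1(paths[1])
    per_job <- data.frame(job = 1L, n_reads = r$n_reads, seeks = r$seeks,
                          elapsed_s = r$elapsed_s,
                          reads_per_sec = r$reads_per_sec)
    return(structure(list(per_job = per_job, baseline_s = r$elapsed_s,
                          ratio = 1.0),
                     class = "bench_parallel_result"))
  }
  baseline <- run1(paths[1])$elapsed_s
  res <- if (.Platform$OS.type == "unix")
    parallel::mclapply(paths[seq_len(jobs)], run1, mc.cores = jobs)
  else lapply(paths[seq_len(jobs)], run1)
  per_job <- data.frame(
    job = seq_len(jobs),
    n_reads = vapply(res, function(r) r$n_reads, 0L),
    seeks = vapply(res, function(r) r$seeks, 0L),
    elapsed_s = vapply(res, function(r) r$elapsed_s, 0),
    reads_per_sec = vapply(res, function(r) r$reads_per_sec, 0))
  structure(
    list(per_job = per_job, baseline_s = baseline,
         ratio = mean(per_job$elapsed_s) / baseline),
    class = "bench_parallel_result")
}

#' @export
print.bench_parallel_result <- function(x, ...) {
  cat(sprintf("<bench_parallel_result> %d job(s); mean job time %.2fs; ratio vs single job %.2f\n",
              nrow(x$per_job), mean(x$per_job$elapsed_s), x$ratio))
  invisible(x)
}

#' Format benchmark results as a TSV report
#'
#' @param ... [bench_access()] results.
#' @param jobs Job count to record per row.
#' @return Character vector of TSV lines (with header).
#' @export
bench_report <- function(..., jobs = 1L) {
  rs <- list(...)
  c("mode\tjobs\treads\treads_per_sec\tseeks\tbytes",
    vapply(rs, function(r)
      sprintf("%s\t%d\t%d\t%.1f\t%d\t%.0f", r$mode, jobs, r$n_reads,
              r$reads_per_sec, r$seeks, r$bytes_read), ""))
}
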