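# FASTQ and unaligned-SAM emission, plus pass/fail splitting by mean
# qscore. Both formats carry the same (sequence, qualities) content and are
# mutually convertible losslessly; SAM additionally stores the read-level
# mean qscore in auxiliary tags (qs:i rounded half-up, mq:f full precision)
# so a split can be reproduced from either representation.

PHRED_MAX_ENCODABLE <- 93L

round_half_up <- function(x) floor(x + 0.5)

# phred+33 encoding; values outside [0,93] are clamped with a logged count
phred33_encode <- function(q, context = "record") {
  q <- as.integer(q)
  n_clamped <- sum(q < 0L | q > PHRED_MAX_ENCODABLE)
  if (n_clamped > 0L)
    message(sprintf("%s: clamped %d quality value(s) to the encodable range [0, %d]",
                    context, n_clamped, PHRED_MAX_ENCODABLE))
  q <- pmin(pmax(q, 0L), PHRED_MAX_ENCODABLE)
  intToUtf8(q + 33L)
}

phred33_decode <- function(s) {
  if (!nzchar(s)) return(integer())
  utf8ToInt(s) - 33L
}

#' Write basecall results as FASTQ or unaligned SAM
#'
#' FASTQ records are the standard 4 lines with phred+33 quality characters.
#' SAM records carry flag 4 (unmapped) with RNAME/POS/CIGAR unset and two
#' auxiliary tags for the mean qscore: `qs:i` (rounded half-up) and `mq:f`
#' (full precision). Quality values outside the encodable range 0..93 are
#' clamped (with a logged count).
#'
#' @param results List of [basecall_result()].
#' @param path Output path.
#' @return Number of records written, invisibly.
#' @export
write_fastq <- function(results, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(results)) {
    lines <- vapply(results, function(r)
      paste0("@", r$read_id, "\n", r$sequence, "\n+\n",
             phred33_encode(r$qualities, r$read_id)), "")
    writeLines(lines, con, sep = "\n")
  }
  invisible(length(results))
}

sam_header_lines <- function()
  c("@HD\tVN:1.6\tSO:unknown",
    "@PG\tID:slow5pipe\tPN:slow5pipe")

sam_record_line <- function(r) {
  empty <- !nzchar(r$sequence)
  paste(r$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
        if (empty) "*" else r$sequence,
        if (empty) "*" else phred33_encode(r$qualities, r$read_id),
        paste0("qs:i:", if (is.nan(r$mean_qscore)) 0L
               else as.integer(round_half_up(r$mean_qscore))),
        paste0("mq:f:", sprintf("%.6g", r$mean_qscore)),
        sep = "\t")
}

#' @rdname write_fastq
#' @export
write_sam <- function(results, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sam_header_lines(), con, sep = "\n")
  if (length(results))
    writeLines(vapply(results, sam_record_line, ""), con, sep = "\n")
  invisible(length(results))
}

#' Parse basecall results back from FASTQ or unaligned SAM
#'
#' Used by the splitting tool and by round-trip checks. Both parsers return
#' the decoded results together with the verbatim record text, so that
#' splitting can route records byte-identically.
#'
#' @param path Input file.
#' @return A list with `results` (list of [basecall_result()]), `records`
#'   (character vector, one verbatim record each — 4 joined lines for
#'   FASTQ, one line for SAM), and for SAM `header_lines` and `tag_qscore`
#'   (numeric, `NA` where no tag was present).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: ", length(lines), " lines is not a multiple of 4")
  n <- length(lines) %/% 4L
  results <- vector("list", n)
  records <- character(n)
  for (i in seq_len(n)) {
    chunk <- lines[(4L * (i - 1L) + 1L):(4L * i)]
    if (!startsWith(chunk[1], "@") || !startsWith(chunk[3], "+"))
      stop("malformed FASTQ record at index ", i)
    id <- sub("\\s.*$", "", substring(chunk[1], 2L))
    q <- phred33_decode(chunk[4])
    if (length(q) != nchar(chunk[2]))
      stop("malformed FASTQ record at index ", i,
           ": sequence/quality length mismatch")
    results[[i]] <- basecall_result(id, chunk[2], q)
    records[i] <- paste(chunk, collapse = "\n")
  }
  list(results = results, records = records)
}

#' @rdname read_fastq
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "@")
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  results <- vector("list", length(body))
  tagq <- rep(NA_real_, length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("malformed SAM record at index ", i)
    seqs <- if (f[10] == "*") "" else f[10]
    quals <- if (f[11] == "*") integer() else phred33_decode(f[11])
    results[[i]] <- basecall_result(f[1], seqs, quals)
    opts <- f[-(1:11)]
    mq <- grep("^mq:f:", opts, value = TRUE)
    qs <- grep("^qs:i:", opts, value = TRUE)
    if (length(mq)) tagq[i] <- as.numeric(sub("^mq:f:", "", mq[1]))
    else if (length(qs)) tagq[i] <- as.numeric(sub("^qs:i:", "", qs[1]))
  }
  list(results = results, records = body, header_lines = lines[is_hdr],
       tag_qscore = tagq)
}

#' Partition basecall results by mean qscore
#'
#' Pass/fail routing at an inclusive boundary: a read passes when its mean
#' qscore is greater than or equal to `threshold` (so a read at exactly the
#' threshold passes, matching the common q >= 7 "pass" convention).
#'
#' @param results List of [basecall_result()].
#' @param threshold Non-negative mean-qscore threshold.
#' @return A list with disjoint elements `pass` and `fail` whose union is
#'   the input.
#' @export
split_by_qscore <- function(results, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  mq <- vapply(results, function(r) r$mean_qscore, 0)
  passes <- !is.nan(mq) & mq >= threshold
  list(pass = results[passes], fail = results[!passes])
}

#' Split a FASTQ or unaligned-SAM file into pass/fail files
#'
#' Standalone re-splitting tool: routes each record of the input to
#' `<prefix>.pass.<ext>` or `<prefix>.fail.<ext>` at an inclusive
#' mean-qscore boundary, without altering record bytes (SAM header lines are
#' replicated into both outputs). For FASTQ the mean qscore is recomputed
#' from the per-base qualities via [mean_qscore()]. For SAM the stored tag
#' (`mq:f`, falling back to `qs:i`) is trusted by default; set
#' `recompute = TRUE` to recompute from the base qualities instead. Tagless
#' SAM records are always recomputed.
#'
#' @param input Input FASTQ or SAM file.
#' @param threshold Non-negative mean-qscore threshold.
#' @param output_prefix Prefix for the two output files; defaults to the
#'   input path without its extension.
#' @param format `"auto"` (by extension, falling back to content sniffing),
#'   `"fastq"`, or `"sam"`.
#' @param recompute Recompute SAM mean qscores from base qualities even when
#'   a tag is present.
#' @return Named integer vector `c(pass = ..., fail = ...)`, invisibly.
#' @export
split_qscore_tool <- function(input, threshold,
                              output_prefix = NULL,
                              format = c("auto", "fastq", "sam"),
                              recompute = FALSE) {
  format <- match.arg(format)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  ext <- tolower(tools::file_ext(input))
  if (format == "auto") {
    format <- if (ext == "sam") "sam"
    else if (ext %in% c("fastq", "fq")) "fastq"
    else {
      l1 <- readLines(input, n = 1L, warn = FALSE)
      if (length(l1) && grepl("^@(HD|PG|SQ|RG|CO)\t", l1)) "sam" else "fastq"
    }
  }
  if (is.null(output_prefix))
    output_prefix <- if (nzchar(ext)) sub(paste0("\\.", ext, "$"), "", input)
                     else input
  out_ext <- if (format == "sam") "sam" else if (nzchar(ext)) ext else "fastq"
  out_pass <- paste0(output_prefix, ".pass.", out_ext)
  out_fail <- paste0(output_prefix, ".fail.", out_ext)
  cleanup <- TRUE
  on.exit(if (cleanup) unlink(c(out_pass, out_fail)), add = TRUE)

  if (format == "fastq") {
    parsed <- tryCatch(read_fastq(input), error = function(e)
      stop("split failed: ", conditionMessage(e), call. = FALSE))
    mq <- vapply(parsed$results, function(r) r$mean_qscore, 0)
    prefix_lines <- character()
  } else {
    parsed <- tryCatch(read_sam(input), error = function(e)
      stop("split failed: ", conditionMessage(e), call. = FALSE))
    mq <- if (recompute) vapply(parsed$results, function(r) r$mean_qscore, 0)
          else parsed$tag_qscore
    need <- is.na(mq)
    if (any(need))
      mq[need] <- vapply(parsed$results[need], function(r) r$mean_qscore, 0)
    prefix_lines <- parsed$header_lines
  }
  passes <- !is.nan(mq) & mq >= threshold
  write_routed <- function(path, recs) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (length(prefix_lines)) writeLines(prefix_lines, con, sep = "\n")
    if (length(recs)) writeLines(recs, con, sep = "\n")
  }
  write_routed(out_pass, parsed$records[passes])
  write_routed(out_fail, parsed$records[!passes])
  cleanup <- FALSE
  invisible(c(pass = sum(passes), fail = sum(!passes)))
}
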