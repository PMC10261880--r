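# SLOW5 (ASCII TSV) and BLOW5 (compressed binary) file I/O.
#
# Binary layout (this package's own, versioned):
#   magic (8 bytes: "BLW5", version byte, 0x0A 0x1A 0x00)
#   u32 header-body length
#   header body: u8 record-codec, u8 signal-codec, u32 num_read_groups,
#     per group {u32 n_attrs, per attr {str16 name, str32 value}},
#     u16 n_aux, per field {str16 name, u8 type}
#   records: u32 payload length, payload (record-codec compressed)
# All integers little-endian. Everything is byte-deterministic given the
# same inputs (no timestamps, stable attribute order), so tests can compare
# file digests.

BLOW5_MAGIC <- as.raw(c(0x42, 0x4C, 0x57, 0x35, 0x01, 0x0A, 0x1A, 0x00))
ASCII_SENTINEL <- "#slow5pipe_ascii"

rc_id <- function(codec) match(codec, RECORD_CODECS) - 1L
sc_id <- function(codec) match(codec, SIGNAL_CODECS) - 1L

# ---- little-endian packing helpers ------------------------------------------

w_u8 <- function(x) as.raw(x)
w_u16 <- function(x) {
  if (x > 32767L) stop("string too long for 16-bit length prefix")
  writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}
w_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
w_f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
w_str16 <- function(s) { b <- charToRaw(s); c(w_u16(length(b)), b) }
w_str32 <- function(s) { b <- charToRaw(s); c(w_u32(length(b)), b) }

cur_new <- function(bytes) {
  e <- new.env(parent = emptyenv()); e$b <- bytes; e$p <- 1L; e
}
cur_take <- function(cur, n) {
  if (cur$p + n - 1L > length(cur$b)) stop("truncated header or record body")
  out <- cur$b[seq.int(cur$p, length.out = n)]
  cur$p <- cur$p + as.integer(n)
  out
}
cur_u8 <- function(cur) as.integer(cur_take(cur, 1L))
cur_u16 <- function(cur) readBin(cur_take(cur, 2L), "integer", size = 2L,
                                 signed = FALSE, endian = "little")
cur_u32 <- function(cur) readBin(cur_take(cur, 4L), "integer", size = 4L,
                                 endian = "little")
cur_f64 <- function(cur) readBin(cur_take(cur, 8L), "double", size = 8L,
                                 endian = "little")
cur_str16 <- function(cur) rawToChar(cur_take(cur, cur_u16(cur)))
cur_str32 <- function(cur) rawToChar(cur_take(cur, cur_u32(cur)))
cur_done <- function(cur) cur$p == length(cur$b) + 1L

# ---- header serialization ----------------------------------------------------

ser_header_bin <- function(header) {
  parts <- list(w_u8(rc_id(header$record_codec)), w_u8(sc_id(header$signal_codec)),
                w_u32(header$num_read_groups))
  for (a in header$attributes) {
    parts <- c(parts, list(w_u32(length(a))))
    for (i in seq_along(a))
      parts <- c(parts, list(w_str16(names(a)[i]), w_str32(a[[i]])))
  }
  parts <- c(parts, list(w_u16(nrow(header$aux_schema))))
  for (i in seq_len(nrow(header$aux_schema)))
    parts <- c(parts, list(w_str16(header$aux_schema$name[i]),
                           w_u8(match(header$aux_schema$type[i], AUX_TYPES))))
  do.call(c, parts)
}

parse_header_bin <- function(bytes) {
  cur <- cur_new(bytes)
  rc <- cur_u8(cur); sc <- cur_u8(cur)
  if (rc < 0L || rc >= length(RECORD_CODECS)) stop("unknown record codec id: ", rc)
  if (sc < 0L || sc >= length(SIGNAL_CODECS)) stop("unknown signal codec id: ", sc)
  ngrp <- cur_u32(cur)
  attrs <- vector("list", ngrp)
  for (g in seq_len(ngrp)) {
    n <- cur_u32(cur)
    a <- character(n); nm <- character(n)
    for (i in seq_len(n)) { nm[i] <- cur_str16(cur); a[i] <- cur_str32(cur) }
    attrs[[g]] <- setNames(a, nm)
  }
  naux <- cur_u16(cur)
  nms <- character(naux); tps <- character(naux)
  for (i in seq_len(naux)) {
    nms[i] <- cur_str16(cur)
    tps[i] <- AUX_TYPES[cur_u8(cur)]
  }
  if (!cur_done(cur)) stop("trailing bytes after header body")
  run_header(num_read_groups = ngrp, attributes = attrs,
             aux_schema = data.frame(name = nms, type = tps,
                                     stringsAsFactors = FALSE),
             record_codec = RECORD_CODECS[rc + 1L],
             signal_codec = SIGNAL_CODECS[sc + 1L])
}

ser_header_ascii <- function(header) {
  lines <- c(paste0(ASCII_SENTINEL, "\t1"),
             paste0("#record_codec\t", header$record_codec),
             paste0("#signal_codec\t", header$signal_codec),
             paste0("#num_read_groups\t", header$num_read_groups))
  for (g in seq_along(header$attributes)) {
    a <- header$attributes[[g]]
    for (i in seq_along(a))
      lines <- c(lines, paste("#attr", g - 1L, names(a)[i], a[[i]], sep = "\t"))
  }
  for (i in seq_len(nrow(header$aux_schema)))
    lines <- c(lines, paste("#aux", header$aux_schema$name[i],
                            header$aux_schema$type[i], sep = "\t"))
  cols <- c("read_id", "read_group", "digitisation", "offset", "range",
            "sampling_rate", "len_raw_signal", "raw_signal",
            header$aux_schema$name)
  c(lines, paste0("#columns\t", paste(cols, collapse = "\t")))
}

parse_header_ascii <- function(lines) {
  if (!length(lines) || !startsWith(lines[1], paste0(ASCII_SENTINEL, "\t")))
    stop("bad magic: not a SLOW5 ASCII file")
  hdr_lines <- lines[startsWith(lines, "#")]
  fields <- strsplit(hdr_lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[`, "", 1L)
  get1 <- function(k) {
    i <- which(key == k)
    if (!length(i)) stop("truncated header: missing ", k)
    fields[[i[1]]][2]
  }
  version <- get1(ASCII_SENTINEL)
  if (!identical(version, "1")) stop("unsupported version: ", version)
  ngrp <- as.integer(get1("#num_read_groups"))
  attrs <- rep(list(character()), ngrp)
  for (f in fields[key == "#attr"]) {
    g <- as.integer(f[2]) + 1L
    attrs[[g]] <- c(attrs[[g]], setNames(f[4], f[3]))
  }
  aux_f <- fields[key == "#aux"]
  schema <- data.frame(name = vapply(aux_f, `[`, "", 2L),
                       type = vapply(aux_f, `[`, "", 3L),
                       stringsAsFactors = FALSE)
  header <- run_header(num_read_groups = ngrp, attributes = attrs,
                       aux_schema = schema,
                       record_codec = get1("#record_codec"),
                       signal_codec = get1("#signal_codec"))
  list(header = header, n_header_lines = length(hdr_lines))
}

# ---- record serialization ----------------------------------------------------

pack_record <- function(read, header) {
  sig <- encode_signal(read$raw_signal, header$signal_codec)
  parts <- list(w_str16(read$read_id),
                w_u32(read$read_group),
                w_f64(c(read$digitisation, read$offset, read$range,
                        read$sampling_rate)),
                w_u32(length(read$raw_signal)),
                w_u32(length(sig)),
                sig)
  schema <- header$aux_schema
  for (i in seq_len(nrow(schema))) {
    v <- read$aux[[schema$name[i]]]
    parts <- c(parts, list(switch(schema$type[i],
                                  int = w_u32(v),
                                  double = w_f64(v),
                                  string = w_str16(v))))
  }
  do.call(c, parts)
}

# binary record parsing lives in compiled code (unpack_record_cpp): it is
# the hot loop of every sequential scan, and it re-checks the type
# invariants (bounds, 16-bit range, calibration positivity, id shape) as
# part of deserialization
unpack_record <- function(payload, header) {
  l <- unpack_record_cpp(payload,
                         sc_id(header$signal_codec),
                         match(header$aux_schema$type, AUX_TYPES),
                         header$aux_schema$name,
                         header$num_read_groups)
  class(l) <- "signal_read"
  l
}

record_to_ascii <- function(read, header) {
  fields <- c(read$read_id, read$read_group,
              sprintf("%.17g", c(read$digitisation, read$offset, read$range,
                                 read$sampling_rate)),
              length(read$raw_signal),
              paste(read$raw_signal, collapse = ","))
  schema <- header$aux_schema
  for (i in seq_len(nrow(schema))) {
    v <- read$aux[[schema$name[i]]]
    fields <- c(fields, switch(schema$type[i],
                               int = sprintf("%d", as.integer(v)),
                               double = sprintf("%.17g", v),
                               string = v))
  }
  paste(fields, collapse = "\t")
}

record_from_ascii <- function(line, header) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  n_fixed <- 8L
  schema <- header$aux_schema
  if (length(f) != n_fixed + nrow(schema))
    stop("malformed SLOW5 row: expected ", n_fixed + nrow(schema),
         " fields, got ", length(f))
  n_samples <- as.integer(f[7])
  sig <- if (n_samples == 0L) integer() else
    as.integer(strsplit(f[8], ",", fixed = TRUE)[[1]])
  if (length(sig) != n_samples)
    stop("malformed SLOW5 row: len_raw_signal disagrees with raw_signal")
  aux <- list()
  for (i in seq_len(nrow(schema)))
    aux[[schema$name[i]]] <- switch(schema$type[i],
                                    int = as.integer(f[n_fixed + i]),
                                    double = as.numeric(f[n_fixed + i]),
                                    string = f[n_fixed + i])
  read <- signal_read(f[1], raw_signal = sig, read_group = as.integer(f[2]),
                      digitisation = as.numeric(f[3]), offset = as.numeric(f[4]),
                      range = as.numeric(f[5]), sampling_rate = as.numeric(f[6]),
                      aux = aux)
  validate_read_against_header(read, header)
  read
}

check_writable_reads <- function(reads, header, existing_ids = character()) {
  ids <- vapply(reads, function(r) r$read_id, "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate read_id within one file: ", paste(unique(dup), collapse = ", "))
  clash <- intersect(ids, existing_ids)
  if (length(clash))
    stop("read_id collision with existing record(s): ",
         paste(clash, collapse = ", "))
  for (r in reads) {
    validate_read_against_header(r, header)
    for (nm in names(r$aux))
      if (is.character(r$aux[[nm]]) && grepl("[\t\n]", r$aux[[nm]]))
        stop(sprintf("read '%s': string aux '%s' contains tab/newline",
                     r$read_id, nm))
  }
  ids
}

# ---- writing -----------------------------------------------------------------

#' Write a SLOW5/BLOW5 file
#'
#' Writes a header section followed by one record per read, in input order.
#' `binary = TRUE` produces the compressed binary dialect (BLOW5);
#' `binary = FALSE` the tab-separated ASCII dialect (SLOW5). By default the
#' dialect is inferred from the file extension (`.blow5` means binary).
#' Output is byte-deterministic for identical inputs.
#'
#' @param path Output path.
#' @param header A [run_header()].
#' @param reads List of [signal_read()] objects; `read_id`s must be unique
#'   and aux fields must conform to the header schema.
#' @param binary Write the binary dialect?
#' @return Number of records written, invisibly.
#' @export
write_slow5 <- function(path, header, reads,
                        binary = grepl("\\.blow5$", path)) {
  stopifnot(inherits(header, "run_header"))
  check_writable_reads(reads, header)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(BLOW5_MAGIC, con)
    hb <- ser_header_bin(header)
    writeBin(c(w_u32(length(hb)), hb), con)
    buf <- list(); bn <- 0L
    for (r in reads) {
      comp <- compress_record(pack_record(r, header), header$record_codec)
      buf[[length(buf) + 1L]] <- c(w_u32(length(comp)), comp)
      bn <- bn + 1L
      if (bn == 512L) { writeBin(do.call(c, buf), con); buf <- list(); bn <- 0L }
    }
    if (bn) writeBin(do.call(c, buf), con)
  } else {
    con <- file(path, "wb")  # binary mode keeps line endings deterministic
    on.exit(close(con))
    writeLines(ser_header_ascii(header), con, sep = "\n")
    if (length(reads))
      writeLines(vapply(reads, record_to_ascii, "", header = header), con,
                 sep = "\n")
  }
  invisible(length(reads))
}

#' Append reads to an existing SLOW5/BLOW5 file
#'
#' New records follow the existing ones; previously written bytes are not
#' touched. The file's own header governs codecs and the aux schema, so the
#' appended reads must conform to it and must not reuse an existing
#' `read_id`. Appending invalidates any side-car index (stale indexes are
#' detected on load).
#'
#' @param path Existing SLOW5/BLOW5 file.
#' @param reads List of [signal_read()] objects to append.
#' @return New total record count, invisibly.
#' @export
append_slow5 <- function(path, reads) {
  if (!file.exists(path)) stop("cannot append: file does not exist: ", path)
  header <- read_header(path)
  existing <- read_slow5(path)
  existing_ids <- vapply(existing$reads, function(r) r$read_id, "")
  check_writable_reads(reads, header, existing_ids = existing_ids)
  if (is_blow5(path)) {
    con <- file(path, "ab")
    on.exit(close(con))
    for (r in reads) {
      comp <- compress_record(pack_record(r, header), header$record_codec)
      writeBin(c(w_u32(length(comp)), comp), con)
    }
  } else {
    con <- file(path, "ab")
    on.exit(close(con))
    if (length(reads))
      writeLines(vapply(reads, record_to_ascii, "", header = header), con,
                 sep = "\n")
  }
  invisible(length(existing_ids) + length(reads))
}

# ---- reading -----------------------------------------------------------------

is_blow5 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 8L)
  length(head) == 8L && identical(head[1:4], BLOW5_MAGIC[1:4])
}

#' Read the header of a SLOW5/BLOW5 file
#'
#' Detects the dialect, validates magic bytes and version, and returns the
#' [run_header()] exactly as written (attribute order preserved).
#'
#' @param path A SLOW5/BLOW5 file.
#' @return A [run_header()].
#' @export
read_header <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 8L)
  if (length(head) == 8L && identical(head[1:4], BLOW5_MAGIC[1:4])) {
    if (!identical(head, BLOW5_MAGIC))
      stop("unsupported version byte in BLOW5 magic: ", as.integer(head[5]))
    lenraw <- readBin(con, "raw", n = 4L)
    if (length(lenraw) < 4L) stop("truncated header: missing length")
    hlen <- readBin(lenraw, "integer", size = 4L, endian = "little")
    hb <- readBin(con, "raw", n = hlen)
    if (length(hb) < hlen) stop("truncated header body")
    return(parse_header_bin(hb))
  }
  # ASCII dialect: the first byte must open a "#"-prefixed header line
  if (!length(head) || head[1] != charToRaw("#"))
    stop("bad magic bytes: not a SLOW5/BLOW5 file")
  lines <- readLines(path, warn = FALSE)
  parse_header_ascii(lines)$header
}

# instrumented low-level binary stream; counters feed the bench module
blow5_open <- function(path) {
  if (!is_blow5(path)) stop("not a BLOW5 binary file: ", path)
  st <- new.env(parent = emptyenv())
  st$con <- file(path, "rb")
  st$path <- path
  st$bytes_read <- 0
  st$seeks <- 0L
  magic <- st_read(st, 8L)
  if (!identical(magic, BLOW5_MAGIC)) stop("bad magic bytes")
  hlen <- readBin(st_read(st, 4L), "integer", size = 4L, endian = "little")
  st$header <- parse_header_bin(st_read(st, hlen))
  st$data_start <- 12L + hlen
  st$offset <- st$data_start
  st
}

st_read <- function(st, n) {
  out <- readBin(st$con, "raw", n = n)
  st$bytes_read <- st$bytes_read + length(out)
  out
}

st_seek <- function(st, pos) {
  seek(st$con, where = pos, origin = "start")
  st$seeks <- st$seeks + 1L
  st$offset <- pos
}

st_close <- function(st) close(st$con)

# next length-prefixed compressed payload, or NULL at EOF
st_next_payload <- function(st) {
  at <- st$offset
  lenraw <- st_read(st, 4L)
  if (length(lenraw) == 0L) return(NULL)
  if (length(lenraw) < 4L)
    stop("truncated record at offset ", at, ": incomplete length prefix")
  len <- readBin(lenraw, "integer", size = 4L, endian = "little")
  payload <- st_read(st, len)
  if (length(payload) < len)
    stop("truncated record at offset ", at, ": expected ", len,
         " payload bytes, got ", length(payload))
  st$offset <- at + 4L + len
  list(offset = at, length = 4L + len, payload = payload)
}

decode_payload <- function(payload, header)
  unpack_record(decompress_record(payload, header$record_codec), header)

# read_id alone, without decoding signal/aux; used by the indexer
payload_read_id <- function(payload, header) {
  cur <- cur_new(decompress_record(payload, header$record_codec))
  cur_str16(cur)
}

# Buffered sequential record fetching: the file is consumed in large
# forward block reads (default 1 MiB) and records are sliced out of the
# buffer in memory. This is what "sequential access" buys mechanically —
# bulk transfers instead of one small read (or seek) per record.
BLOCK_BYTES <- 1048576L

st_buf_init <- function(st) { st$buf <- raw(); st$bufpos <- 1L; invisible(st) }

st_buf_avail <- function(st) length(st$buf) - st$bufpos + 1L

st_buf_fill <- function(st, n) {
  while (st_buf_avail(st) < n) {
    chunk <- st_read(st, BLOCK_BYTES)
    if (!length(chunk)) return(FALSE)
    st$buf <- c(if (st_buf_avail(st) > 0L)
      st$buf[st$bufpos:length(st$buf)] else raw(), chunk)
    st$bufpos <- 1L
  }
  TRUE
}

st_buf_take <- function(st, n) {
  out <- st$buf[seq.int(st$bufpos, length.out = n)]
  st$bufpos <- st$bufpos + as.integer(n)
  out
}

# buffered equivalent of st_next_payload (forward-only)
st_next_payload_buffered <- function(st) {
  at <- st$offset
  if (!st_buf_fill(st, 4L)) {
    if (st_buf_avail(st) == 0L) return(NULL)
    stop("truncated record at offset ", at, ": incomplete length prefix")
  }
  len <- readBin(st_buf_take(st, 4L), "integer", size = 4L, endian = "little")
  if (!st_buf_fill(st, len))
    stop("truncated record at offset ", at, ": expected ", len,
         " payload bytes, got ", st_buf_avail(st))
  payload <- st_buf_take(st, len)
  st$offset <- at + 4L + len
  list(offset = at, length = 4L + len, payload = payload)
}

#' Read an entire SLOW5/BLOW5 file into memory
#'
#' Sequentially decodes every record. For batched streaming with bounded
#' memory use [stream_batches()] instead.
#'
#' @param path A SLOW5/BLOW5 file.
#' @return A list with elements `header` (a [run_header()]) and `reads`
#'   (list of [signal_read()]).
#' @export
read_slow5 <- function(path) {
  if (is_blow5(path)) {
    st <- blow5_open(path)
    st_buf_init(st)
    on.exit(st_close(st))
    reads <- list()
    i <- 0L
    repeat {
      rec <- st_next_payload_buffered(st)
      if (is.null(rec)) break
      i <- i + 1L
      reads[[i]] <- decode_payload(rec$payload, st$header)
    }
    return(list(header = st$header, reads = reads))
  }
  lines <- readLines(path, warn = FALSE)
  ph <- parse_header_ascii(lines)
  rows <- lines[!startsWith(lines, "#")]
  rows <- rows[nzchar(rows)]
  list(header = ph$header,
       reads = lapply(rows, record_from_ascii, header = ph$header))
}

# ---- random-access index -----------------------------------------------------

index_path <- function(path) paste0(path, ".idx")

file_fingerprint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 64L)
  list(size = file.size(path), head = paste(as.character(head), collapse = ""))
}

#' Build a byte-offset index for a BLOW5 file
#'
#' Scans the binary file once, recording each record's byte offset and
#' length, and persists the result as a side-car text file (`<path>.idx`)
#' so later sessions can random-access without rescanning. The side-car
#' stores a fingerprint (data-file size plus leading bytes) used to detect
#' staleness. Random access is defined for the binary dialect only; ASCII
#' files are sequential-only.
#'
#' @param path A BLOW5 file.
#' @return An object of class `blow5_index` with a data frame `entries`
#'   (`read_id`, `offset`, `length`) and `source_path`.
#' @export
build_index <- function(path) {
  st <- blow5_open(path)
  st_buf_init(st)
  on.exit(st_close(st))
  ids <- character(); offs <- numeric(); lens <- numeric()
  last_good <- st$data_start
  repeat {
    rec <- tryCatch(st_next_payload_buffered(st), error = function(e)
      stop("index error: ", conditionMessage(e),
           " (last good offset: ", last_good, ")", call. = FALSE))
    if (is.null(rec)) break
    ids <- c(ids, payload_read_id(rec$payload, st$header))
    offs <- c(offs, rec$offset)
    lens <- c(lens, rec$length)
    last_good <- rec$offset + rec$length
  }
  idx <- structure(
    list(entries = data.frame(read_id = ids, offset = offs, length = lens,
                              stringsAsFactors = FALSE),
         source_path = path),
    class = "blow5_index")
  fp <- file_fingerprint(path)
  con <- file(index_path(path), "wb")
  writeLines(c("#blow5_index\t1",
               paste0("#data_size\t", format(fp$size, scientific = FALSE)),
               paste0("#data_head\t", fp$head),
               "#columns\tread_id\toffset\tlength",
               sprintf("%s\t%.0f\t%.0f", ids, offs, lens)),
             con, sep = "\n")
  close(con)
  idx
}

#' Load a previously built side-car index
#'
#' Verifies the stored fingerprint against the current data file and refuses
#' stale indexes (e.g. after an append).
#'
#' @param path The BLOW5 data file (not the `.idx` side-car).
#' @return A `blow5_index`.
#' @export
load_index <- function(path) {
  ip <- index_path(path)
  if (!file.exists(ip))
    stop("no index side-car for ", path, "; run build_index() first")
  lines <- readLines(ip, warn = FALSE)
  meta <- strsplit(lines[startsWith(lines, "#")], "\t", fixed = TRUE)
  key <- vapply(meta, `[`, "", 1L)
  size <- as.numeric(meta[[which(key == "#data_size")]][2])
  head_hex <- meta[[which(key == "#data_head")]][2]
  fp <- file_fingerprint(path)
  if (!identical(fp$size, size) || !identical(fp$head, head_hex))
    stop("stale index for ", path, ": data file changed; rebuild with build_index()")
  rows <- strsplit(lines[!startsWith(lines, "#")], "\t", fixed = TRUE)
  structure(
    list(entries = data.frame(
      read_id = vapply(rows, `[`, "", 1L),
      offset = as.numeric(vapply(rows, `[`, "", 2L)),
      length = as.numeric(vapply(rows, `[`, "", 3L)),
      stringsAsFactors = FALSE),
      source_path = path),
    class = "blow5_index")
}

#' @export
print.blow5_index <- function(x, ...) {
  cat(sprintf("<blow5_index> %d record(s) for %s\n",
              nrow(x$entries), x$source_path))
  invisible(x)
}

#' Fetch a single read by identifier (random access)
#'
#' Seeks to the indexed byte offset, reads exactly the record's bytes, and
#' decodes them. The result is identical to what a full sequential scan
#' yields for the same `read_id`.
#'
#' @param path A BLOW5 file.
#' @param read_id Identifier to fetch.
#' @param index Optional [build_index()]/[load_index()] result; when `NULL`
#'   the side-car is loaded (or built if absent).
#' @return A [signal_read()].
#' @export
get_read <- function(path, read_id, index = NULL) {
  if (is.null(index))
    index <- if (file.exists(index_path(path))) load_index(path) else build_index(path)
  i <- match(read_id, index$entries$read_id)
  if (is.na(i)) stop("read_id not found in index: ", read_id)
  st <- blow5_open(path)
  on.exit(st_close(st))
  fetch_at(st, index$entries$offset[i], index$entries$length[i])
}

# shared by get_read and the random-access benchmark (persistent handle)
fetch_at <- function(st, offset, length) {
  st_seek(st, offset)
  rec <- st_next_payload(st)
  if (is.null(rec) || rec$length != length)
    stop("record at offset ", offset, " does not match index entry")
  decode_payload(rec$payload, st$header)
}
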