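# Multi-read FAST5 (HDF5) interop: reading the legacy container and
# converting it to BLOW5. Only the multi-read layout is supported (one
# "read_<id>" group per read holding Raw/Signal plus calibration attributes
# on channel_id). FAST5 is read/converted only, never produced as an
# analysis output; the writer below exists so the synthetic generator can
# build fixtures.

FAST5_CAL_ATTRS <- c("digitisation", "offset", "range", "sampling_rate")

#' Write reads to a multi-read FAST5 container
#'
#' Fixture writer for the synthetic-data module: emits the multi-read HDF5
#' layout (`/read_<id>/Raw/Signal` with `read_id` on `Raw` and the
#' calibration quartet on `channel_id`), uncompressed.
#'
#' @param reads List of [signal_read()].
#' @param path Output `.fast5` path (overwritten).
#' @param omit_calibration_for Read ids whose calibration attributes are
#'   deliberately left out — used to exercise per-read error handling on
#'   degraded files.
#' @return Number of reads written, invisibly.
#' @export
write_fast5 <- function(reads, path, omit_calibration_for = character()) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE, after = FALSE)
  for (r in reads) {
    g <- paste0("read_", r$read_id)
    rhdf5::h5createGroup(fid, g)
    rhdf5::h5createGroup(fid, paste0(g, "/Raw"))
    rhdf5::h5createGroup(fid, paste0(g, "/channel_id"))
    rhdf5::h5write(r$raw_signal, fid, paste0(g, "/Raw/Signal"))
    raw_gid <- rhdf5::H5Gopen(fid, paste0(g, "/Raw"))
    rhdf5::h5writeAttribute(r$read_id, raw_gid, "read_id")
    rhdf5::H5Gclose(raw_gid)
    if (!r$read_id %in% omit_calibration_for) {
      ch_gid <- rhdf5::H5Gopen(fid, paste0(g, "/channel_id"))
      rhdf5::h5writeAttribute(r$digitisation, ch_gid, "digitisation")
      rhdf5::h5writeAttribute(r$offset, ch_gid, "offset")
      rhdf5::h5writeAttribute(r$range, ch_gid, "range")
      rhdf5::h5writeAttribute(r$sampling_rate, ch_gid, "sampling_rate")
      rhdf5::H5Gclose(ch_gid)
    }
  }
  invisible(length(reads))
}

#' Read a multi-read FAST5 file
#'
#' Yields one [signal_read()] per `read_<id>` group with signal samples and
#' calibration scalars taken verbatim from the container. A read missing its
#' raw-signal dataset or a calibration attribute produces a per-read error
#' entry (naming the group); the remaining reads are still returned.
#'
#' @param path A multi-read FAST5 (HDF5) file.
#' @return A list with `reads` (list of [signal_read()]), `errors` (named
#'   character vector, one message per failed group), and `header` (a
#'   minimal one-group [run_header()]).
#' @export
read_fast5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  groups <- ls$name[ls$otype == "H5I_GROUP"]
  groups <- groups[startsWith(groups, "read_")]
  reads <- list()
  errors <- character()
  for (g in groups) {
    res <- tryCatch({
      sig <- as.integer(rhdf5::h5read(path, paste0(g, "/Raw/Signal")))
      cal <- rhdf5::h5readAttributes(path, paste0(g, "/channel_id"))
      missing <- setdiff(FAST5_CAL_ATTRS, names(cal))
      if (length(missing))
        stop("missing calibration attribute(s): ", paste(missing, collapse = ", "))
      raw_attrs <- rhdf5::h5readAttributes(path, paste0(g, "/Raw"))
      id <- if (!is.null(raw_attrs$read_id)) as.character(raw_attrs$read_id)
            else sub("^read_", "", g)
      signal_read(id, raw_signal = sig,
                  digitisation = as.numeric(cal$digitisation),
                  offset = as.numeric(cal$offset),
                  range = as.numeric(cal$range),
                  sampling_rate = as.numeric(cal$sampling_rate))
    }, error = function(e) e)
    if (inherits(res, "error"))
      errors[g] <- conditionMessage(res)
    else
      reads[[length(reads) + 1L]] <- res
  }
  list(reads = reads, errors = errors, header = run_header())
}

#' Convert multi-read FAST5 files to one BLOW5 file
#'
#' Every read of every input appears exactly once in the output with its
#' signal samples bit-identical; reads from the i-th input file are placed
#' in read group i-1 (a `source_file` header attribute records the origin).
#' Output is byte-deterministic, so re-running the conversion reproduces the
#' same file.
#'
#' @param in_paths Character vector of multi-read FAST5 files.
#' @param out_path Output BLOW5 path.
#' @param record_codec,signal_codec Codecs for the output (see
#'   [run_header()]).
#' @return Number of records written, invisibly.
#' @export
convert_fast5_to_blow5 <- function(in_paths, out_path,
                                   record_codec = "zlib",
                                   signal_codec = "delta_zigzag_varint") {
  stopifnot(length(in_paths) >= 1L)
  all_reads <- list()
  attrs <- vector("list", length(in_paths))
  for (i in seq_along(in_paths)) {
    f5 <- read_fast5(in_paths[i])
    if (length(f5$errors))
      stop("cannot convert ", in_paths[i], ": ",
           paste(names(f5$errors), f5$errors, sep = ": ", collapse = "; "))
    for (r in f5$reads) {
      r$read_group <- i - 1L
      all_reads[[length(all_reads) + 1L]] <- r
    }
    attrs[[i]] <- c(source_file = basename(in_paths[i]))
  }
  ids <- vapply(all_reads, function(r) r$read_id, "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("read_id collision across inputs: ", paste(dup, collapse = ", "))
  header <- run_header(num_read_groups = length(in_paths), attributes = attrs,
                       record_codec = record_codec, signal_codec = signal_codec)
  write_slow5(out_path, header, all_reads, binary = TRUE)
}
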