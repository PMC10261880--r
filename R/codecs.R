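# Record and signal codecs. Record codecs act on the whole serialized record
# payload; the signal codec acts on the 16-bit sample vector before it is
# embedded in the payload.

#' Compress or decompress a record payload
#'
#' `codec = "none"` is the identity, `"zlib"` uses deflate (via
#' [memCompress()]), `"zstd"` uses the zstd library. `decompress_record()`
#' inverts `compress_record()` exactly for every codec.
#'
#' @param bytes Raw vector.
#' @param codec One of `"none"`, `"zlib"`, `"zstd"`.
#' @return Raw vector.
#' @export
compress_record <- function(bytes, codec) {
  stopifnot(is.raw(bytes))
  switch(codec,
         none = bytes,
         zlib = memCompress(bytes, type = "gzip"),
         zstd = zstd_compress_raw(bytes, 3L),
         stop("unknown record codec: ", codec))
}

#' @rdname compress_record
#' @export
decompress_record <- function(bytes, codec) {
  stopifnot(is.raw(bytes))
  switch(codec,
         none = bytes,
         zlib = memDecompress(bytes, type = "gzip"),
         zstd = zstd_decompress_raw(bytes),
         stop("unknown record codec: ", codec))
}

#' Encode or decode a signal-sample vector
#'
#' With `codec = "delta_zigzag_varint"` the first sample is stored as a
#' zigzag-encoded varint and every subsequent sample as the zigzag varint of
#' its delta from the predecessor (zigzag maps 0, -1, 1, -2 to 0, 1, 2, 3).
#' With `codec = "none"` samples are stored as little-endian 16-bit signed
#' integers. Decoding requires the sample count, which the record stores
#' separately, and inverts encoding exactly.
#'
#' @param samples Integer vector of 16-bit signed samples.
#' @param codec One of `"none"`, `"delta_zigzag_varint"`.
#' @param bytes Raw vector produced by `encode_signal()`.
#' @param n_samples Number of samples to decode.
#' @return `encode_signal()` a raw vector; `decode_signal()` an integer
#'   vector.
#' @export
encode_signal <- function(samples, codec) {
  samples <- as.integer(samples)
  switch(codec,
         none = {
           if (length(samples) &&
               (min(samples) < INT16_MIN || max(samples) > INT16_MAX))
             stop("signal sample outside 16-bit signed range")
           writeBin(samples, raw(), size = 2L, endian = "little")
         },
         delta_zigzag_varint = sig_encode_dzv(samples),
         stop("unknown signal codec: ", codec))
}

#' @rdname encode_signal
#' @export
decode_signal <- function(bytes, codec, n_samples) {
  stopifnot(is.raw(bytes))
  n_samples <- as.integer(n_samples)
  switch(codec,
         none = {
           if (length(bytes) != 2L * n_samples)
             stop("truncated signal stream: expected ", 2L * n_samples,
                  " bytes, got ", length(bytes))
           readBin(bytes, "integer", n = n_samples, size = 2L,
                   signed = TRUE, endian = "little")
         },
         delta_zigzag_varint = sig_decode_dzv(bytes, n_samples),
         stop("unknown signal codec: ", codec))
}
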