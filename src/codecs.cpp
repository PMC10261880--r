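#include <Rcpp.h>
#include <zstd.h>
#include <cctype>
#include <cstring>

using namespace Rcpp;

// Zigzag interleaves signed integers onto unsigned so small-magnitude deltas
// (the common case for nanopore signal) take one varint byte:
// 0 -> 0, -1 -> 1, 1 -> 2, -2 -> 3, ...
static inline uint32_t zigzag32(int32_t v) {
  return (static_cast<uint32_t>(v) << 1) ^ static_cast<uint32_t>(v >> 31);
}

static inline int32_t unzigzag32(uint32_t v) {
  return static_cast<int32_t>(v >> 1) ^ -static_cast<int32_t>(v & 1);
}

// [[Rcpp::export]]
RawVector sig_encode_dzv(IntegerVector samples) {
  std::vector<uint8_t> out;
  out.reserve(static_cast<size_t>(samples.size()) * 2 + 8);
  int32_t prev = 0;
  for (R_xlen_t i = 0; i < samples.size(); ++i) {
    int32_t v = samples[i];
    if (v == NA_INTEGER || v < -32768 || v > 32767)
      stop("signal sample %d is not a 16-bit signed integer", (int)(i + 1));
    int32_t d = (i == 0) ? v : v - prev;
    prev = v;
    uint32_t z = zigzag32(d);
    while (z >= 0x80u) {
      out.push_back(static_cast<uint8_t>(z | 0x80u));
      z >>= 7;
    }
    out.push_back(static_cast<uint8_t>(z));
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector sig_decode_dzv(RawVector bytes, int n_samples) {
  if (n_samples < 0) stop("negative sample count");
  IntegerVector out(n_samples);
  size_t pos = 0, len = bytes.size();
  int32_t prev = 0;
  for (int i = 0; i < n_samples; ++i) {
    uint32_t z = 0;
    int shift = 0;
    for (;;) {
      if (pos >= len)
        stop("truncated signal stream: ended inside sample %d of %d", i + 1, n_samples);
      uint8_t b = bytes[pos++];
      z |= static_cast<uint32_t>(b & 0x7Fu) << shift;
      if (!(b & 0x80u)) break;
      shift += 7;
      if (shift > 28) stop("malformed varint in signal stream at sample %d", i + 1);
    }
    int32_t d = unzigzag32(z);
    int32_t v = (i == 0) ? d : prev + d;
    if (v < -32768 || v > 32767)
      stop("decoded sample %d outside 16-bit range", i + 1);
    out[i] = v;
    prev = v;
  }
  if (pos != len)
    stop("trailing bytes in signal stream: %d byte(s) after last sample", (int)(len - pos));
  return out;
}

// Decode one serialized record payload (already record-decompressed) into
// the fields of a signal_read. Invariants are re-checked here: bounds on
// every slice, 16-bit signal range, calibration positivity, read_id shape,
// read-group range, and no trailing bytes.
// aux_types: 1 = int, 2 = double, 3 = string (schema order).
// [[Rcpp::export]]
List unpack_record_cpp(RawVector payload, int signal_codec,
                       IntegerVector aux_types, CharacterVector aux_names,
                       int num_read_groups) {
  const uint8_t* p = payload.size() ? RAW(payload) : nullptr;
  size_t len = payload.size(), pos = 0;
  auto need = [&](size_t n) {
    if (pos + n > len) stop("truncated record body");
  };
  auto u16 = [&]() { need(2); uint32_t v = p[pos] | (p[pos + 1] << 8); pos += 2; return v; };
  auto u32 = [&]() {
    need(4);
    uint32_t v = (uint32_t)p[pos] | ((uint32_t)p[pos + 1] << 8) |
                 ((uint32_t)p[pos + 2] << 16) | ((uint32_t)p[pos + 3] << 24);
    pos += 4; return v;
  };
  auto f64 = [&]() { need(8); double v; memcpy(&v, p + pos, 8); pos += 8; return v; };
  auto str16 = [&]() {
    uint32_t n = u16(); need(n);
    std::string s(reinterpret_cast<const char*>(p + pos), n);
    pos += n; return s;
  };

  std::string read_id = str16();
  if (read_id.empty()) stop("deserialized read_id is empty");
  for (char c : read_id)
    if (isspace(static_cast<unsigned char>(c)))
      stop("deserialized read_id contains whitespace");
  int read_group = (int)u32();
  if (read_group < 0 || read_group >= num_read_groups)
    stop("deserialized read_group out of range");
  double dig = f64(), off = f64(), range = f64(), rate = f64();
  if (!(dig > 0) || !(range > 0) || !(rate > 0))
    stop("deserialized calibration scalars must be positive");
  int n_samples = (int)u32();
  uint32_t enc_len = u32();
  need(enc_len);

  IntegerVector sig(n_samples);
  if (signal_codec == 0) {
    if (enc_len != (uint32_t)(2 * n_samples))
      stop("truncated signal stream in record");
    for (int i = 0; i < n_samples; ++i) {
      int16_t v;
      memcpy(&v, p + pos + 2 * i, 2);
      sig[i] = v;
    }
  } else {
    size_t sp = pos, send = pos + enc_len;
    int32_t prev = 0;
    for (int i = 0; i < n_samples; ++i) {
      uint32_t z = 0;
      int shift = 0;
      for (;;) {
        if (sp >= send) stop("truncated signal stream in record");
        uint8_t b = p[sp++];
        z |= (uint32_t)(b & 0x7Fu) << shift;
        if (!(b & 0x80u)) break;
        shift += 7;
        if (shift > 28) stop("malformed varint in record signal");
      }
      int32_t d = unzigzag32(z);
      int32_t v = (i == 0) ? d : prev + d;
      if (v < -32768 || v > 32767) stop("decoded sample outside 16-bit range");
      sig[i] = v;
      prev = v;
    }
    if (sp != send) stop("trailing bytes in record signal stream");
  }
  pos += enc_len;

  List aux(aux_types.size());
  for (R_xlen_t i = 0; i < aux_types.size(); ++i) {
    switch (aux_types[i]) {
    case 1: aux[i] = (int)u32(); break;
    case 2: aux[i] = f64(); break;
    case 3: aux[i] = str16(); break;
    default: stop("unknown aux type id");
    }
  }
  if (aux.size() > 0) aux.attr("names") = aux_names;
  if (pos != len) stop("trailing bytes after record body");

  return List::create(_["read_id"] = read_id, _["read_group"] = read_group,
                      _["digitisation"] = dig, _["offset"] = off,
                      _["range"] = range, _["sampling_rate"] = rate,
                      _["raw_signal"] = sig, _["aux"] = aux);
}

// [[Rcpp::export]]
RawVector zstd_compress_raw(RawVector x, int level = 3) {
  size_t bound = ZSTD_compressBound(x.size());
  std::vector<uint8_t> buf(bound);
  size_t n = ZSTD_compress(buf.data(), bound,
                           x.size() ? RAW(x) : nullptr, x.size(), level);
  if (ZSTD_isError(n)) stop("zstd compression failed: %s", ZSTD_getErrorName(n));
  return RawVector(buf.begin(), buf.begin() + n);
}

// [[Rcpp::export]]
RawVector zstd_decompress_raw(RawVector x) {
  unsigned long long sz = ZSTD_getFrameContentSize(x.size() ? RAW(x) : nullptr, x.size());
  if (sz == ZSTD_CONTENTSIZE_ERROR) stop("not a zstd frame");
  if (sz == ZSTD_CONTENTSIZE_UNKNOWN) stop("zstd frame does not declare its content size");
  std::vector<uint8_t> buf(static_cast<size_t>(sz));
  size_t n = ZSTD_decompress(buf.data(), buf.size(),
                             x.size() ? RAW(x) : nullptr, x.size());
  if (ZSTD_isError(n)) stop("zstd decompression failed: %s", ZSTD_getErrorName(n));
  if (n != sz) stop("zstd decompression produced unexpected size");
  return RawVector(buf.begin(), buf.begin() + n);
}
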