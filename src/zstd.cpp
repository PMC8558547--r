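#include <Rcpp.h>
#include <zstd.h>

using namespace Rcpp;

// Single-frame zstd helpers. Frame splitting and the seekable seek-table
// framing live in R (R/seekable.R); C++ is only the codec boundary.

// [[Rcpp::export(name = ".zstd_compress_frame")]]
RawVector zstd_compress_frame(RawVector x, int level) {
  size_t bound = ZSTD_compressBound(x.size());
  std::vector<unsigned char> buf(bound);
  size_t n = ZSTD_compress(buf.data(), bound, RAW(x), x.size(), level);
  if (ZSTD_isError(n)) {
    stop("zstd compression failed: %s", ZSTD_getErrorName(n));
  }
  RawVector out(n);
  memcpy(RAW(out), buf.data(), n);
  return out;
}

// expected_size is the uncompressed frame size recorded in the seek table;
// a mismatch or a malformed frame is a hard error (integrity surface).
// [[Rcpp::export(name = ".zstd_decompress_frame")]]
RawVector zstd_decompress_frame(RawVector x, double expected_size) {
  if (expected_size < 0) stop("negative frame size");
  size_t want = (size_t) expected_size;
  RawVector out(want);
  size_t n = ZSTD_decompress(RAW(out), want, RAW(x), x.size());
  if (ZSTD_isError(n)) {
    stop("zstd frame is corrupt: %s", ZSTD_getErrorName(n));
  }
  if (n != want) {
    stop("zstd frame decompressed to %d bytes, seek table promised %d",
         (int) n, (int) want);
  }
  return out;
}

// [[Rcpp::export(name = ".zstd_version")]]
int zstd_version() {
  return (int) ZSTD_versionNumber();
}
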