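#include <Rcpp.h>
#include <zlib.h>

// CRC-32 (ISO 3309) over a raw vector, as required by PNG chunk trailers.
// Returned as double because R has no unsigned 32-bit integer type.
// [[Rcpp::export]]
double crc32_raw(Rcpp::RawVector x) {
  uLong crc = crc32(0L, Z_NULL, 0);
  if (x.size() > 0)
    crc = crc32(crc, reinterpret_cast<const Bytef*>(&x[0]),
                static_cast<uInt>(x.size()));
  return static_cast<double>(crc);
}
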