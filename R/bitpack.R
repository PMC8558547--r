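# Bit packing of symbol codes, most-significant-bits-first within each byte.
# 5-bit codes cross byte boundaries as a contiguous bit stream, TwoBit style.
# Everything is vectorized: packBits()/rawToBits() work LSB-first per byte,
# so rows of an 8 x nbytes bit matrix are reversed to get MSB-first order.

pack_codes <- function(codes, bits) {
  n <- length(codes)
  if (n == 0L) return(raw(0))
  bm <- matrix(FALSE, nrow = bits, ncol = n)
  for (j in seq_len(bits)) {
    bm[j, ] <- bitwAnd(bitwShiftR(codes, bits - j), 1L) == 1L
  }
  stream <- as.vector(bm)
  nbytes <- ceiling(length(stream) / 8)
  pad <- nbytes * 8L - length(stream)
  if (pad > 0L) stream <- c(stream, rep(FALSE, pad))
  sm <- matrix(stream, nrow = 8L)
  packBits(as.vector(sm[8:1, , drop = FALSE]), type = "raw")
}

# bytes: a contiguous slice of a packed payload; bit_offset: number of bits
# at the start of `bytes` that precede the first wanted symbol (0..7).
unpack_codes <- function(bytes, bits, bit_offset, n) {
  if (n == 0L) return(integer(0))
  need_bits <- bit_offset + n * bits
  if (length(bytes) * 8L < need_bits) stop("payload slice shorter than requested symbols")
  b <- rawToBits(bytes)
  m <- matrix(as.integer(b), nrow = 8L)
  stream <- as.vector(m[8:1, , drop = FALSE])
  sel <- matrix(stream[bit_offset + seq_len(n * bits)], nrow = bits)
  as.integer(drop(2^((bits - 1):0) %*% sel))
}

# Payload byte range covering symbols [start, end) at `bits` bits per symbol,
# plus the bit offset of symbol `start` within that range. 0-based bytes.
payload_byte_span <- function(start, end, bits) {
  first <- floor(start * bits / 8)
  last <- ceiling(end * bits / 8)          # exclusive
  list(first = first, last = last, bit_offset = start * bits - first * 8)
}
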