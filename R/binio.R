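# Little-endian fixed-width integer serialization on top of R doubles.
# Offsets and lengths in the container are 64-bit unsigned; R doubles are
# exact up to 2^53, far beyond any FASTA this package will meet.

u64_to_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x >= 2^53)) stop("u64 out of the exactly representable range")
  out <- raw(8L * length(x))
  pos <- seq_along(x) * 8L - 7L
  for (i in 0:7) {
    out[pos + i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_u64 <- function(r) {
  if (length(r) %% 8L != 0L) stop("u64 field truncated")
  m <- matrix(as.integer(r), nrow = 8L)
  as.numeric(drop(2^(8 * (0:7)) %*% m))
}

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x >= 2^32)) stop("u32 overflow")
  out <- raw(4L * length(x))
  pos <- seq_along(x) * 4L - 3L
  for (i in 0:3) {
    out[pos + i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

raw_to_u32 <- function(r) {
  if (length(r) %% 4L != 0L) stop("u32 field truncated")
  m <- matrix(as.integer(r), nrow = 4L)
  as.numeric(drop(2^(8 * (0:3)) %*% m))
}

# Structured errors so callers (CLI, tests) can discriminate failure modes.
fastar_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fastar_error"), call = call))
}
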