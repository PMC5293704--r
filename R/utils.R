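# byte-level helpers shared by the FPS codec

# 256 x 8 lookup: row b+1 holds the bits of byte value b, LSB first
# (FPS convention: bit k lives in byte k %/% 8, mask bitwShiftL(1, k %% 8))
byte_bits_table <- local({
  tab <- matrix(0L, nrow = 256L, ncol = 8L)
  for (b in 0:255) tab[b + 1L, ] <- bitwAnd(bitwShiftR(b, 0:7), 1L)
  tab
})

# hex string (one fingerprint) -> integer byte values
hex_to_bytes <- function(hex) {
  chars <- strsplit(tolower(hex), "", fixed = TRUE)[[1L]]
  if (length(chars) %% 2L != 0L) return(NULL)
  vals <- match(chars, c(0:9, letters[1:6])) - 1L
  if (anyNA(vals)) return(NULL)
  idx <- seq(1L, length(vals), by = 2L)
  vals[idx] * 16L + vals[idx + 1L]
}

bytes_to_hex <- function(bytes) {
  paste(sprintf("%02x", bytes), collapse = "")
}

# one row of 0/1 bits -> byte values, LSB-first within each byte
bits_to_bytes <- function(bits) {
  n_bytes <- ceiling(length(bits) / 8L)
  padded <- c(bits, integer(n_bytes * 8L - length(bits)))
  dim(padded) <- c(8L, n_bytes)
  as.integer(colSums(padded * 2L^(0:7)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
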