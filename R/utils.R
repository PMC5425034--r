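# Small shared helpers.

# FNV-1a style checksum of a string, as 8 hex digits; used to stamp run
# artifacts with their configuration.
checksum_hex <- function(x) {
  bytes <- utf8ToInt(as.character(x))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}
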