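# Internal helpers shared across modules.
#
# Base encoding used throughout: integer codes 1=A, 2=C, 3=G, 4=T, 5=deletion
# marker, 0=position not covered. Feature tensors use the fixed row/channel
# order A, G, T, C.

BASES <- c("A", "C", "G", "T")
TENSOR_BASES <- c("A", "G", "T", "C")
# map base code (1..4, alphabetical) -> tensor row/channel index (A,G,T,C order)
CODE_TO_TENSOR <- c(1L, 4L, 2L, 3L)
DEL_CODE <- 5L

base_to_code <- function(x) {
  m <- match(x, BASES)
  m[is.na(m)] <- 0L
  m
}

code_to_base <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- code >= 1L & code <= 4L
  out[ok] <- BASES[code[ok]]
  out[code == DEL_CODE] <- "-"
  out
}

seq_to_codes <- function(seq) {
  base_to_code(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
}

codes_to_seq <- function(codes) {
  paste(BASES[codes], collapse = "")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# parse a CIGAR string into op/length vectors
parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stopf("malformed CIGAR: %s", cigar)
  list(op = ops, len = lens)
}
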