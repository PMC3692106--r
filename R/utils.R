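# Internal helpers: typed error conditions and TSS-relative coordinate
# arithmetic shared across modules.

pd_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "promdesign_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

validation_error <- function(msg, ...) pd_stop(msg, "validation_error", ...)
parse_error      <- function(msg, ...) pd_stop(msg, "parse_error", ...)
conflict_error   <- function(msg, ...) pd_stop(msg, "conflict_error", ...)
io_error         <- function(msg, ...) pd_stop(msg, "io_error", ...)

DNA_ALPHABET <- c("A", "C", "G", "T")

is_dna <- function(x) {
  nchar(x) >= 1L && all(strsplit(x, "")[[1]] %in% DNA_ALPHABET)
}

# Coordinate convention: the canvas covers positions -L..-1, position -1 being
# the base immediately upstream of the TSS; position 0 does not exist. A motif
# of length k whose most-upstream base sits at s occupies s..s+k-1 and has
# center s + (k-1)/2 -- an integer for odd k, a half-integer for even k.

motif_start <- function(center, k) center - (k - 1) / 2
motif_end   <- function(center, k) center + (k - 1) / 2

center_has_legal_parity <- function(center, k) {
  s <- motif_start(center, k)
  isTRUE(all.equal(s, round(s)))
}

# map a TSS-relative position to a 1-based index on a canvas of length L
pos_to_index <- function(pos, L) as.integer(pos + L + 1)
index_to_pos <- function(idx, L) as.integer(idx - L - 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
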