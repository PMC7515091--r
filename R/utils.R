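# Internal helpers shared across modules.

# Comma-joined key per row of an integer state matrix.
.stateKeys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]), sep = ","))
}

.key1 <- function(v) paste(v, collapse = ",")

# Row permutation sorting an integer matrix lexicographically by columns.
.lexOrder <- function(m) {
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Unique rows of an integer matrix, lexicographically sorted.
.uniqueSortedRows <- function(m) {
  keys <- .stateKeys(m)
  m <- m[!duplicated(keys), , drop = FALSE]
  m[.lexOrder(m), , drop = FALSE]
}
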