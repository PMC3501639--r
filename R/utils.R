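# Internal helpers shared across modules.

# Deterministic per-replicate substream seed; kept below 2^31-1.
substream_seed <- function(seed, r) {
  s <- (as.numeric(seed) %% 65011) * 33013 + as.numeric(r) * 48271
  as.integer(s %% 2147483587 + 1)
}

# Evaluate expr with a temporarily seeded RNG; NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# character matrix (A/C/G/T/-/N) -> integer matrix 1..4 with NA for gaps/N
seq_char_to_int <- function(m) {
  out <- matrix(match(m, DNA_BASES), nrow = nrow(m), dimnames = dimnames(m))
  out
}

seq_int_to_char <- function(m) {
  out <- matrix(DNA_BASES[m], nrow = nrow(m), dimnames = dimnames(m))
  out[is.na(out)] <- "N"
  out
}

# Collapse rows of a matrix to strings (haplotype keys).
row_keys <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
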