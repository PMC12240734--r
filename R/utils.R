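RNA_BASES <- c("A", "C", "G", "U")

# Integer base codes 0..3 (A,C,G,U); N (or anything else) -> NA.
kmer_codes <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(chars, RNA_BASES) - 1L
}

# 1-based lexicographic k-mer index for every window of a code vector;
# windows containing NA stay NA. length(code) must be >= k.
kmer_indices <- function(code, k) {
  m <- embed(code, k)  # row i = code[i+k-1], ..., code[i]
  as.integer(m %*% 4^(seq_len(k) - 1)) + 1L
}

# All k-mers over {A,C,G,U} in lexicographic order.
kmer_names <- function(k) {
  nm <- ""
  for (i in seq_len(k)) nm <- paste0(rep(nm, each = 4L), RNA_BASES)
  nm
}

# Deterministic 31-bit seed mixing (splitmix-flavoured, in double arithmetic)
# so independent substreams can be keyed on (seed, index, ...).
mix_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (v in c(...)) {
    x <- (x * 48271 + as.numeric(v) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}
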