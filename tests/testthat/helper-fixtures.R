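# Shared helpers: independent brute-force references and tiny fixtures.
# These never call into the suffix tree, so they can serve as oracles for it.

# Overlapping occurrences of word w in sequence s by direct position scan.
brute_count <- function(s, w) {
  m <- nchar(s); L <- nchar(w)
  if (m < L) return(0L)
  starts <- seq_len(m - L + 1)
  sum(substring(s, starts, starts + L - 1) == w)
}

# All suffixes of a sequence (position, string), for leaf-annotation checks.
brute_suffixes <- function(s) {
  m <- nchar(s)
  data.frame(pos = seq_len(m), suffix = substring(s, seq_len(m), m),
             stringsAsFactors = FALSE)
}

# Write a sequence set (or raw lines) to a temporary FASTA file.
tmp_fasta <- function(x) {
  path <- tempfile(fileext = ".fasta")
  if (is.character(x) && is.null(names(x))) writeLines(x, path)
  else write_fasta(x, path)
  path
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
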