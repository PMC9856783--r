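# Shared test helpers: tiny builders for tables and planted families.

# FrequencyTable straight from counts (bypasses trimming).
mk_table <- function(label, seqs, counts) {
  counts <- as.integer(counts)
  tot <- sum(counts)
  new("FrequencyTable",
    cycleLabel = label, sequences = seqs, counts = counts,
    frequencies = counts / tot, totalReads = tot,
    rejections = c(missing_flank = 0L, length_out_of_bounds = 0L,
                   ambiguous_base = 0L)
  )
}

# random ACGT strings; len may be a vector recycled over n
rand_seqs <- function(n, len = 30) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# apply exactly k substitutions to a sequence (edit distance <= k)
substitute_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# seeds for planted families: random 30-mers, mutually > minDist apart
planted_seeds <- function(n, minDist = 12, len = 30) {
  seeds <- character(0)
  while (length(seeds) < n) {
    cand <- rand_seqs(1, len)
    if (!length(seeds) ||
        all(levenshtein(cand, seeds, cutoff = minDist) > minDist)) {
      seeds <- c(seeds, cand)
    }
  }
  seeds
}
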