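# Shared fixtures built in code: tiny genomes, catalogs and an independent
# brute-force context oracle.

toy_genome <- function(seqs) reference_genome(seqs)

toy_catalog <- function(chrom, pos, ref, alt, sample_id = "s1") {
  suppressMessages(mutation_catalog(data.frame(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    stringsAsFactors = FALSE)))
}

# Random ACGT genome string (independent of the package generator).
random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent reverse complement (no package code).
rc_str <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

# Brute-force context abundance oracle: enumerate all full windows on BOTH
# strands, state each window pyrimidine-centered (reverse-complementing
# purine-centered ones), tally, divide by 2.
brute_abundance <- function(seq, k) {
  w <- 2 * k + 1
  out <- list()
  for (strand_seq in c(seq, rc_str(seq))) {
    L <- nchar(strand_seq)
    if (L < w) next
    for (i in 1:(L - w + 1)) {
      win <- substr(strand_seq, i, i + w - 1)
      if (grepl("N", win, fixed = TRUE)) next
      if (!substr(win, k + 1, k + 1) %in% c("C", "T")) win <- rc_str(win)
      out[[length(out) + 1]] <- win
    }
  }
  tab <- table(unlist(out)) / 2
  tab
}
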