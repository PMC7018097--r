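#' Read a reference genome from FASTA
#'
#' Loads a (multi-record) FASTA file into a `ReferenceGenome`: an in-memory
#' map from chromosome name to an uppercase DNA string over `{A,C,G,T,N}`.
#' Sequence names are taken as the first whitespace-delimited token of each
#' header.
#'
#' @param path path to a FASTA file.
#' @return a `ReferenceGenome` object (list with elements `sequences`, a named
#'   character vector, and `lengths`, a named integer vector).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_fasta(fa)
#' g$lengths
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stopf("malformed FASTA '%s': %s", path,
                                           conditionMessage(e)))
  if (length(ss) == 0L) stopf("empty FASTA file: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stopf("duplicate sequence names in %s", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  reference_genome(seqs)
}

#' Construct a ReferenceGenome from named DNA strings
#'
#' @param sequences named character vector of DNA strings (uppercased on
#'   input; only `A`, `C`, `G`, `T`, `N` allowed).
#' @return a `ReferenceGenome`.
#' @export
reference_genome <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stopf("sequences must be named by chromosome")
  if (anyDuplicated(names(sequences)))
    stopf("chromosome names must be unique")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stopf("non-ACGTN characters in sequence(s): %s",
          paste(names(sequences)[bad], collapse = ", "))
  structure(
    list(sequences = sequences,
         lengths = setNames(nchar(sequences), names(sequences))),
    class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat(sprintf("ReferenceGenome: %d sequence(s), %s bp total\n",
              length(x$sequences), format(sum(x$lengths), big.mark = ",")))
  for (nm in utils::head(names(x$lengths), 10))
    cat(sprintf("  %s  %s bp\n", nm, format(x$lengths[[nm]], big.mark = ",")))
  if (length(x$lengths) > 10) cat("  ...\n")
  invisible(x)
}

genome_seq <- function(genome, chrom) {
  s <- genome$sequences[[chrom]]
  if (is.null(s)) stopf("chromosome '%s' not in genome", chrom)
  s
}

#' Extract the sequence context around a position
#'
#' Returns the plus-strand sequence of length `2k + 1` centered at `pos`
#' (1-based). Positions whose window would run off the chromosome are an
#' error.
#'
#' @param genome a `ReferenceGenome`.
#' @param chrom chromosome name.
#' @param pos 1-based position (scalar or vector; with vector input `chrom`
#'   is recycled).
#' @param k flank width in bp (1 for trinucleotide, 2 for pentanucleotide).
#' @return character vector of contexts; contexts containing `N` are returned
#'   as-is and should be excluded downstream.
#' @export
extract_context <- function(genome, chrom, pos, k = 1L) {
  stopifnot(k >= 1L)
  if (length(chrom) == 1L && length(pos) > 1L) chrom <- rep(chrom, length(pos))
  out <- character(length(pos))
  for (cm in unique(chrom)) {
    idx <- which(chrom == cm)
    s <- genome_seq(genome, cm)
    L <- nchar(s)
    p <- pos[idx]
    if (any(p < 1L + k | p > L - k))
      stopf("position(s) on %s within %d bp of a chromosome end (or out of range)",
            cm, k)
    out[idx] <- substring(s, p - k, p + k)
  }
  out
}

## ---- mutation channels -----------------------------------------------------

#' The full pyrimidine-collapsed channel space
#'
#' Channels are written `X..[R>A]..Y` with the mutated pyrimidine `R` in
#' brackets inside its `2k + 1` context. Ordering is lexicographic by
#' (substitution type, context), substitution types in the order
#' C>A, C>G, C>T, T>A, T>C, T>G — fixed so output files are bit-stable.
#'
#' @param k flank width (1 gives 96 channels, 2 gives 1536).
#' @return character vector of channel names.
#' @export
channel_space <- function(k = 1L) {
  stopifnot(k %in% c(1L, 2L))
  flanks <- do.call(paste0, rev(expand.grid(rep(list(BASES), k),
                                            stringsAsFactors = FALSE)))
  flanks <- sort(flanks)
  out <- character(0)
  for (sub in SUBSTITUTIONS) {
    ref <- substr(sub, 1, 1)
    grid <- expand.grid(right = flanks, left = flanks,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$left, grid$right), ]
    out <- c(out, paste0(grid$left, "[", sub, "]", grid$right))
  }
  out
}

#' Collapse a substitution onto its pyrimidine-centered channel
#'
#' A substitution whose reference base is a purine is reverse-complemented
#' (ref and alt complemented, context reverse-complemented) so every channel
#' is stated with a C or T as the mutated base — the standard convention that
#' merges reverse-complement-equivalent mutation types.
#'
#' @param ref reference base(s).
#' @param alt alternate base(s).
#' @param context plus-strand context string(s), odd length, centered on `ref`.
#' @return channel name(s) like `"A[C>T]G"`; `NA` for contexts containing `N`.
#' @export
collapse_channel <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  if (n == 0L) return(character(0))
  w <- unique(nchar(context))
  if (length(w) != 1L || w %% 2L != 1L)
    stopf("contexts must share one odd length")
  k <- (w - 1L) %/% 2L
  center <- substr(context, k + 1L, k + 1L)
  if (any(center != ref & !grepl("N", context, fixed = TRUE)))
    stopf("context center does not match ref")
  if (any(ref == alt)) stopf("ref == alt is not a substitution")
  pur <- ref %in% c("A", "G")
  ref2 <- ref; alt2 <- alt; ctx2 <- context
  if (any(pur)) {
    ref2[pur] <- comp_base(ref[pur])
    alt2[pur] <- comp_base(alt[pur])
    ctx2[pur] <- revcomp_fixed(context[pur], w)
  }
  out <- paste0(substr(ctx2, 1L, k), "[", ref2, ">", alt2, "]",
                substr(ctx2, k + 2L, w))
  out[grepl("N", context, fixed = TRUE)] <- NA_character_
  out
}

#' Context (without substitution) of a channel name
#' @param channel channel name(s) like `"A[C>T]G"`.
#' @return plain context string(s) like `"ACG"`.
#' @export
channel_context <- function(channel) {
  sub("\\[([CT])>[ACGT]\\]", "\\1", channel)
}

#' Substitution type of a channel name
#' @param channel channel name(s).
#' @return strings like `"C>T"`.
#' @export
channel_type <- function(channel) {
  sub("^.*\\[([CT]>[ACGT])\\].*$", "\\1", channel)
}

## ---- context abundance -----------------------------------------------------

# All pyrimidine-centered contexts of width 2k+1, sorted.
pyrimidine_contexts <- function(k = 1L) {
  w <- 2L * k + 1L
  grid <- expand.grid(rep(list(BASES), w), stringsAsFactors = FALSE)
  ctx <- do.call(paste0, grid)
  ctx <- ctx[substr(ctx, k + 1L, k + 1L) %in% PYRIMIDINES]
  sort(ctx)
}

# Collapse a full 4^(2k+1) k-mer count vector onto pyrimidine-centered
# contexts (purine-centered counts folded onto their reverse complements).
collapse_kmer_counts <- function(counts, k) {
  nm <- names(counts)
  center <- substr(nm, k + 1L, k + 1L)
  pyr <- center %in% PYRIMIDINES
  out <- counts[pyr]
  rc <- revcomp_fixed(nm[!pyr], 2L * k + 1L)
  add <- tapply(counts[!pyr], rc, sum)
  out[names(add)] <- out[names(add)] + add
  full <- setNames(numeric(length(pyrimidine_contexts(k))),
                   pyrimidine_contexts(k))
  full[names(out)] <- out
  full
}

#' Count pyrimidine-collapsed context abundance
#'
#' Counts, over a genome (or a restricted region set), how many positions
#' carry each `2k + 1`-bp context, with plus/minus strands collapsed onto
#' pyrimidine-centered strings. Each genomic position with a full non-N
#' window is counted exactly once; overlapping regions are merged before
#' counting. This is the abundance term `A` of the expected-mutation model
#' and the denominator of genome-frequency normalization.
#'
#' @param genome a `ReferenceGenome`.
#' @param regions optional data.frame with `chrom`, `start`, `end` (0-based
#'   half-open, BED convention); `NULL` means the whole genome.
#' @param k flank width (1 or 2).
#' @param region_label label stored on the result.
#' @return a `ContextAbundance`: list with `k`, `counts` (named numeric over
#'   the complete pyrimidine context space) and `region_label`.
#' @export
count_context_abundance <- function(genome, regions = NULL, k = 1L,
                                    region_label = if (is.null(regions)) "genome" else "regions") {
  stopifnot(k %in% c(1L, 2L))
  w <- 2L * k + 1L
  total <- setNames(numeric(4L^w),
                    Biostrings::mkAllStrings(BASES, w))
  add_seq <- function(s) {
    if (nchar(s) < w) return(invisible(NULL))
    cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                width = w)
    total[names(cnt)] <<- total[names(cnt)] + cnt
    invisible(NULL)
  }
  if (is.null(regions)) {
    for (s in genome$sequences) add_seq(s)
  } else {
    regions <- merge_intervals(regions)
    for (i in seq_len(nrow(regions))) {
      cm <- regions$chrom[i]
      s <- genome_seq(genome, cm)
      L <- nchar(s)
      if (regions$start[i] < 0 || regions$end[i] > L)
        stopf("region %s:%d-%d outside genome", cm, regions$start[i],
              regions$end[i])
      # centers are positions start+1 .. end (1-based); windows extend k bp
      lo <- max(1L, regions$start[i] + 1L - k)
      hi <- min(L, regions$end[i] + k)
      add_seq(substr(s, lo, hi))
    }
  }
  structure(list(k = k,
                 counts = collapse_kmer_counts(total, k),
                 region_label = region_label),
            class = "ContextAbundance")
}

#' @export
print.ContextAbundance <- function(x, ...) {
  cat(sprintf("ContextAbundance (k=%d, %s): %d contexts, %s positions\n",
              x$k, x$region_label, length(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}
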