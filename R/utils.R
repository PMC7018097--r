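#' @importFrom stats setNames
NULL

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over character strings of equal or unequal
#' length; `N` is preserved.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast reverse complement for a vector of fixed-width strings (width w),
# avoiding XStringSet overhead in hot paths.
revcomp_fixed <- function(x, w) {
  if (length(x) == 0L) return(character(0))
  m <- matrix(unlist(strsplit(comp_base(x), "", fixed = TRUE), use.names = FALSE),
              nrow = w)
  do.call(paste0, lapply(seq_len(w), function(i) m[w - i + 1L, ]))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Merge 0-based half-open intervals per chromosome into a disjoint sorted set.
merge_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]
    rs <- numeric(0); re <- numeric(0)
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (s[i] <= keep_e) {
          keep_e <- max(keep_e, e[i])
        } else {
          rs <- c(rs, keep_s); re <- c(re, keep_e)
          keep_s <- s[i]; keep_e <- e[i]
        }
      }
    }
    rs <- c(rs, keep_s); re <- c(re, keep_e)
    data.frame(chrom = d$chrom[1], start = rs, end = re,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
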