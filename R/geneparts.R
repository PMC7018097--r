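GENE_PARTS <- c("5'UTR", "first exon", "first intron", "middle exon",
                "middle intron", "last intron", "last exon", "3'UTR")

#' Read gene models from a refFlat-like (genePred) TSV
#'
#' Expects tab-separated columns `gene`, `chrom`, `strand`, `txStart`,
#' `txEnd`, `cdsStart`, `cdsEnd`, `exonCount`, `exonStarts`, `exonEnds`
#' (coordinates 0-based half-open; exon lists comma-separated, UCSC style).
#'
#' @param path file path.
#' @return a `GeneModelSet`: list of gene records with 1-based inclusive
#'   exon intervals.
#' @export
read_genepred <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = TRUE, check.names = FALSE)
  need <- c("gene", "chrom", "strand", "txStart", "txEnd", "cdsStart",
            "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene model file missing column(s): %s",
                          paste(miss, collapse = ", "))
  genes <- lapply(seq_len(nrow(df)), function(i) {
    es <- as.integer(strsplit(sub(",$", "", df$exonStarts[i]), ",")[[1]])
    ee <- as.integer(strsplit(sub(",$", "", df$exonEnds[i]), ",")[[1]])
    gene_model(df$gene[i], df$chrom[i], df$strand[i],
               tx_start = df$txStart[i] + 1L, tx_end = df$txEnd[i],
               cds_start = df$cdsStart[i] + 1L, cds_end = df$cdsEnd[i],
               exon_starts = es + 1L, exon_ends = ee)
  })
  structure(genes, class = "GeneModelSet")
}

#' Construct a gene model (1-based inclusive coordinates)
#' @param gene,chrom,strand identifiers.
#' @param tx_start,tx_end,cds_start,cds_end transcript and CDS bounds.
#' @param exon_starts,exon_ends parallel vectors of exon bounds, sorted by
#'   genomic position.
#' @return a `GeneModel` list.
#' @export
gene_model <- function(gene, chrom, strand, tx_start, tx_end,
                       cds_start, cds_end, exon_starts, exon_ends) {
  stopifnot(length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends), strand %in% c("+", "-"))
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 tx_start = tx_start, tx_end = tx_end,
                 cds_start = cds_start, cds_end = cds_end,
                 exon_starts = exon_starts, exon_ends = exon_ends),
            class = "GeneModel")
}

# Intersect exon intervals with [lo, hi]; returns matrix with start/end rows.
clip_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

# Decompose one gene into the eight parts; each part is a list of
# (start, end) intervals in 5'->3' order.
gene_parts <- function(g) {
  es <- g$exon_starts; ee <- g$exon_ends
  n <- length(es)
  plus <- g$strand == "+"
  utr5 <- if (plus) clip_intervals(es, ee, g$tx_start, g$cds_start - 1L)
          else clip_intervals(es, ee, g$cds_end + 1L, g$tx_end)
  utr3 <- if (plus) clip_intervals(es, ee, g$cds_end + 1L, g$tx_end)
          else clip_intervals(es, ee, g$tx_start, g$cds_start - 1L)
  cds_ex <- clip_intervals(es, ee, g$cds_start, g$cds_end)
  if (!plus) {
    flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
    utr5 <- flip(utr5); utr3 <- flip(utr3); cds_ex <- flip(cds_ex)
  }
  nce <- nrow(cds_ex)
  first_ex <- if (nce >= 1) cds_ex[1, , drop = FALSE] else cds_ex[0, , drop = FALSE]
  last_ex <- if (nce >= 2) cds_ex[nce, , drop = FALSE] else cds_ex[0, , drop = FALSE]
  mid_ex <- if (nce >= 3) cds_ex[2:(nce - 1), , drop = FALSE] else cds_ex[0, , drop = FALSE]
  introns <- if (n >= 2) cbind(start = ee[-n] + 1L, end = es[-1] - 1L)
             else cbind(start = integer(0), end = integer(0))
  introns <- introns[introns[, "start"] <= introns[, "end"], , drop = FALSE]
  if (!plus) introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
  ni <- nrow(introns)
  first_in <- if (ni >= 1) introns[1, , drop = FALSE] else introns
  last_in <- if (ni >= 2) introns[ni, , drop = FALSE] else introns[0, , drop = FALSE]
  mid_in <- if (ni >= 3) introns[2:(ni - 1), , drop = FALSE] else introns[0, , drop = FALSE]
  setNames(list(utr5, first_ex, first_in, mid_ex, mid_in, last_in, last_ex, utr3),
           GENE_PARTS)
}

#' Mutation density across eight gene parts in 20 bins
#'
#' Decomposes each gene into 5'UTR, first/middle/last coding exons,
#' first/middle/last introns and 3'UTR, splits every qualifying contiguous
#' sequence of a part into 20 near-equal bins (bin widths within a sequence
#' differ by at most 1 bp; bin 1 is the 5' end), discards sequences shorter
#' than 20 bp, and pools mutations and base pairs per (part, bin) across all
#' genes. Genes with fewer than three exons contribute only to the parts
#' they define.
#'
#' @param catalog a `MutationCatalog`.
#' @param genes a `GeneModelSet` (or list of `GeneModel`).
#' @param n_bins number of bins per sequence (default 20).
#' @param min_length minimum sequence length retained (default 20 bp).
#' @return a `GenePartProfile`: data.frame with `part` (ordered factor),
#'   `bin`, `bp`, `mutations` and `rate` (mutations per Mb).
#' @export
gene_part_profile <- function(catalog, genes, n_bins = 20L, min_length = 20L) {
  bp <- matrix(0, nrow = length(GENE_PARTS), ncol = n_bins,
               dimnames = list(GENE_PARTS, NULL))
  muts <- bp
  mut_by_chrom <- split(catalog$pos, catalog$chrom)
  mut_by_chrom <- lapply(mut_by_chrom, sort)
  for (g in genes) {
    parts <- gene_parts(g)
    mp <- mut_by_chrom[[g$chrom]]
    for (pn in names(parts)) {
      iv <- parts[[pn]]
      if (nrow(iv) == 0L) next
      for (r in seq_len(nrow(iv))) {
        s <- iv[r, "start"]; e <- iv[r, "end"]
        L <- e - s + 1L
        if (L < min_length) next
        base <- L %/% n_bins; extra <- L %% n_bins
        widths <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
        ends <- s - 1L + cumsum(widths)
        starts <- c(s, utils::head(ends, -1L) + 1L)
        bin_ids <- seq_len(n_bins)
        if (g$strand == "-") bin_ids <- rev(bin_ids)
        bp[pn, bin_ids] <- bp[pn, bin_ids] + widths
        if (!is.null(mp) && length(mp)) {
          cnt <- findInterval(ends, mp) - findInterval(starts - 1L, mp)
          muts[pn, bin_ids] <- muts[pn, bin_ids] + cnt
        }
      }
    }
  }
  out <- data.frame(part = factor(rep(GENE_PARTS, each = n_bins),
                                  levels = GENE_PARTS),
                    bin = rep(seq_len(n_bins), times = length(GENE_PARTS)),
                    bp = as.vector(t(bp)),
                    mutations = as.vector(t(muts)))
  out$rate <- ifelse(out$bp > 0, 1e6 * out$mutations / out$bp, NA_real_)
  structure(out, class = c("GenePartProfile", "data.frame"))
}
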