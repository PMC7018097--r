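#' Construct an anchor set
#'
#' Anchors are single-base genomic points (CTCF motif centers, TSSs) around
#' which mutation profiles are stacked over a symmetric flank; minus-strand
#' anchors are flipped so offsets always run 5' to 3'.
#'
#' @param chrom,center,strand vectors describing the anchors (`center`
#'   1-based; `strand` `"+"` or `"-"`).
#' @param flank flank width in bp (window length `2 * flank + 1`).
#' @param kind free-text label, e.g. `"ctcf_motif"` or `"tss"`.
#' @return an `AnchorSet` (data.frame subclass with `flank`/`kind`
#'   attributes).
#' @export
anchor_set <- function(chrom, center, strand = "+", flank, kind = "anchor") {
  if (length(chrom) == 0L) stopf("anchor set is empty")
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  structure(data.frame(chrom = as.character(chrom),
                       center = as.integer(center),
                       strand = rep_len(strand, length(chrom)),
                       stringsAsFactors = FALSE),
            class = c("AnchorSet", "data.frame"),
            flank = as.integer(flank), kind = kind)
}

#' Read anchors from a BED6 file
#'
#' Uses the interval midpoint as the anchor center and honors the strand
#' column (missing strand defaults to `"+"`).
#'
#' @param path BED3/BED6 file.
#' @inheritParams anchor_set
#' @return an `AnchorSet`.
#' @export
read_anchors <- function(path, flank, kind = "anchor") {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("BED file needs at least 3 columns")
  center <- as.integer(floor((df[[2]] + df[[3]] + 1) / 2))  # midpoint, 1-based
  strand <- if (ncol(df) >= 6L) df[[6]] else "+"
  strand[!strand %in% c("+", "-")] <- "+"
  anchor_set(df[[1]], center, strand, flank = flank, kind = kind)
}

# Check all windows fit inside the genome.
check_anchor_bounds <- function(anchors, genome, pad = 0L) {
  flank <- attr(anchors, "flank")
  for (cm in unique(anchors$chrom)) {
    L <- genome$lengths[[cm]]
    if (is.null(L)) stopf("anchor chromosome '%s' not in genome", cm)
    p <- anchors$center[anchors$chrom == cm]
    if (any(p - flank - pad < 1L | p + flank + pad > L))
      stopf("anchor window(s) on %s extend outside the genome", cm)
  }
  invisible(TRUE)
}

# For each anchor window, the indices (into the catalog) and aligned offsets
# of the mutations it contains. Overlapping windows each count a shared
# mutation at their own offset (stacking semantics).
window_hits <- function(catalog, anchors) {
  flank <- attr(anchors, "flank")
  res_window <- integer(0); res_mut <- integer(0); res_off <- integer(0)
  for (cm in unique(anchors$chrom)) {
    aidx <- which(anchors$chrom == cm)
    midx <- which(catalog$chrom == cm)
    if (length(midx) == 0L) next
    ord <- midx[order(catalog$pos[midx])]
    mp <- catalog$pos[ord]
    lo <- findInterval(anchors$center[aidx] - flank - 1L, mp) + 1L
    hi <- findInterval(anchors$center[aidx] + flank, mp)
    for (j in seq_along(aidx)) {
      if (lo[j] > hi[j]) next
      sel <- lo[j]:hi[j]
      off <- mp[sel] - anchors$center[aidx[j]]
      if (anchors$strand[aidx[j]] == "-") off <- -off
      res_window <- c(res_window, rep.int(aidx[j], length(sel)))
      res_mut <- c(res_mut, ord[sel])
      res_off <- c(res_off, off)
    }
  }
  list(window = res_window, mut = res_mut, offset = res_off)
}

#' Stacked observed mutation profile around anchors
#'
#' Counts mutations at each aligned offset across all anchor windows.
#'
#' @param catalog a `MutationCatalog`.
#' @param anchors an `AnchorSet`.
#' @return a `PositionProfile`: data.frame with `offset`
#'   (`-flank..+flank`) and `observed`.
#' @export
stack_profile <- function(catalog, anchors) {
  if (!inherits(anchors, "AnchorSet") || nrow(anchors) == 0L)
    stopf("anchors must be a non-empty AnchorSet")
  flank <- attr(anchors, "flank")
  hits <- window_hits(catalog, anchors)
  obs <- tabulate(hits$offset + flank + 1L, nbins = 2L * flank + 1L)
  structure(data.frame(offset = seq(-flank, flank), observed = obs),
            class = c("PositionProfile", "data.frame"),
            flank = flank, kind = attr(anchors, "kind"),
            n_anchors = nrow(anchors))
}

# Matrix of pyrimidine-collapsed contexts at every offset of every window
# (rows = anchors, cols = offsets -flank..flank, minus-strand rows flipped);
# NA where the context contains N.
window_context_matrix <- function(genome, anchors, k = 1L) {
  flank <- attr(anchors, "flank")
  check_anchor_bounds(anchors, genome, pad = k)
  L <- 2L * flank + 1L
  ctx <- matrix(NA_character_, nrow = nrow(anchors), ncol = L)
  w <- 2L * k + 1L
  for (i in seq_len(nrow(anchors))) {
    s <- genome_seq(genome, anchors$chrom[i])
    win <- substr(s, anchors$center[i] - flank - k, anchors$center[i] + flank + k)
    v <- substring(win, seq_len(L), seq_len(L) + w - 1L)
    if (anchors$strand[i] == "-") v <- rev(v)
    ctx[i, ] <- v
  }
  ctx[grepl("N", ctx, fixed = TRUE)] <- NA_character_
  # collapse purine-centered contexts
  flat <- as.vector(ctx)
  ok <- !is.na(flat)
  center <- substr(flat[ok], k + 1L, k + 1L)
  pur <- center %in% c("A", "G")
  if (any(pur)) {
    u <- unique(flat[ok][pur])
    flat[ok][pur] <- setNames(revcomp_fixed(u, w), u)[flat[ok][pur]]
  }
  matrix(flat, nrow = nrow(anchors))
}

#' Context-expected mutation profile around anchors
#'
#' Implements the stacked expected-count model: over all anchor windows the
#' per-context mutation frequency is `f = M / A` (mutated-context count over
#' context abundance, both measured on the stacked windows). Within each
#' window the positions are weighted `Wp = f_p / sum_q f_q` and the window's
#' own mutation count `m` is redistributed as `m * Wp`; the stacked expected
#' profile is the sum over windows, so the expected total equals the
#' observed total by construction.
#'
#' @param catalog a `MutationCatalog`.
#' @param anchors an `AnchorSet`.
#' @param genome a `ReferenceGenome`.
#' @param k context flank width for `f = M/A` (default trinucleotide).
#' @return a `PositionProfile` with `offset`, `observed` and `expected`.
#' @export
expected_profile <- function(catalog, anchors, genome, k = 1L) {
  flank <- attr(anchors, "flank")
  ctxmat <- window_context_matrix(genome, anchors, k = k)
  hits <- window_hits(catalog, anchors)
  L <- 2L * flank + 1L
  obs <- tabulate(hits$offset + flank + 1L, nbins = L)
  # M and A over the stacked windows
  mut_ctx <- ctxmat[cbind(hits$window, hits$offset + flank + 1L)]
  M <- table(mut_ctx[!is.na(mut_ctx)])
  A <- table(as.vector(ctxmat))
  f <- setNames(numeric(length(A)), names(A))
  f[names(M)] <- as.numeric(M) / as.numeric(A[names(M)])
  m_per_window <- tabulate(hits$window, nbins = nrow(anchors))
  fmat <- matrix(0, nrow = nrow(anchors), ncol = L)
  known <- !is.na(ctxmat)
  fmat[known] <- f[ctxmat[known]]
  rs <- rowSums(fmat)
  expected <- numeric(L)
  use <- which(m_per_window > 0 & rs > 0)
  for (i in use)
    expected <- expected + m_per_window[i] * fmat[i, ] / rs[i]
  structure(data.frame(offset = seq(-flank, flank), observed = obs,
                       expected = expected),
            class = c("PositionProfile", "data.frame"),
            flank = flank, kind = attr(anchors, "kind"),
            n_anchors = nrow(anchors), k = k,
            f = f, total_mutations = sum(m_per_window))
}

#' @export
print.PositionProfile <- function(x, ...) {
  cat(sprintf("PositionProfile (%s): %d anchors, offsets %+d..%+d, %d observed mutations\n",
              attr(x, "kind"), attr(x, "n_anchors"), -attr(x, "flank"),
              attr(x, "flank"), sum(x$observed)))
  invisible(x)
}

#' Context-normalized mutation profile around TSSs
#'
#' For each focus channel (defaults: the POLE signature peaks C>A at TCT,
#' C>T at TCG, T>G at TTT), divides the per-offset count of mutations in
#' that channel by the per-offset count of the channel's context across the
#' stacked windows. Offsets with no context occurrence are reported as
#' missing, not zero. Raw channel counts aggregated in fixed-width bins are
#' emitted alongside.
#'
#' @param catalog a `MutationCatalog`.
#' @param anchors an `AnchorSet` of TSSs (strand honored).
#' @param genome a `ReferenceGenome`.
#' @param focus_channels channel names (see [channel_space()]).
#' @param bin_width width of the raw-count bins in bp (default 100).
#' @return list with `per_offset` (data.frame: channel, offset, mutations,
#'   context_sites, rate) and `binned` (data.frame: channel, bin_start,
#'   bin_end, mutations).
#' @export
tss_profile <- function(catalog, anchors, genome,
                        focus_channels = c("T[C>A]T", "T[C>T]G", "T[T>G]T"),
                        bin_width = 100L) {
  flank <- attr(anchors, "flank")
  k <- (nchar(channel_context(focus_channels[1])) - 1L) %/% 2L
  ctxmat <- window_context_matrix(genome, anchors, k = k)
  hits <- window_hits(catalog, anchors)
  L <- 2L * flank + 1L
  offsets <- seq(-flank, flank)
  # channel of every mutation hit
  mut_channel <- rep(NA_character_, length(hits$mut))
  if (length(hits$mut)) {
    ctx <- extract_context(genome, catalog$chrom[hits$mut],
                           catalog$pos[hits$mut], k = k)
    okc <- !grepl("N", ctx, fixed = TRUE)
    mut_channel[okc] <- collapse_channel(catalog$ref[hits$mut][okc],
                                         catalog$alt[hits$mut][okc], ctx[okc])
  }
  per_offset <- list(); binned <- list()
  brk <- seq(-flank, flank + 1L, by = bin_width)
  for (ch in focus_channels) {
    ctx_ch <- channel_context(ch)
    nsites <- colSums(ctxmat == ctx_ch, na.rm = TRUE)
    sel <- !is.na(mut_channel) & mut_channel == ch
    muts <- tabulate(hits$offset[sel] + flank + 1L, nbins = L)
    rate <- ifelse(nsites > 0, muts / nsites, NA_real_)
    per_offset[[ch]] <- data.frame(channel = ch, offset = offsets,
                                   mutations = muts, context_sites = nsites,
                                   rate = rate, stringsAsFactors = FALSE)
    bi <- findInterval(hits$offset[sel], brk)
    bm <- tabulate(bi, nbins = length(brk) - 1L)
    binned[[ch]] <- data.frame(channel = ch,
                               bin_start = brk[-length(brk)],
                               bin_end = pmin(brk[-1] - 1L, flank),
                               mutations = bm, stringsAsFactors = FALSE)
  }
  list(per_offset = do.call(rbind, per_offset),
       binned = do.call(rbind, binned))
}
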