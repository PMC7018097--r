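METHYL_BIN_LABELS <- c("[0]", "(0,0.1]", "(0.1,0.2]", "(0.2,0.3]",
                       "(0.3,0.4]", "(0.4,0.5]", "(0.5,0.6]", "(0.6,0.7]",
                       "(0.7,0.8]", "(0.8,0.9]", "(0.9,1)", "[1]")

#' Read a CpG methylation track
#'
#' Reads a bedGraph/bedMethyl-like TSV with columns `chrom`, `pos` (1-based
#' position of the CpG cytosine on the plus strand), `beta` (methylation
#' fraction in `[0, 1]`) and optionally `coverage`.
#'
#' @param path file path.
#' @return a `MethylationTrack` (data.frame subclass).
#' @export
read_methylation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "beta")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("methylation track missing column(s): %s",
                          paste(miss, collapse = ", "))
  methylation_track(df)
}

#' Construct a MethylationTrack
#' @param df data.frame with `chrom`, `pos`, `beta` and optional `coverage`.
#' @return a `MethylationTrack`.
#' @export
methylation_track <- function(df) {
  if (any(df$beta < 0 | df$beta > 1, na.rm = TRUE))
    stopf("methylation beta outside [0, 1]")
  df$pos <- as.integer(df$pos)
  structure(as.data.frame(df), class = c("MethylationTrack", "data.frame"))
}

#' Validate CpG sites against the genome
#'
#' Keeps only sites whose position is a `C` immediately followed by a `G` on
#' the plus strand; others are dropped with a warning.
#'
#' @param track a `MethylationTrack`.
#' @param genome a `ReferenceGenome`.
#' @return the filtered track.
#' @export
validate_cpgs <- function(track, genome) {
  ok <- logical(nrow(track))
  for (cm in unique(track$chrom)) {
    idx <- which(track$chrom == cm)
    s <- genome_seq(genome, cm)
    p <- track$pos[idx]
    inb <- p >= 1L & p + 1L <= nchar(s)
    ok[idx] <- inb
    ok[idx][inb] <- substring(s, p[inb], p[inb] + 1L) == "CG"
  }
  if (any(!ok)) warnf("%d site(s) are not CpG on the plus strand; dropped",
                      sum(!ok))
  out <- track[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign CpG sites to the 12 methylation bins
#'
#' Bin 1 holds fully unmethylated sites (`beta = 0`), bin 12 fully methylated
#' sites (`beta = 1`), and bins 2-11 the half-open deciles
#' `(0, 0.1], ..., (0.9, 1.0)`.
#'
#' @param track a validated `MethylationTrack`.
#' @param min_coverage optional minimum coverage filter (sites below it are
#'   excluded before binning; default off).
#' @return the track with an integer `bin` column (1-12) and a `bin_label`
#'   factor.
#' @export
bin_cpgs_by_methylation <- function(track, min_coverage = NULL) {
  if (any(track$beta < 0 | track$beta > 1))
    stopf("methylation beta outside [0, 1]")
  if (!is.null(min_coverage)) {
    if (!"coverage" %in% names(track))
      stopf("min_coverage given but track has no coverage column")
    track <- track[track$coverage >= min_coverage, , drop = FALSE]
  }
  b <- track$beta
  bin <- ifelse(b == 0, 1L, ifelse(b == 1, 12L,
                pmin(as.integer(ceiling(b * 10)) + 1L, 11L)))
  track$bin <- bin
  track$bin_label <- factor(METHYL_BIN_LABELS[bin],
                            levels = METHYL_BIN_LABELS)
  rownames(track) <- NULL
  track
}

# CpG-unit C>T mutations: a C>T at the plus-strand C of a CpG, or a G>A at
# the paired G (which collapses onto the same CpG unit).
cpg_ct_mutations <- function(catalog, genome) {
  if (nrow(catalog) == 0L)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      cpg_pos = integer(0)))
  out <- vector("list", length(unique(catalog$chrom)))
  i <- 0L
  for (cm in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == cm)
    s <- genome_seq(genome, cm)
    L <- nchar(s)
    p <- catalog$pos[idx]
    plus <- catalog$ref[idx] == "C" & catalog$alt[idx] == "T" &
      p < L & substring(s, p + 1L, p + 1L) == "G"
    minus <- catalog$ref[idx] == "G" & catalog$alt[idx] == "A" &
      p > 1L & substring(s, p - 1L, p - 1L) == "C"
    cp <- c(p[plus], p[minus] - 1L)
    sid <- c(catalog$sample_id[idx][plus], catalog$sample_id[idx][minus])
    i <- i + 1L
    out[[i]] <- data.frame(sample_id = sid, chrom = rep(cm, length(cp)),
                           cpg_pos = cp, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-bin CpG C>T mutation rates for one or more groups
#'
#' For each group's catalog, counts C>T mutations at binned CpG cytosines
#' (both strands: a G>A at the paired G maps to the same CpG unit) and
#' converts to mutations per megabase of CpG sites:
#' `rate = 1e6 * mutations / sites`.
#'
#' @param catalogs named list of `MutationCatalog`, one per group (a single
#'   catalog is treated as one group).
#' @param binned_track output of [bin_cpgs_by_methylation()].
#' @param genome a `ReferenceGenome`.
#' @param mode `"pooled"` (pool mutations across a group's samples; default)
#'   or `"per_sample"` (average per-sample rates).
#' @return a `MethylBinProfile`: data.frame with `group`, `bin`, `bin_label`,
#'   `sites`, `mutations`, `rate` (NA-flagged where a bin is empty).
#' @export
mutation_rate_per_bin <- function(catalogs, binned_track, genome,
                                  mode = c("pooled", "per_sample")) {
  mode <- match.arg(mode)
  if (inherits(catalogs, "MutationCatalog")) catalogs <- list(group = catalogs)
  if (!"bin" %in% names(binned_track))
    stopf("track has no 'bin' column; run bin_cpgs_by_methylation() first")
  site_key <- paste(binned_track$chrom, binned_track$pos)
  sites_per_bin <- tabulate(binned_track$bin, nbins = 12L)
  res <- lapply(names(catalogs), function(g) {
    cpg <- cpg_ct_mutations(catalogs[[g]], genome)
    hit <- match(paste(cpg$chrom, cpg$cpg_pos), site_key)
    cpg <- cpg[!is.na(hit), , drop = FALSE]
    bin_of <- binned_track$bin[hit[!is.na(hit)]]
    if (mode == "pooled") {
      muts <- tabulate(bin_of, nbins = 12L)
      rate <- ifelse(sites_per_bin > 0, 1e6 * muts / sites_per_bin, NA_real_)
    } else {
      samples <- unique(catalogs[[g]]$sample_id)
      per <- sapply(samples, function(sid)
        tabulate(bin_of[cpg$sample_id == sid], nbins = 12L))
      per <- matrix(per, nrow = 12L)
      rates <- sweep(per, 1, sites_per_bin, "/") * 1e6
      rate <- rowMeans(rates)
      rate[sites_per_bin == 0] <- NA_real_
      muts <- rowSums(per)
    }
    data.frame(group = g, bin = 1:12, bin_label = METHYL_BIN_LABELS,
               sites = sites_per_bin, mutations = muts, rate = rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("MethylBinProfile", "data.frame"))
}

#' Per-bin mutation burden relative to a reference group
#'
#' Divides every group's per-bin rate by the reference group's rate in the
#' same bin (the reference group's own ratios are all 1). A flat ratio
#' across bins means the groups share the same methylation dependence and
#' differ only in total burden.
#'
#' @param profile a `MethylBinProfile` covering all groups.
#' @param reference_group group name used as denominator.
#' @return data.frame with `group`, `bin`, `bin_label`, `ratio` (NA where the
#'   reference rate is zero or undefined).
#' @export
relative_burden <- function(profile, reference_group) {
  if (!reference_group %in% profile$group)
    stopf("reference group '%s' not in profile", reference_group)
  ref <- profile[profile$group == reference_group, ]
  ref_rate <- ref$rate[match(1:12, ref$bin)]
  out <- profile[c("group", "bin", "bin_label")]
  denom <- ref_rate[profile$bin]
  out$ratio <- ifelse(!is.na(denom) & denom > 0, profile$rate / denom,
                      NA_real_)
  rownames(out) <- NULL
  out
}

# Pentanucleotide (NNCGN) context of CpG sites, pyrimidine-stated (the
# center is the plus-strand C, so no collapsing is needed beyond taking the
# plus strand). Sites too close to a chromosome end or with N are NA.
cpg_penta_contexts <- function(sites, genome) {
  ctx <- rep(NA_character_, nrow(sites))
  for (cm in unique(sites$chrom)) {
    idx <- which(sites$chrom == cm)
    s <- genome_seq(genome, cm)
    L <- nchar(s)
    p <- sites$pos[idx]
    inb <- p >= 3L & p + 2L <= L
    ctx[idx][inb] <- substring(s, p[inb] - 2L, p[inb] + 2L)
  }
  ctx[!is.na(ctx) & grepl("N", ctx, fixed = TRUE)] <- NA_character_
  ctx
}

# All 64 NNCGN contexts, sorted.
nncgn_contexts <- function() {
  g <- expand.grid(n3 = BASES, n2 = BASES, n1 = BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$n1, g$n2, "CG", g$n3))
}

#' Pentanucleotide context composition of CpG sets
#'
#' Distribution over the 64 `NNCGN` contexts for each methylation bin (or for
#' any CpG site set).
#'
#' @param binned_track output of [bin_cpgs_by_methylation()] (or any
#'   data.frame of CpG sites with `chrom`, `pos`; a missing `bin` column is
#'   treated as one bin).
#' @param genome a `ReferenceGenome`.
#' @return matrix (bins x 64 contexts) of proportions, each row summing to 1
#'   (empty bins are all-NA).
#' @export
context_composition_per_bin <- function(binned_track, genome) {
  if (!"bin" %in% names(binned_track)) binned_track$bin <- 1L
  ctx <- cpg_penta_contexts(binned_track, genome)
  keep <- !is.na(ctx)
  bins <- sort(unique(binned_track$bin))
  space <- nncgn_contexts()
  out <- matrix(NA_real_, nrow = length(bins), ncol = length(space),
                dimnames = list(as.character(bins), space))
  for (i in seq_along(bins)) {
    sel <- keep & binned_track$bin == bins[i]
    if (!any(sel)) next
    tab <- table(factor(ctx[sel], levels = space))
    out[i, ] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' TTCGA share of CpG C>T mutations
#'
#' The fraction (in percent) of distinct mutated TTCGA sites among all
#' NN[C>T]GN mutations of a catalog — the statistic that quantifies how
#' much more likely a TT[C>T]GA-context driver site (such as TP53 R213*)
#' is to be hit in one mutational background than another. Sites are
#' counted once per distinct (chrom, position); mutations are pooled over
#' samples.
#'
#' @param catalog a `MutationCatalog`.
#' @param genome a `ReferenceGenome`.
#' @return list with `ttcga_sites` (distinct mutated TTCGA CpG units),
#'   `nncgn_mutations` (all CpG C>T mutations) and `percent`
#'   (`100 * ttcga_sites / nncgn_mutations`; NA when no CpG mutations).
#' @export
ttcga_fraction <- function(catalog, genome) {
  cpg <- cpg_ct_mutations(catalog, genome)
  n_all <- nrow(cpg)
  if (n_all == 0L)
    return(list(ttcga_sites = 0L, nncgn_mutations = 0L, percent = NA_real_))
  ctx <- cpg_penta_contexts(data.frame(chrom = cpg$chrom, pos = cpg$cpg_pos),
                            genome)
  hit <- !is.na(ctx) & ctx == "TTCGA"
  n_sites <- length(unique(paste(cpg$chrom[hit], cpg$cpg_pos[hit])))
  list(ttcga_sites = n_sites, nncgn_mutations = n_all,
       percent = 100 * n_sites / n_all)
}

#' Pentanucleotide composition-normalized mutation burden of a CpG bin
#'
#' Re-weights a bin's per-context C>T mutation counts `N(k)` by the ratio of
#' genome-wide context weights `f(k)` to the bin's own context weights
#' `F(k)`:
#' \deqn{C = \sum_k N(k) \, f(k) / F(k)}
#' so a bin over-enriched in a hot context is shrunk toward what its burden
#' would be at the genome-wide composition. When the bin's composition
#' equals the genome-wide composition the formula collapses to the raw total
#' \eqn{\sum_k N(k)}.
#'
#' @param bin_sites CpG sites of one bin (data.frame with `chrom`, `pos`).
#' @param catalog a `MutationCatalog` (only CpG C>T mutations at `bin_sites`
#'   are counted).
#' @param genome a `ReferenceGenome`.
#' @param genome_weights named numeric over the 64 `NNCGN` contexts summing
#'   to 1: the genome-wide CpG context weights `f`. Computed from
#'   `all_sites` when `NULL`.
#' @param all_sites all genome-wide CpG sites (required when
#'   `genome_weights` is `NULL`).
#' @return list with `C` (normalized burden), `sum_N` (raw burden),
#'   `percent_change` (`100 * (C - sum_N) / sum_N`), and the per-context
#'   `N`, `f`, `F` vectors.
#' @export
penta_normalized_rate <- function(bin_sites, catalog, genome,
                                  genome_weights = NULL, all_sites = NULL) {
  space <- nncgn_contexts()
  if (is.null(genome_weights)) {
    if (is.null(all_sites))
      stopf("supply genome_weights or all_sites")
    ctx_all <- cpg_penta_contexts(all_sites, genome)
    tab <- table(factor(ctx_all[!is.na(ctx_all)], levels = space))
    genome_weights <- as.numeric(tab) / sum(tab)
    names(genome_weights) <- space
  }
  f <- genome_weights[space]
  if (abs(sum(f) - 1) > 1e-8) stopf("genome_weights must sum to 1")
  ctx_bin <- cpg_penta_contexts(bin_sites, genome)
  tabF <- table(factor(ctx_bin[!is.na(ctx_bin)], levels = space))
  Fw <- as.numeric(tabF) / sum(tabF)
  names(Fw) <- space
  cpg <- cpg_ct_mutations(catalog, genome)
  hit <- match(paste(cpg$chrom, cpg$cpg_pos),
               paste(bin_sites$chrom, bin_sites$pos))
  cpg <- cpg[!is.na(hit), , drop = FALSE]
  mut_ctx <- cpg_penta_contexts(data.frame(chrom = cpg$chrom,
                                           pos = cpg$cpg_pos), genome)
  N <- as.numeric(table(factor(mut_ctx[!is.na(mut_ctx)], levels = space)))
  names(N) <- space
  if (any(N > 0 & Fw == 0))
    stopf("context(s) mutated but absent from the bin: %s",
          paste(space[N > 0 & Fw == 0], collapse = ", "))
  term <- ifelse(N == 0 & Fw == 0, 0, N * f / Fw)
  C <- sum(term)
  sum_N <- sum(N)
  list(C = C, sum_N = sum_N,
       percent_change = if (sum_N > 0) 100 * (C - sum_N) / sum_N else NA_real_,
       N = N, f = f, F = Fw)
}
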