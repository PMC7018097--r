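## Synthetic-data generator: genomes, methylation, replication landscapes,
## gene models, motifs, dyads, and signature-driven mutation cohorts with
## plantable effects. Fully deterministic per seed.

#' Built-in 96-channel signatures for POLE-mutant groups
#'
#' Qualitative archetypes of the POLE exonuclease-mutant mutational process
#' (COSMIC signature 10-like): peaks at C>A in TCT, C>T in TCG and T>G in
#' TTT, with the C>T-at-CpG share elevated in the V411L archetype relative
#' to P286R, and an MSS archetype dominated by CpG C>T. Used as generator
#' truth; any user-supplied 96-vector works in its place.
#'
#' @param variant one of `"P286R"`, `"V411L"`, `"Other-Exo"`, `"MSS"`.
#' @return named numeric vector over [channel_space()] summing to 1.
#' @export
pole_signature <- function(variant = c("P286R", "V411L", "Other-Exo", "MSS")) {
  variant <- match.arg(variant)
  space <- channel_space(1L)
  sig <- setNames(numeric(96), space)
  cpg_ct <- space[channel_type(space) == "C>T" &
                    substr(channel_context(space), 3, 3) == "G"]
  add <- function(channels, mass) sig[channels] <<- sig[channels] + mass / length(channels)
  if (variant == "P286R") {
    add("T[C>A]T", 0.30); add("T[T>G]T", 0.20); add("T[C>T]G", 0.05)
    add(setdiff(cpg_ct, "T[C>T]G"), 0.06)
  } else if (variant == "V411L") {
    add("T[C>A]T", 0.15); add("T[T>G]T", 0.10); add("T[C>T]G", 0.18)
    add(setdiff(cpg_ct, "T[C>T]G"), 0.12)
  } else if (variant == "Other-Exo") {
    add("T[C>A]T", 0.22); add("T[T>G]T", 0.15); add("T[C>T]G", 0.10)
    add(setdiff(cpg_ct, "T[C>T]G"), 0.08)
  } else {
    add(cpg_ct, 0.45)
  }
  rest <- 1 - sum(sig)
  sig <- sig + rest / 96
  sig / sum(sig)
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the stated GC content, with Poisson-placed CpG islands
#' (segments re-drawn at elevated C/G frequency, raising local CpG density).
#'
#' @param length chromosome length in bp (>= 10 kb).
#' @param gc_fraction genome-wide GC fraction (default 0.42, human-like).
#' @param cpg_island_rate expected islands per bp (default 1 per 50 kb).
#' @param island_length island length in bp (default 500).
#' @param island_gc GC fraction inside islands (default 0.7).
#' @param chrom chromosome name.
#' @param seed RNG seed; the output is deterministic per seed.
#' @return a `ReferenceGenome` with one chromosome.
#' @export
simulate_genome <- function(length, gc_fraction = 0.42,
                            cpg_island_rate = 1 / 5e4, island_length = 500L,
                            island_gc = 0.7, chrom = "chr1", seed = 1L) {
  if (length < 1e4) stopf("genome length must be >= 10 kb")
  if (gc_fraction <= 0 || gc_fraction >= 1 || island_gc <= 0 || island_gc >= 1)
    stopf("GC fractions must lie in (0, 1)")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(BASES, length, replace = TRUE, prob = p[BASES])
  n_isl <- stats::rpois(1, cpg_island_rate * length)
  if (n_isl > 0) {
    starts <- sample.int(max(1L, length - island_length), n_isl, replace = TRUE)
    pi <- c(A = (1 - island_gc) / 2, C = island_gc / 2,
            G = island_gc / 2, T = (1 - island_gc) / 2)
    for (s in starts) {
      idx <- s:min(length, s + island_length - 1L)
      bases[idx] <- sample(BASES, base::length(idx), replace = TRUE,
                           prob = pi[BASES])
    }
  }
  reference_genome(setNames(paste(bases, collapse = ""), chrom))
}

#' All plus-strand CpG cytosine positions of a genome
#' @param genome a `ReferenceGenome`.
#' @return data.frame with `chrom`, `pos`.
#' @export
find_cpgs <- function(genome) {
  out <- lapply(names(genome$sequences), function(cm) {
    m <- gregexpr("CG", genome$sequences[[cm]], fixed = TRUE)[[1]]
    p <- as.integer(m[m > 0])
    data.frame(chrom = cm, pos = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a CpG methylation track
#'
#' Beta values are drawn from a bimodal mixture — a spike at 0, a spike at
#' 1, a dominant high-methylation Beta body and a minority low-methylation
#' body (the bimodal shape of somatic-tissue WGBS) — so all 12 methylation
#' bins are populated, including the degenerate `[0]` and `[1]` bins. CpGs
#' inside `low_regions` (e.g. promoters) draw from a low-methylation Beta
#' instead.
#'
#' @param genome a `ReferenceGenome`.
#' @param p_zero,p_one spike probabilities (defaults 0.08 and 0.12).
#' @param shape1,shape2 high-methylation Beta body parameters (5, 1.5).
#' @param body_low_frac fraction of body draws from the low-methylation
#'   component (default 0.25).
#' @param body_low_shape1,body_low_shape2 low body parameters (1.5, 5).
#' @param low_regions optional data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) where beta ~ Beta(`low_shape1`, `low_shape2`).
#' @param low_shape1,low_shape2 low-methylation Beta parameters (1, 8).
#' @param mean_coverage Poisson mean of per-site coverage (30).
#' @param seed RNG seed.
#' @return a `MethylationTrack` over every CpG of the genome.
#' @export
simulate_methylation <- function(genome, p_zero = 0.08, p_one = 0.12,
                                 shape1 = 5, shape2 = 1.5,
                                 body_low_frac = 0.25,
                                 body_low_shape1 = 1.5, body_low_shape2 = 5,
                                 low_regions = NULL, low_shape1 = 1,
                                 low_shape2 = 8, mean_coverage = 30,
                                 seed = 1L) {
  set.seed(seed)
  sites <- find_cpgs(genome)
  n <- nrow(sites)
  u <- stats::runif(n)
  beta <- ifelse(stats::runif(n) < body_low_frac,
                 stats::rbeta(n, body_low_shape1, body_low_shape2),
                 stats::rbeta(n, shape1, shape2))
  beta[u < p_zero] <- 0
  beta[u >= p_zero & u < p_zero + p_one] <- 1
  if (!is.null(low_regions)) {
    low <- logical(n)
    for (i in seq_len(nrow(low_regions))) {
      low <- low | (sites$chrom == low_regions$chrom[i] &
                      sites$pos > low_regions$start[i] &
                      sites$pos <= low_regions$end[i])
    }
    beta[low] <- stats::rbeta(sum(low), low_shape1, low_shape2)
  }
  sites$beta <- beta
  sites$coverage <- stats::rpois(n, mean_coverage)
  methylation_track(sites)
}

#' Simulate a replication/gene/motif/dyad landscape
#'
#' The replication-timing profile is a smooth sinusoid spanning the default
#' five-bin range `[-4.51712, 80.6964]`, so every timing bin is populated
#' and left/right replication breakpoints sit at the analytic extrema
#' (returned as truth). Gene models all have at least three exons with every
#' part at least 20 bp; motifs are Poisson-placed points with random strand;
#' dyads are regularly spaced with jitter.
#'
#' @param genome a `ReferenceGenome` (single chromosome).
#' @param timing_period sinusoid period in bp (default 2 Mb).
#' @param timing_step bedGraph interval width (default 10 kb).
#' @param n_genes number of gene models (default 40).
#' @param motif_rate expected motifs per bp (default 1 per 50 kb).
#' @param motif_margin distance motifs keep from chromosome ends (1.2 kb).
#' @param dyad_spacing mean dyad spacing in bp (default 1 kb).
#' @param seed RNG seed.
#' @return list with `timing` (a `TimingTrack`), `genes` (`GeneModelSet`),
#'   `motifs` (data.frame chrom/center/strand), `dyads` (chrom/pos) and
#'   `truth` (timing extrema = replication breakpoints, direction by span).
#' @export
simulate_landscape <- function(genome, timing_period = 2e6,
                               timing_step = 1e4, n_genes = 40L,
                               motif_rate = 1 / 5e4, motif_margin = 1200L,
                               dyad_spacing = 1e3, seed = 1L) {
  set.seed(seed)
  cm <- names(genome$sequences)[1]
  L <- genome$lengths[[cm]]
  lo <- TIMING_BIN_BOUNDS[1]; hi <- TIMING_BIN_BOUNDS[length(TIMING_BIN_BOUNDS)]
  mid <- (lo + hi) / 2; amp <- (hi - lo) / 2
  starts <- seq(0L, L - timing_step, by = timing_step)
  mids <- starts + timing_step / 2
  timing <- timing_track(data.frame(
    chrom = cm, start = starts, end = starts + timing_step,
    value = mid + amp * sin(2 * pi * mids / timing_period)))
  # extrema of sin(2 pi x / T): x = T/4 + j T/2
  extrema <- timing_period / 4 +
    (0:floor(2 * L / timing_period)) * timing_period / 2
  extrema <- extrema[extrema <= L]
  # genes: fixed internal structure, alternating strand, spaced on a grid
  if (n_genes > 0) {
    exon_w <- 400L; intron_w <- 900L; utr5_w <- 300L; utr3_w <- 500L
    n_ex <- 5L
    glen <- utr5_w + utr3_w + n_ex * exon_w + (n_ex - 1L) * intron_w
    gap <- max(1000, floor((L - 2000 - n_genes * glen) / max(1, n_genes)))
    if (gap < 200) stopf("genome too short for %d genes", n_genes)
    genes <- vector("list", n_genes)
    at <- 1000L
    for (i in seq_len(n_genes)) {
      strand <- if (i %% 2L == 0L) "-" else "+"
      tx_start <- at
      ex_s <- integer(n_ex); ex_e <- integer(n_ex)
      pos <- tx_start
      for (j in seq_len(n_ex)) {
        ex_s[j] <- pos
        w <- exon_w + (if (j == 1L) utr5_w else 0L) + (if (j == n_ex) utr3_w else 0L)
        ex_e[j] <- pos + w - 1L
        pos <- ex_e[j] + 1L + intron_w
      }
      tx_end <- ex_e[n_ex]
      if (strand == "+") {
        cds_start <- ex_s[1] + utr5_w; cds_end <- ex_e[n_ex] - utr3_w
      } else {
        cds_start <- ex_s[1] + utr3_w; cds_end <- ex_e[n_ex] - utr5_w
      }
      genes[[i]] <- gene_model(sprintf("gene%03d", i), cm, strand,
                               tx_start, tx_end, cds_start, cds_end,
                               ex_s, ex_e)
      at <- tx_end + gap
      if (at + glen > L - 1000L) { genes <- genes[seq_len(i)]; break }
    }
    genes <- structure(genes, class = "GeneModelSet")
  } else genes <- structure(list(), class = "GeneModelSet")
  n_motif <- stats::rpois(1, motif_rate * L)
  motifs <- data.frame(
    chrom = rep(cm, n_motif),
    center = sort(sample((motif_margin + 1L):(L - motif_margin), n_motif)),
    strand = sample(c("+", "-"), n_motif, replace = TRUE),
    stringsAsFactors = FALSE)
  dyad_pos <- seq(200L, L - 200L, by = dyad_spacing)
  dyad_pos <- dyad_pos + sample(-100:100, length(dyad_pos), replace = TRUE)
  dyad_pos <- dyad_pos[dyad_pos > 80L & dyad_pos < L - 80L]
  dyads <- data.frame(chrom = cm, pos = as.integer(dyad_pos),
                      stringsAsFactors = FALSE)
  list(timing = timing, genes = genes, motifs = motifs, dyads = dyads,
       truth = list(timing_period = timing_period, extrema = extrema,
                    first_span_direction = "right"))
}

## ---- mutation sampling -----------------------------------------------------

base_code_table <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A")] <- 0L; tab[utf8ToInt("C")] <- 1L
  tab[utf8ToInt("G")] <- 2L; tab[utf8ToInt("T")] <- 3L
  tab
})

# 64 x 4 lookup: row = trinucleotide code (16*b1 + 4*b2 + b3), column = alt
# base code + 1; entry = signature probability of the collapsed channel
# (0 where alt equals the center base).
signature_lut <- function(signature) {
  space <- channel_space(1L)
  if (is.null(names(signature))) names(signature) <- space
  if (!setequal(names(signature), space))
    stopf("signature must be named over the 96-channel space")
  if (any(signature < 0) || abs(sum(signature) - 1) > 1e-6)
    stopf("signature must be a probability vector")
  S <- matrix(0, nrow = 64L, ncol = 4L)
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  ctx <- paste0(g$b1, g$b2, g$b3)
  code <- 16L * (match(g$b1, BASES) - 1L) + 4L * (match(g$b2, BASES) - 1L) +
    (match(g$b3, BASES) - 1L)
  for (i in seq_along(ctx)) {
    center <- g$b2[i]
    for (alt in setdiff(BASES, center)) {
      ch <- collapse_channel(center, alt, ctx[i])
      S[code[i] + 1L, match(alt, BASES)] <- signature[[ch]]
    }
  }
  S
}

# Reverse-complement lookup for trinucleotide codes, and the collapsed
# (pyrimidine-centered) representative of each code.
collapse_code_table <- local({
  codes <- 0:63
  b1 <- codes %/% 16L; b2 <- (codes %/% 4L) %% 4L; b3 <- codes %% 4L
  rc <- (3L - b3) * 16L + (3L - b2) * 4L + (3L - b1)
  ifelse(b2 %in% c(1L, 3L), codes, rc)  # C=1, T=3 are pyrimidines
})

# Per-position, per-alt sampling weights over one chromosome.
# Returns list(pos, W) where W is an n x 4 matrix (columns = alt A,C,G,T);
# positions at chromosome ends or with N in the window have zero weight.
# Each weight is signature[channel] / abundance(collapsed context), so the
# expected channel distribution of a sampled catalog equals the signature
# regardless of genome composition (the sampler inverts build_spectrum).
position_weights <- function(seq, S) {
  v <- base_code_table[utf8ToInt(seq)]
  L <- length(v)
  ctx <- 16L * v[1:(L - 2L)] + 4L * v[2:(L - 1L)] + v[3:L]
  pos <- 2:(L - 1L)
  ok <- !is.na(ctx)
  coll <- collapse_code_table[ctx[ok] + 1L]
  A <- tabulate(coll + 1L, nbins = 64L)
  W <- matrix(0, nrow = L - 2L, ncol = 4L)
  W[ok, ] <- S[ctx[ok] + 1L, ] / A[coll + 1L]
  list(pos = pos, W = W, center = v[2:(L - 1L)])
}

# Apply a multiplicative modifier to weights at given positions for a given
# (center base, alt base) pair, or for all alts when alt is NULL.
apply_factor <- function(pw, positions, factor, center = NULL, alt = NULL) {
  idx <- positions - 1L  # pos p maps to row p - 1
  idx <- idx[idx >= 1L & idx <= nrow(pw$W)]
  if (!is.null(center))
    idx <- idx[pw$center[idx] == (match(center, BASES) - 1L)]
  if (length(idx) == 0L) return(pw)
  if (is.null(alt)) pw$W[idx, ] <- pw$W[idx, ] * factor
  else pw$W[idx, match(alt, BASES)] <- pw$W[idx, match(alt, BASES)] * factor
  pw
}

positions_in_regions <- function(regions, chrom, L) {
  out <- integer(0)
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r)))
    out <- c(out, (max(1L, r$start[i] + 1L)):(min(L, r$end[i])))
  unique(out)
}

#' Simulate a signature-driven mutation catalog
#'
#' Draws exactly `n` distinct positions (without replacement) with
#' probability proportional to the signature weight of each candidate
#' (position, alt) channel, optionally thinned or boosted by modifiers, then
#' draws the alt allele conditionally. Modifiers:
#' \describe{
#'   \item{methylation}{`list(track, slope)` — multiplies the C>T odds at
#'     each CpG cytosine (and G>A at the paired G) by `slope * beta`.}
#'   \item{strand_bias}{list of `list(type, factor, directions)` — within
#'     `left`-direction regions multiplies the plus-strand pyrimidine-stated
#'     type (e.g. C>A) by `factor`; within `right` regions the complementary
#'     purine-stated type.}
#'   \item{region_factor}{list of `list(regions, factor)` — multiplies all
#'     weights inside the regions (0-based half-open), e.g. CTCF or exon
#'     depletion with `factor < 1`.}
#'   \item{position_factor}{list of `list(positions, factor)` — multiplies
#'     all weights at the listed 1-based positions (e.g. minor-groove-in
#'     excess).}
#' }
#'
#' @param genome a `ReferenceGenome`.
#' @param signature named 96-channel probability vector.
#' @param n number of mutations to draw per the catalog.
#' @param sample_id sample label for the records.
#' @param modifiers list as described above (default none).
#' @param seed RNG seed.
#' @return a `MutationCatalog`.
#' @export
simulate_mutations <- function(genome, signature, n, sample_id = "sample1",
                               modifiers = list(), seed = 1L) {
  set.seed(seed)
  S <- signature_lut(signature)
  recs <- list()
  chroms <- names(genome$sequences)
  # build weights per chromosome, then sample jointly
  pws <- list(); tot <- numeric(length(chroms))
  for (ci in seq_along(chroms)) {
    cm <- chroms[ci]
    seq_ <- genome$sequences[[cm]]
    pw <- position_weights(seq_, S)
    if (!is.null(modifiers$methylation)) {
      tr <- modifiers$methylation$track
      sl <- modifiers$methylation$slope
      sites <- tr[tr$chrom == cm, , drop = FALSE]
      if (nrow(sites)) {
        pw <- apply_factor_vec(pw, sites$pos, sl * sites$beta,
                               center = "C", alt = "T")
        pw <- apply_factor_vec(pw, sites$pos + 1L, sl * sites$beta,
                               center = "G", alt = "A")
      }
    }
    for (sb in modifiers$strand_bias %||% list()) {
      ref <- substr(sb$type, 1, 1); alt <- substr(sb$type, 3, 3)
      dd <- sb$directions
      lf <- dd[dd$chrom == cm & dd$direction == "left", , drop = FALSE]
      rt <- dd[dd$chrom == cm & dd$direction == "right", , drop = FALSE]
      L <- genome$lengths[[cm]]
      if (nrow(lf))
        pw <- apply_factor(pw, positions_in_regions(lf, cm, L), sb$factor,
                           center = ref, alt = alt)
      if (nrow(rt))
        pw <- apply_factor(pw, positions_in_regions(rt, cm, L), sb$factor,
                           center = comp_base(ref), alt = comp_base(alt))
    }
    for (rf in modifiers$region_factor %||% list()) {
      L <- genome$lengths[[cm]]
      pos <- positions_in_regions(rf$regions, cm, L)
      if (length(pos)) pw <- apply_factor(pw, pos, rf$factor)
    }
    for (pf in modifiers$position_factor %||% list()) {
      pos <- pf$positions$pos[pf$positions$chrom == cm]
      if (length(pos)) pw <- apply_factor(pw, pos, pf$factor)
    }
    pws[[ci]] <- pw
    tot[ci] <- sum(pw$W)
  }
  wpos_all <- unlist(lapply(pws, function(pw) rowSums(pw$W)), use.names = FALSE)
  n_avail <- sum(wpos_all > 0)
  if (n > n_avail)
    stopf("requested %d mutations but only %d weighted positions available",
          n, n_avail)
  # weighted sampling without replacement (exponential-keys method)
  keys <- rep(Inf, length(wpos_all))
  pos_ok <- wpos_all > 0
  keys[pos_ok] <- stats::rexp(sum(pos_ok)) / wpos_all[pos_ok]
  pick <- order(keys)[seq_len(n)]
  # map back to (chrom, pos) and draw alts
  sizes <- vapply(pws, function(pw) nrow(pw$W), integer(1))
  offs <- cumsum(c(0L, sizes))
  chrom_i <- findInterval(pick - 1L, offs[-length(offs)],
                          rightmost.closed = FALSE)
  chrom_i <- pmin(pmax(chrom_i, 1L), length(chroms))
  local_i <- pick - offs[chrom_i]
  pos <- integer(n); refb <- character(n); altb <- character(n)
  for (j in seq_len(n)) {
    pw <- pws[[chrom_i[j]]]
    i <- local_i[j]
    w <- pw$W[i, ]
    altb[j] <- sample(BASES, 1L, prob = w)
    pos[j] <- pw$pos[i]
    refb[j] <- BASES[pw$center[i] + 1L]
  }
  suppressMessages(mutation_catalog(data.frame(
    sample_id = sample_id, chrom = chroms[chrom_i], pos = pos,
    ref = refb, alt = altb, stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized per-position factor for one (center, alt) pair.
apply_factor_vec <- function(pw, positions, factors, center, alt) {
  idx <- positions - 1L
  keep <- idx >= 1L & idx <= nrow(pw$W)
  idx <- idx[keep]; factors <- factors[keep]
  sel <- pw$center[idx] == (match(center, BASES) - 1L)
  idx <- idx[sel]; factors <- factors[sel]
  if (length(idx))
    pw$W[idx, match(alt, BASES)] <- pw$W[idx, match(alt, BASES)] * factors
  pw
}

#' Simulate a full synthetic cohort bundle
#'
#' Generates every input the analysis modules consume — genome, methylation
#' track, replication landscape, gene models, motifs, dyads — plus
#' per-sample signature-driven mutation catalogs with plantable effects and
#' a planted recurrent hotspot (a C>T at a TTCGA site, the TP53 R213*-like
#' context), carried per sample with group-specific Bernoulli probability.
#' The returned truth record holds every planted parameter so each
#' downstream estimate can be scored.
#'
#' @param groups named list: per group `list(n_samples, signature,
#'   n_mutations, carriage)` (`carriage` = hotspot carriage probability).
#'   Default: P286R / V411L / Other-Exo archetypes, 5 samples each, 20,000
#'   mutations per sample, carriage 0.625 / 0.194 / 0.194.
#' @param genome_length genome size in bp (default 5 Mb).
#' @param modifiers modifier spec applied to every sample (see
#'   [simulate_mutations()]); entries referring to landscape features may be
#'   given as functions of the bundle-in-progress via `make_modifiers`.
#' @param make_modifiers optional `function(genome, methylation, landscape)`
#'   returning the modifier list (overrides `modifiers`).
#' @param seed master RNG seed; per-sample seeds are derived from it.
#' @return a `SyntheticBundle`: list with `genome`, `methylation`,
#'   `landscape`, `catalog` (all samples pooled, `sample_id` set),
#'   `groups` (named vector sample -> group), `hotspot` (chrom/pos/ref/alt)
#'   and `truth`.
#' @export
simulate_cohort <- function(groups = NULL, genome_length = 5e6,
                            modifiers = list(), make_modifiers = NULL,
                            seed = 1L) {
  if (is.null(groups)) {
    groups <- list(
      "P286R" = list(n_samples = 5L, signature = pole_signature("P286R"),
                     n_mutations = 20000L, carriage = 0.625),
      "V411L" = list(n_samples = 5L, signature = pole_signature("V411L"),
                     n_mutations = 20000L, carriage = 0.194),
      "Other-Exo" = list(n_samples = 5L, signature = pole_signature("Other-Exo"),
                         n_mutations = 20000L, carriage = 0.194))
  }
  genome <- simulate_genome(genome_length, seed = seed)
  methylation <- simulate_methylation(genome, seed = seed + 1L)
  landscape <- simulate_landscape(genome, seed = seed + 2L)
  if (!is.null(make_modifiers))
    modifiers <- make_modifiers(genome, methylation, landscape)
  cm <- names(genome$sequences)[1]
  hotspot_pos <- find_hotspot_site(genome)
  hotspot <- data.frame(chrom = cm, pos = hotspot_pos, ref = "C", alt = "T",
                        stringsAsFactors = FALSE)
  set.seed(seed + 3L)
  sample_seeds <- sample.int(2^30, sum(vapply(groups, `[[`, 0L, "n_samples")))
  carrier_draw <- stats::runif(length(sample_seeds))
  cats <- list(); glab <- character(0)
  si <- 0L
  for (g in names(groups)) {
    spec <- groups[[g]]
    for (j in seq_len(spec$n_samples)) {
      si <- si + 1L
      sid <- sprintf("%s_s%02d", g, j)
      cat_ <- simulate_mutations(genome, spec$signature, spec$n_mutations,
                                 sample_id = sid, modifiers = modifiers,
                                 seed = sample_seeds[si])
      if (carrier_draw[si] < spec$carriage) {
        cat_ <- cat_[!(cat_$chrom == cm & cat_$pos == hotspot_pos), ,
                     drop = FALSE]
        cat_ <- rbind(as.data.frame(cat_),
                      data.frame(sample_id = sid, chrom = cm,
                                 pos = hotspot_pos, ref = "C", alt = "T"))
      }
      cats[[sid]] <- as.data.frame(cat_)
      glab[sid] <- g
    }
  }
  catalog <- suppressMessages(mutation_catalog(do.call(rbind, cats)))
  truth <- list(seed = seed,
                signatures = lapply(groups, `[[`, "signature"),
                carriage = vapply(groups, `[[`, 0, "carriage"),
                n_mutations = vapply(groups, `[[`, 0L, "n_mutations"),
                hotspot = hotspot, modifiers = modifiers,
                landscape = landscape$truth)
  structure(list(genome = genome, methylation = methylation,
                 landscape = landscape, catalog = catalog, groups = glab,
                 hotspot = hotspot, truth = truth),
            class = "SyntheticBundle")
}

#' Simulate hotspot carriage across a large cohort
#'
#' Draws, for each hotspot, per-group carrier counts as independent
#' Bernoulli carriage at the given probabilities — the carriage-level view
#' of a cohort too large to mutation-sample (e.g. the 16 / 31 / 7298
#' group sizes of a registry-scale colorectal cohort).
#'
#' @param group_sizes named integer vector of samples per group.
#' @param carriage matrix (hotspots x groups) of carriage probabilities, or
#'   a single row for one hotspot.
#' @param seed RNG seed.
#' @return list of `HotspotContingency`, one per carriage row.
#' @export
simulate_hotspot_carriage <- function(group_sizes, carriage, seed = 1L) {
  set.seed(seed)
  if (is.null(dim(carriage))) carriage <- matrix(carriage, nrow = 1L)
  if (ncol(carriage) != length(group_sizes))
    stopf("carriage columns must match groups")
  lapply(seq_len(nrow(carriage)), function(i) {
    a <- stats::rbinom(length(group_sizes), group_sizes, carriage[i, ])
    hotspot_contingency(names(group_sizes), a, group_sizes)
  })
}

# First TTCGA occurrence away from the chromosome ends; the planted hotspot
# is the C>T at its central cytosine (TT[C>T]GA context).
find_hotspot_site <- function(genome) {
  cm <- names(genome$sequences)[1]
  s <- genome$sequences[[cm]]
  m <- gregexpr("TTCGA", s, fixed = TRUE)[[1]]
  m <- m[m > 1000 & m < nchar(s) - 1000]
  if (length(m) == 0L || m[1] < 0) stopf("no TTCGA site found in genome")
  as.integer(m[1] + 2L)
}

#' @export
print.SyntheticBundle <- function(x, ...) {
  cat(sprintf("SyntheticBundle: %s bp genome, %d CpGs, %d samples in %d groups, %s mutations\n",
              format(sum(x$genome$lengths), big.mark = ","),
              nrow(x$methylation), length(x$groups),
              length(unique(x$groups)),
              format(nrow(x$catalog), big.mark = ",")))
  cat(sprintf("  planted hotspot: %s:%d %s>%s\n", x$hotspot$chrom,
              x$hotspot$pos, x$hotspot$ref, x$hotspot$alt))
  invisible(x)
}

#' Write a synthetic bundle to standard file formats
#'
#' Emits the genome as FASTA, the pooled catalog as MAF-like TSV, the
#' methylation track and timing profile as TSV/bedGraph, motifs and dyads as
#' BED, gene models as a refFlat-like TSV, group labels as TSV, and the
#' truth record as JSON (when the jsonlite package is available).
#'
#' @param bundle a `SyntheticBundle`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(bundle$genome$sequences)
  Biostrings::writeXStringSet(ss, file.path(dir, "genome.fa"))
  maf <- data.frame(Tumor_Sample_Barcode = bundle$catalog$sample_id,
                    Chromosome = bundle$catalog$chrom,
                    Start_Position = bundle$catalog$pos,
                    Reference_Allele = bundle$catalog$ref,
                    Tumor_Seq_Allele2 = bundle$catalog$alt)
  utils::write.table(maf, file.path(dir, "mutations.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(bundle$methylation),
                     file.path(dir, "methylation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tt <- as.data.frame(bundle$landscape$timing)
  utils::write.table(tt, file.path(dir, "timing.bedgraph"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  mo <- bundle$landscape$motifs
  utils::write.table(data.frame(mo$chrom, mo$center - 1L, mo$center,
                                rep(".", nrow(mo)), rep(0L, nrow(mo)),
                                mo$strand),
                     file.path(dir, "motifs.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  dy <- bundle$landscape$dyads
  utils::write.table(data.frame(dy$chrom, dy$pos - 1L, dy$pos),
                     file.path(dir, "dyads.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gm <- do.call(rbind, lapply(bundle$landscape$genes, function(g)
    data.frame(gene = g$gene, chrom = g$chrom, strand = g$strand,
               txStart = g$tx_start - 1L, txEnd = g$tx_end,
               cdsStart = g$cds_start - 1L, cdsEnd = g$cds_end,
               exonCount = length(g$exon_starts),
               exonStarts = paste0(paste(g$exon_starts - 1L, collapse = ","), ","),
               exonEnds = paste0(paste(g$exon_ends, collapse = ","), ","))))
  utils::write.table(gm, file.path(dir, "genes.genepred"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(bundle$groups),
                                group = unname(bundle$groups)),
                     file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- bundle$truth
    tr$modifiers <- NULL  # may hold closures/large tracks
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
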