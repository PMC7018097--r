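test_that("stack_profile aligns offsets, flips minus strands, stacks overlaps", {
  g <- toy_genome(c(chr1 = random_seq(100, 4)))
  a1 <- anchor_set("chr1", 50L, "+", flank = 5L)
  cat1 <- toy_catalog("chr1", 50L, substr(g$sequences[[1]], 50, 50),
                      setdiff(c("A", "C", "G", "T"),
                              substr(g$sequences[[1]], 50, 50))[1])
  p1 <- stack_profile(cat1, a1)
  expect_equal(p1$observed[p1$offset == 0], 1)
  expect_equal(sum(p1$observed), 1)

  # minus-strand anchor: a mutation 5 bp 3' of center (lower coordinate)
  # appears at offset +5
  a2 <- anchor_set("chr1", 20L, "-", flank = 6L)
  cat2 <- toy_catalog("chr1", 15L, substr(g$sequences[[1]], 15, 15),
                      setdiff(c("A", "C", "G", "T"),
                              substr(g$sequences[[1]], 15, 15))[1])
  p2 <- stack_profile(cat2, a2)
  expect_equal(p2$observed[p2$offset == 5], 1)

  # overlapping windows each count a shared mutation at their own offset
  a3 <- anchor_set("chr1", c(40L, 42L), "+", flank = 3L)
  cat3 <- toy_catalog("chr1", 41L, substr(g$sequences[[1]], 41, 41),
                      setdiff(c("A", "C", "G", "T"),
                              substr(g$sequences[[1]], 41, 41))[1])
  p3 <- stack_profile(cat3, a3)
  expect_equal(sum(p3$observed), 2)
  expect_equal(p3$observed[p3$offset == 1], 1)
  expect_equal(p3$observed[p3$offset == -1], 1)
  expect_error(stack_profile(cat1, a1[0, ]), "non-empty")
})

test_that("expected profile reproduces the hand-evaluated alternating-context toy", {
  # poly-CA track: odd positions have context ACA (X), even GTG (Y);
  # windows at centers 11 and 31 (flank 2) hold contexts X,Y,X,Y,X.
  g <- toy_genome(c(chr1 = strrep("CA", 30)))
  anchors <- anchor_set("chr1", c(11L, 31L), "+", flank = 2L)
  df <- rbind(
    data.frame(sample_id = "s1", pos = c(9L, 11L, 13L), ref = "C", alt = "A"),
    data.frame(sample_id = "s2", pos = c(9L, 11L), ref = "C", alt = "A"),
    data.frame(sample_id = "s1", pos = c(10L, 12L), ref = "A", alt = "C"),
    data.frame(sample_id = "s1", pos = 31L, ref = "C", alt = "A"))
  df$chrom <- "chr1"
  cat_ <- suppressMessages(mutation_catalog(df))
  prof <- expected_profile(cat_, anchors, g)
  # M(X)=6, M(Y)=2, A(X)=6, A(Y)=4 -> f(X)=1, f(Y)=0.5, weights (2,1,2,1,2)/8
  expect_equal(prof$expected, 8 * c(2, 1, 2, 1, 2) / 8)
  expect_equal(sum(prof$expected), sum(prof$observed))
})

test_that("expected profile matches an independent brute-force oracle", {
  for (seed in c(7, 13)) {
    s <- random_seq(300, seed)
    g <- toy_genome(c(chr1 = s))
    set.seed(seed + 100)
    centers <- sort(sample(30:270, 3))
    anchors <- anchor_set("chr1", centers, "+", flank = 10L)
    pos <- unique(unlist(lapply(centers, function(cc) {
      p <- (cc - 10):(cc + 10); sample(p, 6)
    })))
    ref <- substring(s, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
    cat_ <- toy_catalog("chr1", pos, ref, alt)
    prof <- expected_profiles <- expected_profile(cat_, anchors, g)

    # ---- oracle: direct loops, manual collapsing ----
    collapse1 <- function(ctx) {
      if (substr(ctx, 2, 2) %in% c("C", "T")) ctx else rc_str(ctx)
    }
    win_ctx <- list(); win_m <- integer(length(centers))
    for (wi in seq_along(centers)) {
      offs <- (centers[wi] - 10):(centers[wi] + 10)
      win_ctx[[wi]] <- vapply(offs, function(p) collapse1(substr(s, p - 1, p + 1)), "")
    }
    all_ctx <- unique(unlist(win_ctx))
    Atab <- setNames(rep(0, length(all_ctx)), all_ctx)
    Mtab <- Atab
    for (wi in seq_along(centers)) {
      for (x in win_ctx[[wi]]) Atab[x] <- Atab[x] + 1
      offs <- (centers[wi] - 10):(centers[wi] + 10)
      hit <- cat_$pos %in% offs
      win_m[wi] <- sum(hit)
      for (p in cat_$pos[hit]) {
        x <- collapse1(substr(s, p - 1, p + 1))
        Mtab[x] <- Mtab[x] + 1
      }
    }
    f <- setNames(rep(0, length(Atab)), names(Atab))
    f[names(Mtab)] <- Mtab / Atab[names(Mtab)]
    exp_oracle <- numeric(21)
    for (wi in seq_along(centers)) {
      fp <- f[win_ctx[[wi]]]
      if (sum(fp) > 0 && win_m[wi] > 0)
        exp_oracle <- exp_oracle + win_m[wi] * fp / sum(fp)
    }
    expect_equal(prof$expected, unname(exp_oracle), tolerance = 1e-12)
    expect_equal(sum(prof$expected), sum(prof$observed), tolerance = 1e-9)
  }
})

test_that("uniform-context windows spread expectation flat", {
  g <- toy_genome(c(chr1 = strrep("A", 200)))
  anchors <- anchor_set("chr1", 100L, "+", flank = 3L)
  cat_ <- toy_catalog("chr1", c(98L, 100L, 101L), "A", "C",
                      sample_id = c("a", "a", "a"))
  prof <- expected_profile(cat_, anchors, g)
  expect_equal(prof$expected, rep(3 / 7, 7))
})

test_that("TSS profile normalizes by per-offset context counts", {
  s <- rep("A", 200)
  for (p in c(50, 100, 150)) s[p + (1:3)] <- c("T", "C", "G")
  g <- toy_genome(c(chr1 = paste(s, collapse = "")))
  anchors <- anchor_set("chr1", c(50L, 100L, 150L), "+", flank = 10L,
                        kind = "tss")
  cat_ <- toy_catalog("chr1", c(52L, 102L, 152L), "C", "T")
  ts <- tss_profile(cat_, anchors, g, bin_width = 7L)
  po <- ts$per_offset
  row <- po[po$channel == "T[C>T]G" & po$offset == 2, ]
  expect_equal(row$context_sites, 3)
  expect_equal(row$mutations, 3)
  expect_equal(row$rate, 1)
  # offsets with no occurrence of the focus context are missing, not zero
  expect_true(is.na(po$rate[po$channel == "T[C>T]G" & po$offset == 0]))
  # binned raw counts account for all channel mutations
  expect_equal(sum(ts$binned$mutations[ts$binned$channel == "T[C>T]G"]), 3)
})

test_that("gene part decomposition bins sequences 5'->3' and drops <20 bp parts", {
  gA <- gene_model("gA", "chr1", "+", 101L, 2400L, 301L, 2200L,
                   c(101L, 501L, 1001L, 1501L, 2001L),
                   c(400L, 900L, 1400L, 1900L, 2400L))
  gB <- gene_model("gB", "chr1", "-", 101L, 2400L, 301L, 2200L,
                   c(101L, 501L, 1001L, 1501L, 2001L),
                   c(400L, 900L, 1400L, 1900L, 2400L))
  # 5 mutations in gA's first intron (401-500)
  cat_ <- toy_catalog("chr1", c(410L, 420L, 430L, 440L, 450L, 301L, 2400L),
                      "A", "C")
  prof <- gene_part_profile(cat_, list(gA))
  fi <- prof[prof$part == "first intron", ]
  expect_equal(sum(fi$bp), 100)
  expect_equal(sum(fi$mutations), 5)
  expect_equal(sum(fi$rate * fi$bp) / sum(fi$bp), 1e6 * 5 / 100)
  # + strand: cds start 301 lands in first-exon bin 1; 3'UTR end in bin 20
  fe <- prof[prof$part == "first exon", ]
  expect_equal(fe$mutations[fe$bin == 1], 1)
  u3 <- prof[prof$part == "3'UTR", ]
  expect_equal(u3$mutations[u3$bin == 20], 1)
  # widths within a part differ by at most 1 bp
  expect_lte(diff(range(fe$bp)), 1)

  # minus strand: the same genomic position maps to the mirrored bin;
  # position 2400 is gB's 5'UTR bin 1
  profB <- gene_part_profile(cat_, list(gB))
  u5B <- profB[profB$part == "5'UTR", ]
  expect_equal(u5B$mutations[u5B$bin == 1], 1)

  # middle exon shorter than 20 bp is discarded
  gC <- gene_model("gC", "chr1", "+", 101L, 500L, 101L, 500L,
                   c(101L, 301L, 401L), c(200L, 319L, 500L))
  profC <- gene_part_profile(toy_catalog("chr1", 310L, "A", "C"), list(gC))
  expect_equal(sum(profC$bp[profC$part == "middle exon"]), 0)

  # gene order does not change the pooled profile
  both1 <- gene_part_profile(cat_, list(gA, gB))
  both2 <- gene_part_profile(cat_, list(gB, gA))
  expect_equal(both1, both2)
})

test_that("planted depletion around motif centers drops observed below expected", {
  g <- simulate_genome(2e5, seed = 31)
  set.seed(32)
  centers <- sort(sample(1500:198500, 40))
  anchors <- anchor_set("chr1", centers, "+", flank = 200L, kind = "ctcf_motif")
  depl <- data.frame(chrom = "chr1", start = centers - 111L,
                     end = centers + 110L)
  mods <- list(region_factor = list(list(regions = depl, factor = 0.35)))
  cat_ <- simulate_mutations(g, pole_signature("P286R"), 8000,
                             modifiers = mods, seed = 33)
  prof <- expected_profile(cat_, anchors, g)
  cen <- prof[abs(prof$offset) <= 110, ]
  bw <- 10L
  grp <- floor((cen$offset + 110) / bw)
  ob <- tapply(cen$observed, grp, sum)
  ex <- tapply(cen$expected, grp, sum)
  p <- suppressWarnings(stats::wilcox.test(ob, ex, paired = TRUE,
                                           alternative = "less")$p.value)
  expect_lt(p, 0.001)
  expect_lt(sum(cen$observed), sum(cen$expected))
})

test_that("genePred round trip preserves gene structure", {
  g <- simulate_genome(5e4, seed = 2)
  ls_ <- simulate_landscape(g, n_genes = 3, timing_period = 2e4, seed = 3)
  tmp <- tempfile()
  bundle <- structure(list(genome = g,
                           methylation = simulate_methylation(g, seed = 1),
                           landscape = ls_,
                           catalog = simulate_mutations(g, pole_signature("MSS"),
                                                        50, seed = 4),
                           groups = c(sample1 = "g"),
                           hotspot = data.frame(chrom = "chr1", pos = 1,
                                                ref = "C", alt = "T"),
                           truth = list()),
                      class = "SyntheticBundle")
  write_bundle(bundle, tmp)
  genes2 <- read_genepred(file.path(tmp, "genes.genepred"))
  expect_equal(length(genes2), length(ls_$genes))
  expect_equal(genes2[[1]]$exon_starts, ls_$genes[[1]]$exon_starts)
  expect_equal(genes2[[1]]$cds_end, ls_$genes[[1]]$cds_end)
  g2 <- read_fasta(file.path(tmp, "genome.fa"))
  expect_equal(g2$sequences, g$sequences)
  cat2 <- read_mutations(file.path(tmp, "mutations.maf"), "maf_like_tsv")
  expect_equal(nrow(cat2), nrow(bundle$catalog))
})
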