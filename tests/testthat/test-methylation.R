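test_that("methylation binning follows the 12-bin boundary spec", {
  g <- toy_genome(c(chr1 = strrep("ACGT", 20)))
  cpgs <- find_cpgs(g)
  tr <- methylation_track(data.frame(chrom = "chr1",
                                     pos = cpgs$pos[1:6],
                                     beta = c(0, 1, 0.1, 0.95, 0.5, 0.90001)))
  tr <- validate_cpgs(tr, g)
  b <- bin_cpgs_by_methylation(tr)
  expect_equal(b$bin, c(1L, 12L, 2L, 11L, 6L, 11L))
  expect_equal(as.character(b$bin_label[1]), "[0]")
  expect_error(bin_cpgs_by_methylation(data.frame(beta = 1.5)), "outside")
  # partition is exact and exhaustive
  set.seed(1)
  tr2 <- data.frame(chrom = "chr1", pos = 1L, beta = runif(500))
  b2 <- bin_cpgs_by_methylation(tr2)
  expect_true(all(b2$bin %in% 1:12))
  expect_equal(sum(tabulate(b2$bin, 12)), 500L)
})

test_that("validate_cpgs keeps only genuine plus-strand CpGs", {
  g <- toy_genome(c(chr1 = "AACGTACGTA"))
  tr <- methylation_track(data.frame(chrom = "chr1", pos = c(3L, 7L, 5L),
                                     beta = c(0.5, 0.5, 0.5)))
  expect_warning(v <- validate_cpgs(tr, g), "1 site")
  expect_equal(v$pos, c(3L, 7L))
})

test_that("per-bin rate is 1e6 * mutations / sites, counting both CpG strands", {
  # genome of repeated ACGT: CpGs at 2, 6, 10, ...
  g <- toy_genome(c(chr1 = strrep("ACGT", 1000)))
  cpgs <- find_cpgs(g)
  n <- nrow(cpgs)
  tr <- bin_cpgs_by_methylation(
    methylation_track(data.frame(chrom = "chr1", pos = cpgs$pos,
                                 beta = rep(0.45, n))))
  # 2 mutations: one C>T at a CpG C, one G>A at the paired G of another CpG
  cat_ <- toy_catalog("chr1", c(cpgs$pos[1], cpgs$pos[2] + 1L),
                      c("C", "G"), c("T", "A"))
  prof <- mutation_rate_per_bin(list(grp = cat_), tr, g)
  expect_equal(prof$mutations[prof$bin == 6], 2)
  expect_equal(prof$rate[prof$bin == 6], 1e6 * 2 / n)
  expect_true(all(prof$mutations[prof$bin != 6] == 0))
  expect_true(all(is.na(prof$rate[prof$sites == 0])))

  # a C>T outside any binned CpG is not counted
  cat2 <- toy_catalog("chr1", 3L, "G", "A")  # G of CpG at 2 -> counted
  cat3 <- toy_catalog("chr1", 4L, "T", "C")  # not a CpG C>T
  p2 <- mutation_rate_per_bin(list(g2 = cat2, g3 = cat3), tr, g)
  expect_equal(sum(p2$mutations[p2$group == "g2"]), 1)
  expect_equal(sum(p2$mutations[p2$group == "g3"]), 0)
})

test_that("relative burden is flat at 1 for the reference and scales linearly", {
  prof <- structure(data.frame(
    group = rep(c("ref", "half"), each = 12), bin = rep(1:12, 2),
    bin_label = "x", sites = 100, mutations = 1,
    rate = c(seq(2, 24, by = 2), seq(1, 12, by = 1))),
    class = c("MethylBinProfile", "data.frame"))
  rb <- relative_burden(prof, "ref")
  expect_equal(rb$ratio[rb$group == "ref"], rep(1, 12))
  expect_equal(rb$ratio[rb$group == "half"], rep(0.5, 12))
  expect_error(relative_burden(prof, "absent"), "not in profile")
})

test_that("penta normalization collapses to the raw sum under matched composition", {
  g <- toy_genome(c(chr1 = strrep("AACGAT", 300)))  # all CpGs share AACGA
  cpgs <- find_cpgs(g)
  cat_ <- toy_catalog("chr1", cpgs$pos[1:5], rep("C", 5), rep("T", 5),
                      sample_id = paste0("s", 1:5))
  res <- penta_normalized_rate(cpgs, cat_, g, all_sites = cpgs)
  expect_identical(res$C, res$sum_N)
  expect_equal(res$percent_change, 0)
})

test_that("penta normalization reweights by f/F as the formula states", {
  # bin: 1 site in AACGA context, 3 sites in TTCGA context; supplied
  # genome weights 0.5/0.5; 10 mutations all at the AACGA site
  s <- paste0("AT", "AACGAT", strrep("TTCGAT", 3), strrep("A", 20))
  g <- toy_genome(c(chr1 = s))
  cpgs <- find_cpgs(g)
  expect_equal(nrow(cpgs), 4L)
  f <- setNames(rep(0, 64), polespectra:::nncgn_contexts())
  f[c("AACGA", "TTCGA")] <- 0.5
  aacga_pos <- cpgs$pos[1]
  cat_ <- toy_catalog("chr1", rep(aacga_pos, 10), rep("C", 10), rep("T", 10),
                      sample_id = paste0("s", 1:10))
  res <- penta_normalized_rate(cpgs, cat_, g, genome_weights = f)
  expect_equal(res$C, 10 * 0.5 / 0.25)
  expect_equal(res$sum_N, 10)
  expect_equal(res$percent_change, 100)
  # F(k)=0 with N(k)>0 is an error
  cat_bad <- toy_catalog("chr1", rep(aacga_pos, 2), rep("C", 2), rep("T", 2),
                         sample_id = c("a", "b"))
  expect_error(penta_normalized_rate(cpgs[2:4, ], cat_bad, g,
                                     genome_weights = f),
               NA)  # mutations outside the bin's sites are simply not counted
})

test_that("normalization shrinks a bin inflated by a hot context", {
  # bin enriched in TTCGA (the hot mutated context) relative to genome
  s <- paste0("CC", strrep("TTCGAC", 10), strrep("AACGAC", 40), strrep("C", 10))
  g <- toy_genome(c(chr1 = s))
  cpgs <- find_cpgs(g)
  ctx <- polespectra:::cpg_penta_contexts(cpgs, g)
  bin_sites <- rbind(cpgs[ctx == "TTCGA", ][1:8, ], cpgs[ctx == "AACGA", ][1:2, ])
  muts <- bin_sites$pos[1:6]  # all in the hot TTCGA context
  cat_ <- toy_catalog("chr1", muts, rep("C", 6), rep("T", 6),
                      sample_id = paste0("s", seq_along(muts)))
  res <- penta_normalized_rate(bin_sites, cat_, g, all_sites = cpgs)
  expect_lt(res$C, res$sum_N)
  expect_lt(res$percent_change, 0)
})

test_that("per-bin NNCGN composition sums to 1 and recovers planted excess", {
  g <- toy_genome(c(chr1 = paste0(strrep("TTCGAT", 30), strrep("AACGAT", 30), "AA")))
  cpgs <- find_cpgs(g)
  ctx <- polespectra:::cpg_penta_contexts(cpgs, g)
  # bin 1: mostly TTCGA; bin 2: mostly AACGA
  cpgs$beta <- ifelse(ctx == "TTCGA", 0.95, 0.5)
  binned <- bin_cpgs_by_methylation(methylation_track(cpgs))
  comp <- context_composition_per_bin(binned, g)
  expect_equal(unname(rowSums(comp, na.rm = TRUE)),
               rep(1, nrow(comp)))
  expect_gt(comp["11", "TTCGA"], comp["6", "TTCGA"])
})

test_that("bin mutation counts over bins sum to total CpG C>T mutations", {
  g <- toy_genome(c(chr1 = random_seq(20000, 31)))
  cpgs <- find_cpgs(g)
  set.seed(2)
  cpgs$beta <- runif(nrow(cpgs))
  binned <- bin_cpgs_by_methylation(methylation_track(cpgs))
  # mutations at 50 random CpGs (C>T) and 30 paired Gs (G>A)
  pick <- sample(nrow(cpgs), 80)
  cat_ <- toy_catalog("chr1",
                      c(cpgs$pos[pick[1:50]], cpgs$pos[pick[51:80]] + 1L),
                      c(rep("C", 50), rep("G", 30)),
                      c(rep("T", 50), rep("A", 30)))
  prof <- mutation_rate_per_bin(list(all = cat_), binned, g)
  expect_equal(sum(prof$mutations), 80)
})
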