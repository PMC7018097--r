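test_that("build_spectrum assigns SNVs to channels with proportions summing to 1", {
  g <- toy_genome(c(chr1 = "AACGTT"))
  sp <- build_spectrum(toy_catalog("chr1", 3L, "C", "T"), g, k = 1)
  expect_equal(unname(sp$proportions[["A[C>T]G"]]), 1)
  expect_equal(sum(sp$proportions), 1)
  expect_equal(sp$total, 1)

  # two mutations in different channels -> 0.5 / 0.5
  g2 <- toy_genome(c(chr1 = "ACAATTTA"))
  cat2 <- toy_catalog("chr1", c(2L, 6L), c("C", "T"), c("A", "G"))
  sp2 <- build_spectrum(cat2, g2, k = 1)
  expect_equal(unname(sp2$proportions[["A[C>A]A"]]), 0.5)
  expect_equal(unname(sp2$proportions[["T[T>G]T"]]), 0.5)

  # boundary records are excluded and logged
  cat3 <- toy_catalog("chr1", c(1L, 2L), c("A", "C"), c("G", "A"))
  sp3 <- build_spectrum(cat3, g2, k = 1)
  expect_equal(sp3$n_excluded, 1L)
  expect_equal(sp3$total, 1)
})

test_that("spectrum is additive across per-sample catalogs", {
  g <- toy_genome(c(chr1 = random_seq(3000, 9)))
  sig <- pole_signature("Other-Exo")
  c1 <- simulate_mutations(g, sig, 150, sample_id = "a", seed = 1)
  c2 <- simulate_mutations(g, sig, 150, sample_id = "b", seed = 2)
  combined <- suppressMessages(mutation_catalog(rbind(as.data.frame(c1),
                                                      as.data.frame(c2))))
  s_all <- build_spectrum(combined, g)
  s1 <- build_spectrum(c1, g); s2 <- build_spectrum(c2, g)
  expect_equal(s_all$counts, s1$counts + s2$counts)
})

test_that("genome-frequency normalization divides counts by context abundance", {
  # engineered toy: rare context carries most mutations, so the normalized
  # ranking flips relative to raw proportions
  s <- paste0(strrep("ACG", 40), "TTCTT", strrep("ACG", 5))
  g <- toy_genome(c(chr1 = s))
  ab <- count_context_abundance(g, k = 1)
  tct_pos <- as.integer(regexpr("TCT", s)) + 1L
  acg_pos <- c(2L, 5L, 8L)
  cat_ <- toy_catalog("chr1",
                      c(rep(tct_pos, 4), acg_pos),
                      c(rep("C", 4), rep("C", 3)),
                      c(rep("A", 4), rep("T", 3)),
                      sample_id = c(paste0("s", 1:4), rep("s1", 3)))
  sp <- normalize_to_genome_frequency(build_spectrum(cat_, g), ab)
  expect_equal(unname(sp$normalized_rates[["T[C>A]T"]]),
               4 / ab$counts[["TCT"]], ignore_attr = TRUE)
  expect_equal(unname(sp$normalized_rates[["A[C>T]G"]]),
               3 / ab$counts[["ACG"]], ignore_attr = TRUE)
  # raw: ACG channel < TCA channel? counts 3 < 4 already; flip needs rare
  # context with fewer mutations but higher rate:
  expect_gt(sp$normalized_rates[["T[C>A]T"]], sp$normalized_rates[["A[C>T]G"]])
  expect_error(normalize_to_genome_frequency(build_spectrum(cat_, g, k = 1),
                                             count_context_abundance(g, k = 2)),
               "k=")
})

test_that("cosine similarity has its closed-form values", {
  v1 <- c(1, 1, rep(0, 94)); v2 <- c(1, 0, rep(0, 94))
  expect_equal(cosine_similarity(v1, v2), 1 / sqrt(2))
  expect_equal(cosine_similarity(v1, v1), 1)
  expect_equal(cosine_similarity(c(1, 0, rep(0, 94)), c(0, 1, rep(0, 94))), 0)
  expect_error(cosine_similarity(rep(0, 96), v1), "undefined")
})

test_that("clustering recovers planted archetypes and is order-invariant", {
  g <- toy_genome(c(chr1 = random_seq(2e5, 21)))
  variants <- c("P286R", "V411L", "MSS")
  spectra <- list()
  truth <- character(0)
  for (v in variants) for (j in 1:3) {
    id <- paste0(v, "_", j)
    cat_ <- simulate_mutations(g, pole_signature(v), 10000, sample_id = id,
                               seed = match(v, variants) * 10 + j)
    spectra[[id]] <- build_spectrum(cat_, g)
    truth[id] <- v
  }
  cl <- cluster_samples(spectra, k_groups = 3)
  # planted groups are recovered exactly (up to label permutation)
  expect_equal(length(unique(cl$groups)), 3L)
  for (v in variants)
    expect_equal(length(unique(cl$groups[truth == v])), 1L)
  expect_gt(min(table(cl$groups)), 2L)

  # permuting input order leaves the flat grouping identical
  perm <- rev(seq_along(spectra))
  cl2 <- cluster_samples(spectra[perm], k_groups = 3)
  for (v in variants)
    expect_equal(length(unique(cl2$groups[truth[perm] == v])), 1L)
  expect_error(cluster_samples(spectra[1]), "at least 2")
})

test_that("two identical spectra merge before an orthogonal one", {
  p1 <- setNames(c(1, rep(0, 95)), channel_space(1))
  p2 <- setNames(c(0, 1, rep(0, 94)), channel_space(1))
  mk <- function(p) structure(list(k = 1L, counts = p * 100, proportions = p,
                                   total = 100, n_excluded = 0L),
                              class = "ContextSpectrum")
  cl <- cluster_samples(list(a = mk(p1), b = mk(p1), c = mk(p2)), k_groups = 2)
  expect_equal(unname(cl$groups["a"]), unname(cl$groups["b"]))
  expect_false(cl$groups[["a"]] == cl$groups[["c"]])
  # Newick export round-trips through a tree parser with the same tips
  nwk <- cluster_newick(cl)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
})

test_that("NNLS signature fitting recovers exact mixtures", {
  space <- channel_space(1)
  sigA <- setNames(rep(0, 96), space); sigA[1:48] <- 1 / 48
  sigB <- setNames(rep(0, 96), space); sigB[49:96] <- 1 / 96 * 2
  mk <- function(p) structure(list(k = 1L, counts = p * 1000, proportions = p,
                                   total = 1000, n_excluded = 0L),
                              class = "ContextSpectrum")
  S <- cbind(A = sigA, B = sigB)

  fit1 <- fit_signature_contributions(mk(sigA), S)
  expect_equal(unname(fit1$contributions), c(1, 0), tolerance = 1e-10)

  mix <- 0.7 * sigA + 0.3 * sigB
  fit2 <- fit_signature_contributions(mk(mix), S)
  expect_equal(unname(fit2$weights), c(0.7, 0.3), tolerance = 1e-8)
  expect_lt(fit2$residual, 1e-10)

  # spectrum orthogonal to all signatures -> zero weights, residual = |b|
  orth <- setNames(rep(0, 96), space); orth[1] <- 1
  S2 <- cbind(B = sigB)
  fit3 <- fit_signature_contributions(mk(orth), S2)
  expect_equal(unname(fit3$weights), 0)
  expect_equal(fit3$residual, 1)
  expect_error(fit_signature_contributions(mk(sigA), matrix(numeric(0), 96, 0)),
               "96 x m")
})
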