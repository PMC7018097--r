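---
title: "Methods: models, parameters and design choices in polespectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in polespectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models and conventions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the choices made where the design
was genuinely open.

# Mutation channels and spectra

Every somatic single-base substitution is assigned to a *pyrimidine-collapsed
channel*: the substitution is stated with a C or T as the mutated base,
reverse-complementing the context when the reference base is a purine. With
one flanking base on each side this yields 6 substitution types × 16 contexts
= 96 channels; with two flanking bases, 1536. Channel order is fixed
lexicographically by (substitution type, context), with the types ordered
C>A, C>G, C>T, T>A, T>C, T>G, so written output is bit-stable across runs.

Records whose window runs off a chromosome or contains `N` are excluded from
spectra and counted in an `n_excluded` field; `N`-containing contexts are
likewise excluded from abundance denominators. No pseudocounts or smoothing
are applied anywhere: an empty catalog yields undefined (NA) proportions,
flagged rather than fabricated.

*Genome-frequency normalization* divides each channel count by the
genome-wide abundance of its context, counted once per genomic position over
both strands (pyrimidine-collapsed). This converts a spectrum shaped by
genome composition into per-context mutation rates.

*Clustering* of per-sample spectra uses the distance 1 − cosine similarity on
proportion vectors with average linkage. Neither the distance nor the linkage
is forced by the analysis itself; cosine is the similarity the spectrum
comparisons already use, and average linkage is the common default for
signature work. Ties are broken by input index (the `stats::hclust`
behavior), so the tree is deterministic given input order, and flat groups
from `cutree` are invariant to input permutation. Spectra are clustered as
per-sample *proportions* (not counts), so hypermutated samples do not
dominate; group-average spectra are computed after clustering.

*Signature fitting* decomposes a 96-channel proportion vector onto
user-supplied signature columns by non-negative least squares
(`pracma::lsqnonneg`), reporting raw coefficients, coefficients normalized to
sum 1, and the residual norm. The signature matrix (e.g. COSMIC) is an input,
never bundled.

# Methylation and CpG mutability

CpG sites (validated as plus-strand `CG` against the genome) are stratified
into 12 bins: the degenerate bins `[0]` and `[1]` and the half-open deciles
`(0, 0.1], …, (0.9, 1.0)`. Keeping fully unmethylated and fully methylated
sites separate matters because both are abundant in WGBS data and sit at the
extremes of the mutability gradient.

Mutation burden per bin counts C>T at binned CpG cytosines on *both* strands:
a G>A at the paired guanine is the same deamination event read on the minus
strand and collapses onto the CpG unit. Rates are `1e6 × mutations / sites`
(mut/Mb). Per-group rates pool mutations across samples by default; a
`per_sample` mode averages per-sample rates instead, for cohorts with very
uneven mutation burdens. An optional coverage filter excludes low-coverage
CpGs before binning.

*Relative burden* divides each group's per-bin rate by a reference group's.
If two groups share the same methylation dependence and differ only in total
burden, the ratio is flat across bins — the regression slope of ratio on bin
is statistically zero. This is the inference that separates "more CpG
mutations because of methylation" from "more CpG mutations because of
sequence context".

*Pentanucleotide composition normalization* re-weights a bin's per-context
mutation counts by genome-to-bin composition ratios,
`C = Σ_k N(k) · f(k)/F(k)` over the 64 `NNCGN` contexts (three free
positions). When the bin's composition matches the genome-wide composition
the formula is exactly the identity `C = ΣN`; a bin over-enriched in a hot
context shrinks. A context that is mutated but absent from the bin
(`F(k) = 0`, `N(k) > 0`) is an error, not a silent skip. The related
`ttcga_fraction` statistic reports distinct mutated TTCGA sites per
`NN[C>T]GN` mutation — the quantity that links a group's context preference
to its chance of hitting a TT[C>T]GA driver site.

# Expected-mutation background at anchored windows

Profiles around CTCF motifs, TSSs and nucleosome dyads stack fixed-width
windows on anchor points, flipping minus-strand anchors so offsets run 5'→3'.
A mutation under two overlapping windows is counted once per window at each
window's own offset — stacking semantics, chosen so every window remains a
complete, self-contained observation.

The expected model asks: *given each window's own mutation count, where
within the window should those mutations fall if context were the only
driver?* Per-context frequency `f = M/A` is estimated over the stacked
windows themselves (mutated-context counts over context abundance), each
window's positions are weighted `W_p = f_p / Σ_q f_q`, and its count `m` is
redistributed as `m·W_p`. Summing over windows gives the stacked expected
profile, and by construction `Σ_p expected = Σ m` to machine precision — the
conservation identity that the test suite checks to 1e-9 over a thousand
random windows. Positions with unknown context (N) receive zero weight.

Context width for `f` defaults to trinucleotide, matching the 96-channel
framework; pentanucleotide widths are available but need far more data per
window set to estimate 512 context frequencies stably.

When comparing observed and expected in a region (e.g. ±110 bp of CTCF
centers), the paired rank test is applied to 10-bp bin sums rather than raw
per-offset counts: single-offset counts are small, discrete and skewed, which
miscalibrates a signed-rank test even under the null, while 10-bp sums are
large enough to be comparable. Calibration is verified by simulation: under
context-only generation the test is non-significant at the 5% level in well
over 90% of seeded replicates.

TSS profiles are reported per focus channel (defaults: the signature-10
peaks C>A at TCT, C>T at TCG, T>G at TTT), normalized by the per-offset count
of the channel's context across windows; an offset where the context never
occurs is missing, not zero, so depleted sequence is not confused with
depleted mutability.

# Gene parts, replication and nucleosomes

Each gene model is decomposed into 5'UTR, first/middle/last coding exons,
first/middle/last introns and 3'UTR (strand-aware; all non-first, non-last
elements are pooled as "middle"; a two-exon gene's single intron is treated
as its first intron). Every contiguous sequence of a part shorter than 20 bp
is discarded; the rest are each split into 20 near-equal bins (widths within
1 bp, bin 1 at the 5' end) and pooled by bin index as mut/Mb. Genes with
fewer than three exons contribute only the parts they define.

Replication direction is the sign of the finite-difference derivative of the
timing profile, after a running mean over a 100 kb window (default;
configurable, since the appropriate smoothing depends on the source
profile's resolution). Derivatives below 1e-6 units/bp in magnitude are
"undefined" and excluded from strand counts. Strand asymmetry for a mutation
type is `A = log2(N/n)` with `N` the pyrimidine-stated count and `n` its
complement; `A` is antisymmetric under swapping and is reported as undefined
when either count is zero (a `pseudocount` argument exists but defaults to
off — undefined beats inflated). Timing values are binned into five classes
with the late-to-early boundaries
`[-4.51712, 30.8225), [30.8225, 44.19), [44.19, 55.8262),
[55.8262, 63.7717), [63.7717, 80.6964]` shipped as the default configuration
(half-open, last bin closed).

Nucleosome analysis labels each dyad offset in ±73 bp as minor-groove-in,
minor-groove-out or unassigned via a phase-map config file. The packaged
table (`minor_groove_phase_synthetic.tsv`) is a *synthetic* approximation
derived from the canonical ~10.3-bp helical periodicity (3-bp stretches at
half-integer helical turns face the histones, integer turns face away); it
is explicitly a stand-in that users analyzing real MNase data should replace
with a measured table. Observed and expected rates per phase reuse the
windowed expected model above; the headline quantity is
`relative increase = observed/expected − 1` per phase.

# Hotspot enrichment

A hotspot is an identical substitution carried by at least 20 distinct
samples (the default recurrence threshold; carriage counts once per sample).
Group labels are caller-supplied input: classifying samples into
P286R/V411L/other/wild-type involves upstream evidence (driver calls,
spectrum clustering) that the package supports but does not decide. Because
a multi-group table admits several 2×2 readings, `hotspot_enrichment` tests
*every* pairwise and one-vs-rest grouping and reports each explicitly with
its cross-product odds ratio, exact two-sided p (probability-mass
convention, relative tolerance 1e-7 — the dominant convention in statistical
software) and BH q-value adjusted across hotspots within a grouping.
Degenerate tables (an all-zero margin) have p = 1 by convention. The exact
test is verified against exhaustive hypergeometric enumeration on every 2×2
table with N ≤ 60 and against `stats::fisher.test` on random tables.

# The synthetic-data generator

The generator exists so that every analysis stage has inputs whose truth is
known. It emulates, at reduced scale, the statistical structure the analyses
assume:

* **Genome** — i.i.d. bases at 42% GC with Poisson-placed CpG islands
  (500 bp at 70% GC, one per 50 kb), giving a CpG-enriched backdrop for
  methylation analyses. Default scale 5 Mb (tests and the acceptance script
  use 0.2–2 Mb so the whole suite runs in about a minute; sizes are stated
  with each computed quantity).
* **Methylation** — per-CpG beta from a bimodal mixture: spikes at 0 (8%)
  and 1 (12%), a dominant high Beta(5, 1.5) body and a minority Beta(1.5, 5)
  low body (25% of body draws). The mixture populates all 12 bins including
  the degenerate ones, mimicking the bimodal shape of somatic-tissue WGBS;
  optional low-methylation regions model promoters.
* **Landscape** — a sinusoidal timing profile spanning the full five-bin
  range, so every timing bin is populated and left/right breakpoints are
  analytically known; gene models with five exons and all parts ≥ 20 bp;
  Poisson-placed motifs; jittered ~1 kb-spaced dyads.
* **Mutations** — sites are sampled *without replacement* with per-site,
  per-allele weight `signature[channel] / abundance(context)`, so the
  expected channel distribution of a catalog equals the signature regardless
  of genome composition (the sampler is the inverse of spectrum building).
  Multiplicative modifiers plant effects on top: methylation slope
  (C>T odds at a CpG scaled by β, both strands), strand bias by replication
  direction, region factors (CTCF/exon depletion), position factors
  (minor-groove-in excess), and a recurrent hotspot planted at a TTCGA site
  with per-group Bernoulli carriage. Built-in group signatures
  (`pole_signature`) encode the archetypes: a C>A-at-TCT-dominated P286R, a
  C>T-at-CpG-shifted V411L, an intermediate Other-Exo and a CpG-C>T MSS
  background.
* **Cohorts** — per-sample catalogs under group signatures (default 3 groups
  × 5 samples × 20,000 mutations); registry-scale carriage (16/31/7298-sized
  groups) is simulated at the Bernoulli-carriage level, since genomes for
  7,000 samples would add nothing to the contingency arithmetic being
  exercised.

Everything is deterministic per seed (base R Mersenne-Twister; no
iteration-order dependence).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: real chromatin organization and its correlation
structure (methylation, timing, genes and motifs are placed independently),
selection on drivers (hotspot carriage is a coin flip, not an evolutionary
outcome), sequencing artifacts and calling error, copy number, indels, and
inter-patient heterogeneity beyond the group signature. Recovery of a
planted effect demonstrates that the estimator measures what it claims to
measure, not that the effect has any particular size in tumors.

# Numerical choices and degenerate inputs

* Coordinates: 1-based inclusive for mutations and anchor centers (MAF/VCF
  convention); 0-based half-open for intervals (BED convention). Converters
  sit only at file boundaries.
* Multi-allelic VCF rows are dropped as non-SNV (keeps the channel space
  well-defined); duplicate (sample, chrom, pos) records are deduplicated
  keeping the first; both removals are counted and reported.
* Reference-mismatch against the genome warns and drops by default
  (`on_mismatch = "error"` available) — synthetic and heterogeneous real
  inputs differ in how strictly they can be held to a reference.
* Division-by-zero paths are all explicit: zero-abundance contexts,
  empty bins, zero reference rates and zero asymmetry counts are NA/flagged,
  never silently zero.
* Without-replacement sampling slightly thins the highest-weight channels
  when the requested mutation count approaches the number of available
  sites in a hot context; effect-recovery checks therefore run at genome
  sizes where per-site inclusion probabilities are small.

# Known limitations

* The in-memory genome representation suits the megabase-scale synthetic
  genomes and targeted real analyses; whole-human-genome work would want an
  indexed FASTA backend behind the same `ReferenceGenome` surface.
* The expected-window model estimates `f` from the same windows it predicts
  — it is a composition-adjusted null, not an independent background, which
  is why its conservation property is exact and its use is comparative
  (observed vs expected shape), not absolute.
* The packaged minor-groove phase table is synthetic (above).
* Sample classification into POLE-mutant groups is input, not inference;
  the clustering helper assists but does not decide it.
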