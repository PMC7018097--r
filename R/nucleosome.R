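#' Load a nucleosome minor-groove phase map
#'
#' A phase map labels every dyad offset in `-73..+73` as `minor_in` (minor
#' groove facing the histone core), `minor_out` (facing away) or
#' `unassigned`. The packaged default
#' (`minor_groove_phase_synthetic.tsv`) is a synthetic approximation built
#' from the canonical ~10.3-bp helical periodicity of nucleosomal DNA
#' (3-bp stretches centered at half-integer and integer helical turns from
#' the dyad); replace it with a measured table via `path` for real analyses.
#'
#' @param path TSV with columns `offset`, `phase`; `NULL` loads the packaged
#'   synthetic default.
#' @return data.frame with `offset` (integer) and `phase` (character).
#' @export
load_phase_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "minor_groove_phase_synthetic.tsv",
                        package = "polespectra", mustWork = TRUE)
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("offset", "phase") %in% names(pm)))
    stopf("phase map needs 'offset' and 'phase' columns")
  if (any(abs(pm$offset) > 73L))
    stopf("phase map offsets must lie in -73..+73")
  pm
}

#' Genomic position sets per minor-groove phase
#'
#' Expands each dyad over the phase map: every covered position is labeled
#' by its offset's phase, once per dyad occurrence (overlapping dyad
#' footprints contribute a position once per dyad, consistent with stacked
#' profiling).
#'
#' @param dyads data.frame with `chrom`, `pos` (dyad centers, 1-based).
#' @param phase_map output of [load_phase_map()].
#' @return named list of data.frames (`chrom`, `pos`), one per phase label
#'   other than `unassigned`.
#' @export
assign_minor_groove_phase <- function(dyads, phase_map = load_phase_map()) {
  if (nrow(dyads) == 0L) stopf("empty dyad set")
  phases <- setdiff(unique(phase_map$phase), "unassigned")
  out <- lapply(phases, function(ph) {
    off <- phase_map$offset[phase_map$phase == ph]
    data.frame(chrom = rep(dyads$chrom, each = length(off)),
               pos = rep(dyads$pos, each = length(off)) + off,
               stringsAsFactors = FALSE)
  })
  names(out) <- phases
  out
}

#' Observed vs context-expected mutation rate by minor-groove phase
#'
#' Computes the stacked observed and context-expected mutation profile over
#' the ±73-bp dyad territory (the expected model is the same `f = M/A`
#' machinery used for CTCF windows), aggregates both by minor-groove phase,
#' and reports the relative increase `observed/expected - 1` per phase.
#' A positive minor-in relative increase is the nucleosome periodicity
#' signal.
#'
#' @param catalog a `MutationCatalog`.
#' @param dyads data.frame with `chrom`, `pos`.
#' @param genome a `ReferenceGenome`.
#' @param phase_map output of [load_phase_map()].
#' @param k context flank width for the expected model (default
#'   trinucleotide).
#' @return a `PeriodicityResult`: data.frame with `phase`, `bp`, `observed`,
#'   `expected`, `observed_rate`, `expected_rate`, `relative_increase`.
#' @export
periodicity_rates <- function(catalog, dyads, genome,
                              phase_map = load_phase_map(), k = 1L) {
  if (nrow(dyads) == 0L) stopf("empty dyad set")
  anchors <- anchor_set(dyads$chrom, dyads$pos, "+", flank = 73L,
                        kind = "dyad")
  prof <- expected_profile(catalog, anchors, genome, k = k)
  phase_of <- setNames(phase_map$phase, phase_map$offset)
  ph <- phase_of[as.character(prof$offset)]
  ph[is.na(ph)] <- "unassigned"
  phases <- setdiff(unique(phase_map$phase), "unassigned")
  res <- lapply(phases, function(p) {
    sel <- ph == p
    bp <- sum(sel) * nrow(dyads)
    obs <- sum(prof$observed[sel])
    exp_ <- sum(prof$expected[sel])
    data.frame(phase = p, bp = bp, observed = obs, expected = exp_,
               observed_rate = obs / bp, expected_rate = exp_ / bp,
               relative_increase = if (exp_ > 0) obs / exp_ - 1 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("PeriodicityResult", "data.frame"))
}
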