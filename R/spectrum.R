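#' Build a context-resolved mutation spectrum
#'
#' Assigns every SNV in the catalog to one pyrimidine-collapsed channel
#' (96 channels for trinucleotide contexts, 1536 for pentanucleotide) and
#' tabulates counts and proportions over the complete channel space.
#' Records whose context window runs off a chromosome or contains `N` are
#' excluded and counted in the `n_excluded` attribute.
#'
#' @param catalog a `MutationCatalog`.
#' @param genome a `ReferenceGenome`.
#' @param k flank width (1 or 2).
#' @return a `ContextSpectrum`: list with `k`, `counts`, `proportions`
#'   (both named over the full channel space), `total`, `n_excluded` and
#'   `normalized_rates` (`NULL` until [normalize_to_genome_frequency()]).
#'   With an empty catalog, proportions are `NA` and flagged.
#' @export
build_spectrum <- function(catalog, genome, k = 1L) {
  stopifnot(k %in% c(1L, 2L))
  space <- channel_space(k)
  counts <- setNames(numeric(length(space)), space)
  n_excl <- 0L
  if (nrow(catalog) > 0L) {
    keep <- logical(nrow(catalog))
    ctx <- character(nrow(catalog))
    for (cm in unique(catalog$chrom)) {
      idx <- which(catalog$chrom == cm)
      s <- genome_seq(genome, cm)
      L <- nchar(s)
      p <- catalog$pos[idx]
      inb <- p >= 1L + k & p <= L - k
      keep[idx] <- inb
      ctx[idx][inb] <- substring(s, p[inb] - k, p[inb] + k)
    }
    hasN <- grepl("N", ctx, fixed = TRUE)
    keep <- keep & !hasN
    n_excl <- sum(!keep)
    if (any(keep)) {
      ch <- collapse_channel(catalog$ref[keep], catalog$alt[keep], ctx[keep])
      tab <- table(ch)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  total <- sum(counts)
  props <- if (total > 0) counts / total else setNames(rep(NA_real_, length(space)), space)
  structure(list(k = k, counts = counts, proportions = props,
                 normalized_rates = NULL, total = total, n_excluded = n_excl),
            class = "ContextSpectrum")
}

#' @export
print.ContextSpectrum <- function(x, ...) {
  cat(sprintf("ContextSpectrum (k=%d): %s mutations over %d channels (%d excluded)\n",
              x$k, format(x$total, big.mark = ","), length(x$counts),
              x$n_excluded))
  if (x$total > 0) {
    top <- sort(x$proportions, decreasing = TRUE)[1:5]
    cat("  top channels:",
        paste(sprintf("%s %.3f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.ContextSpectrum <- function(x, ...) {
  d <- data.frame(channel = names(x$counts), count = unname(x$counts),
                  proportion = unname(x$proportions),
                  stringsAsFactors = FALSE)
  if (!is.null(x$normalized_rates))
    d$normalized_rate <- unname(x$normalized_rates)
  d
}

#' Normalize a spectrum by genome context frequency
#'
#' Divides each channel's count by the genome-wide (or region) abundance of
#' its context, yielding per-context mutation rates that are comparable
#' across contexts of different genomic frequency.
#'
#' @param spectrum a `ContextSpectrum`.
#' @param abundance a `ContextAbundance` with matching `k`.
#' @return the spectrum with `normalized_rates` filled; channels whose
#'   context has zero abundance get `NaN` and a warning.
#' @export
normalize_to_genome_frequency <- function(spectrum, abundance) {
  if (spectrum$k != abundance$k)
    stopf("spectrum k=%d but abundance k=%d", spectrum$k, abundance$k)
  ctx <- channel_context(names(spectrum$counts))
  a <- abundance$counts[ctx]
  rates <- spectrum$counts / a
  if (any(a == 0 & spectrum$counts > 0))
    warnf("%d channel(s) have mutations in zero-abundance contexts",
          sum(a == 0 & spectrum$counts > 0))
  spectrum$normalized_rates <- setNames(as.numeric(rates),
                                        names(spectrum$counts))
  spectrum
}

#' Cosine similarity between two spectra
#'
#' @param s1,s2 `ContextSpectrum` objects with the same `k` (or bare numeric
#'   vectors of equal length).
#' @return cosine similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(s1, s2) {
  v1 <- if (inherits(s1, "ContextSpectrum")) s1$proportions else s1
  v2 <- if (inherits(s2, "ContextSpectrum")) s2$proportions else s2
  if (inherits(s1, "ContextSpectrum") && inherits(s2, "ContextSpectrum") &&
      s1$k != s2$k)
    stopf("spectra have different k")
  if (length(v1) != length(v2)) stopf("vectors differ in length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (!is.finite(n1) || !is.finite(n2) || n1 == 0 || n2 == 0)
    stopf("cosine similarity undefined for zero or missing vectors")
  sum(v1 * v2) / (n1 * n2)
}

#' Hierarchically cluster samples by spectrum similarity
#'
#' Agglomerative clustering on the distance `1 - cosine similarity` between
#' per-sample channel proportions. Deterministic given input order; ties are
#' broken by input index (the behavior of [stats::hclust()]).
#'
#' @param spectra named list of `ContextSpectrum` (names are sample labels).
#' @param k_groups optional number of flat groups to cut the tree into.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `tree` (an `hclust`), `distance` (the `dist` used) and,
#'   when `k_groups` is given, `groups` (named integer vector).
#' @export
cluster_samples <- function(spectra, k_groups = NULL, linkage = "average") {
  if (length(spectra) < 2L) stopf("need at least 2 spectra to cluster")
  ks <- vapply(spectra, function(s) s$k, integer(1))
  if (length(unique(ks)) != 1L) stopf("spectra have mixed k")
  if (is.null(names(spectra)))
    names(spectra) <- paste0("sample", seq_along(spectra))
  P <- do.call(rbind, lapply(spectra, function(s) s$proportions))
  n <- nrow(P)
  S <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- cosine_similarity(P[i, ], P[j, ])
  }
  D <- stats::as.dist(1 - S)
  attr(D, "Labels") <- names(spectra)
  tree <- stats::hclust(D, method = linkage)
  out <- list(tree = tree, distance = D)
  if (!is.null(k_groups)) out$groups <- stats::cutree(tree, k = k_groups)
  out
}

#' Export a sample-clustering tree as a Newick string
#'
#' @param clustering result of [cluster_samples()].
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to a file.
#' @export
cluster_newick <- function(clustering, path = NULL) {
  phy <- ape::as.phylo(clustering$tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Fit non-negative signature contributions to a spectrum
#'
#' Decomposes a 96-channel spectrum as a non-negative combination of
#' signature columns (e.g. COSMIC signatures, supplied by the user) via
#' non-negative least squares on the proportion vector.
#'
#' @param spectrum a `ContextSpectrum` with `k = 1`.
#' @param sigs numeric matrix (96 rows, one column per signature; columns
#'   sum to 1) with rownames matching [channel_space()] order, or a named
#'   list of such vectors.
#' @return list with `weights` (raw NNLS coefficients), `contributions`
#'   (weights normalized to sum 1; all zero if the fit is null) and
#'   `residual` (Euclidean norm of the unexplained remainder).
#' @export
fit_signature_contributions <- function(spectrum, sigs) {
  if (spectrum$k != 1L) stopf("signature fitting is defined for k = 1")
  if (is.list(sigs) && !is.matrix(sigs)) sigs <- do.call(cbind, sigs)
  sigs <- as.matrix(sigs)
  if (ncol(sigs) == 0L || nrow(sigs) != 96L)
    stopf("signature matrix must be 96 x m with m >= 1")
  if (any(sigs < 0)) stopf("signature entries must be non-negative")
  if (!is.null(rownames(sigs))) {
    if (!setequal(rownames(sigs), names(spectrum$proportions)))
      stopf("signature rownames do not match the channel space")
    sigs <- sigs[names(spectrum$proportions), , drop = FALSE]
  }
  b <- spectrum$proportions
  if (anyNA(b)) stopf("spectrum proportions undefined (empty catalog)")
  fit <- pracma::lsqnonneg(sigs, as.numeric(b))
  w <- setNames(fit$x, colnames(sigs))
  contrib <- if (sum(w) > 0) w / sum(w) else w
  list(weights = w, contributions = contrib,
       residual = sqrt(sum((b - as.numeric(sigs %*% w))^2)))
}
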