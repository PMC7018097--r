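#' Find recurrent mutation hotspots
#'
#' A hotspot is an identical substitution (chrom, pos, ref, alt) carried by
#' at least `min_recurrence` distinct samples; a sample mutated twice at a
#' site counts once.
#'
#' @param catalog a `MutationCatalog` covering the cohort.
#' @param min_recurrence minimum number of distinct carrying samples
#'   (default 20).
#' @return a `HotspotTable`: data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `recurrence`, sorted by decreasing recurrence.
#' @export
find_hotspots <- function(catalog, min_recurrence = 20L) {
  if (nrow(catalog) == 0L) stopf("empty cohort catalog")
  key <- paste(catalog$chrom, catalog$pos, catalog$ref, catalog$alt, sep = ":")
  u <- !duplicated(paste(catalog$sample_id, key))
  rec <- table(key[u])
  keep <- rec[rec >= min_recurrence]
  if (length(keep) == 0L)
    return(structure(data.frame(chrom = character(0), pos = integer(0),
                                ref = character(0), alt = character(0),
                                recurrence = integer(0)),
                     class = c("HotspotTable", "data.frame")))
  parts <- strsplit(names(keep), ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    ref = vapply(parts, `[`, "", 3L),
                    alt = vapply(parts, `[`, "", 4L),
                    recurrence = as.integer(keep),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$recurrence, out$chrom, out$pos), ]
  rownames(out) <- NULL
  structure(out, class = c("HotspotTable", "data.frame"))
}

#' Group-by-carriage contingency table for one hotspot
#'
#' @param groups named character vector mapping every cohort sample to its
#'   group label (labels are caller-supplied; classification is upstream
#'   input).
#' @param hotspot one-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param catalog the cohort `MutationCatalog`. Samples in the catalog but
#'   not in `groups` are an error.
#' @return a `HotspotContingency`: data.frame with `group`, `carriers`,
#'   `non_carriers` in first-appearance order of `groups`.
#' @export
contingency <- function(groups, hotspot, catalog) {
  if (is.null(names(groups))) stopf("groups must be named by sample")
  unlabeled <- setdiff(unique(catalog$sample_id), names(groups))
  if (length(unlabeled))
    stopf("unlabeled sample(s): %s", paste(utils::head(unlabeled, 5),
                                           collapse = ", "))
  hit <- catalog$chrom == hotspot$chrom & catalog$pos == hotspot$pos &
    catalog$ref == hotspot$ref & catalog$alt == hotspot$alt
  carriers <- unique(catalog$sample_id[hit])
  glev <- unique(unname(groups))
  a <- vapply(glev, function(g)
    sum(names(groups)[groups == g] %in% carriers), numeric(1))
  sizes <- vapply(glev, function(g) sum(groups == g), numeric(1))
  hotspot_contingency(glev, a, sizes)
}

#' Construct a HotspotContingency from counts
#'
#' @param group group labels.
#' @param carriers carrier count per group.
#' @param sizes total samples per group.
#' @return a `HotspotContingency`.
#' @export
hotspot_contingency <- function(group, carriers, sizes) {
  if (any(carriers > sizes) || any(carriers < 0))
    stopf("carriers must lie in [0, group size]")
  structure(data.frame(group = group, carriers = carriers,
                       non_carriers = sizes - carriers,
                       stringsAsFactors = FALSE),
            class = c("HotspotContingency", "data.frame"))
}

#' Per-group carriage percentages
#'
#' @param table a `HotspotContingency`.
#' @return named numeric of `100 * carriers / group size` (NA for empty
#'   groups).
#' @export
group_proportions <- function(table) {
  n <- table$carriers + table$non_carriers
  setNames(ifelse(n > 0, 100 * table$carriers / n, NA_real_), table$group)
}

# Two-sided exact p for every value of the first cell given fixed margins
# (r1, r2 row totals; c1 first-column total), probability-mass convention
# with relative tolerance 1 + 1e-7. Returns the support and p per support
# point.
fisher_p_support <- function(r1, r2, c1) {
  N <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  supp <- lo:hi
  pr <- stats::dhyper(supp, c1, N - c1, r1)
  p <- vapply(seq_along(supp), function(i)
    sum(pr[pr <= pr[i] * (1 + 1e-7)]), numeric(1))
  list(support = supp, prob = pr, p = pmin(p, 1))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test with the standard two-sided probability-mass
#' convention: the p-value sums the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (within a relative tolerance of `1e-7`). The reported
#' odds ratio is the sample cross-product ratio `(a*d)/(b*c)`, `Inf` when
#' `b*c = 0` with `a*d > 0`. A table with an all-zero margin has `p = 1` by
#' convention.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   (`rbind(c(a, b), c(c, d))`).
#' @return list with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stopf("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stopf("table entries must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    return(list(odds_ratio = NA_real_, p_value = 1))
  fp <- fisher_p_support(a + b, c + d, a + c)
  p <- fp$p[match(a, fp$support)]
  or <- if (b * c == 0) { if (a * d > 0) Inf else NA_real_ }
        else (a * d) / (b * c)
  list(odds_ratio = or, p_value = p)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment `q_i = min_{j >= rank(i)} p_(j) * m / j`,
#' preserving input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Test hotspot enrichment across sample groups
#'
#' For every hotspot, builds the group-by-carriage contingency table and
#' tests 2x2 sub-tables — every unordered pair of groups and every group
#' versus the rest — with [fisher_exact()]. Which 2x2 a study intends is
#' often ambiguous, so all groupings are reported explicitly; q-values are
#' BH-adjusted across hotspots within each grouping.
#'
#' @param catalog cohort `MutationCatalog`.
#' @param groups named character vector mapping sample to group.
#' @param hotspots a `HotspotTable` (or data.frame with `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param comparisons `"pairwise"`, `"one_vs_rest"`, or both (default).
#' @return an `EnrichmentResult`: data.frame with `hotspot`, `grouping`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `q`.
#' @export
hotspot_enrichment <- function(catalog, groups, hotspots,
                               comparisons = c("pairwise", "one_vs_rest")) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  if (nrow(hotspots) == 0L) stopf("no hotspots to test")
  res <- list()
  for (i in seq_len(nrow(hotspots))) {
    hs <- hotspots[i, ]
    label <- sprintf("%s:%d %s>%s", hs$chrom, hs$pos, hs$ref, hs$alt)
    ct <- contingency(groups, hs, catalog)
    tabs <- list()
    if ("pairwise" %in% comparisons && nrow(ct) >= 2L) {
      for (g1 in seq_len(nrow(ct) - 1L)) for (g2 in (g1 + 1L):nrow(ct)) {
        nm <- sprintf("%s vs %s", ct$group[g1], ct$group[g2])
        tabs[[nm]] <- c(ct$carriers[g1], ct$non_carriers[g1],
                        ct$carriers[g2], ct$non_carriers[g2])
      }
    }
    if ("one_vs_rest" %in% comparisons && nrow(ct) >= 2L) {
      for (g1 in seq_len(nrow(ct))) {
        nm <- sprintf("%s vs rest", ct$group[g1])
        tabs[[nm]] <- c(ct$carriers[g1], ct$non_carriers[g1],
                        sum(ct$carriers[-g1]), sum(ct$non_carriers[-g1]))
      }
    }
    for (nm in names(tabs)) {
      tb <- tabs[[nm]]
      ft <- fisher_exact(rbind(tb[1:2], tb[3:4]))
      res[[length(res) + 1L]] <- data.frame(
        hotspot = label, grouping = nm, a = tb[1], b = tb[2], c = tb[3],
        d = tb[4], odds_ratio = ft$odds_ratio, p = ft$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  for (g in unique(out$grouping)) {
    sel <- out$grouping == g
    out$q[sel] <- bh_fdr(out$p[sel])
  }
  rownames(out) <- NULL
  structure(out, class = c("EnrichmentResult", "data.frame"))
}
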