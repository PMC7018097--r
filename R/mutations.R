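#' Construct a mutation catalog
#'
#' A `MutationCatalog` is a data.frame of single-base somatic substitutions
#' with columns `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`.
#' Non-SNV rows (multi-base or non-ACGT alleles) are dropped with a message;
#' duplicate (sample, chrom, pos) entries are deduplicated keeping the first.
#'
#' @param df data.frame with the five columns above.
#' @return a `MutationCatalog` (data.frame subclass) with attributes
#'   `n_non_snv` and `n_duplicates` recording dropped rows.
#' @export
mutation_catalog <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  n_non_snv <- sum(!snv)
  if (n_non_snv > 0)
    message(sprintf("%d non-SNV row(s) dropped", n_non_snv))
  df <- df[snv, , drop = FALSE]
  dup <- duplicated(df[c("sample_id", "chrom", "pos")])
  n_dup <- sum(dup)
  if (n_dup > 0)
    message(sprintf("%d duplicate (sample, chrom, pos) row(s) deduplicated", n_dup))
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("MutationCatalog", "data.frame"),
            n_non_snv = n_non_snv, n_duplicates = n_dup)
}

#' Read somatic mutations from a MAF-like TSV or minimal VCF
#'
#' The MAF-like dialect expects columns `Tumor_Sample_Barcode`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`. The minimal VCF
#' dialect reads CHROM/POS/REF/ALT and takes the sample from `sample_id`
#' (VCF carries no tumor barcode in its fixed fields); multi-allelic ALT rows
#' are dropped as non-SNV.
#'
#' @param path file path.
#' @param dialect `"maf_like_tsv"` or `"vcf_minimal"`.
#' @param sample_id sample name used for every record of a VCF (ignored for
#'   MAF input).
#' @return a `MutationCatalog`.
#' @export
read_mutations <- function(path, dialect = c("maf_like_tsv", "vcf_minimal"),
                           sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "maf_like_tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#", check.names = FALSE)
    need <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
              "Reference_Allele", "Tumor_Seq_Allele2")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stopf("MAF-like file missing column(s): %s", paste(miss, collapse = ", "))
    out <- data.frame(sample_id = df$Tumor_Sample_Barcode,
                      chrom = df$Chromosome,
                      pos = df$Start_Position,
                      ref = df$Reference_Allele,
                      alt = df$Tumor_Seq_Allele2,
                      stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    if (length(ln) == 0L) stopf("VCF '%s' has no records", path)
    parts <- strsplit(ln, "\t", fixed = TRUE)
    if (any(lengths(parts) < 5L)) stopf("VCF rows need at least 5 fields")
    if (is.null(sample_id)) sample_id <- "sample1"
    out <- data.frame(sample_id = sample_id,
                      chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      ref = vapply(parts, `[`, "", 4L),
                      alt = vapply(parts, `[`, "", 5L),
                      stringsAsFactors = FALSE)
  }
  mutation_catalog(out)
}

#' Validate a catalog against a reference genome
#'
#' Checks that each record's `ref` matches the genome base at its position.
#' Records outside chromosome bounds or mismatching the genome are either
#' dropped with a warning (default, robust for heterogeneous inputs) or
#' raised as an error.
#'
#' @param catalog a `MutationCatalog`.
#' @param genome a `ReferenceGenome`.
#' @param on_mismatch `"drop"` (warn and remove) or `"error"`.
#' @return the validated `MutationCatalog`.
#' @export
validate_catalog <- function(catalog, genome, on_mismatch = c("drop", "error")) {
  on_mismatch <- match.arg(on_mismatch)
  if (nrow(catalog) == 0L) return(catalog)
  ok <- logical(nrow(catalog))
  for (cm in unique(catalog$chrom)) {
    idx <- which(catalog$chrom == cm)
    if (!cm %in% names(genome$sequences)) { ok[idx] <- FALSE; next }
    s <- genome$sequences[[cm]]
    p <- catalog$pos[idx]
    inb <- p >= 1L & p <= nchar(s)
    ok[idx] <- inb
    ok[idx][inb] <- substring(s, p[inb], p[inb]) == catalog$ref[idx][inb]
  }
  if (any(!ok)) {
    msg <- sprintf("%d record(s) mismatch the reference genome", sum(!ok))
    if (on_mismatch == "error") stopf("%s", msg)
    warnf("%s; dropped", msg)
    catalog <- catalog[ok, , drop = FALSE]
    rownames(catalog) <- NULL
  }
  catalog
}

#' @export
print.MutationCatalog <- function(x, ...) {
  cat(sprintf("MutationCatalog: %d SNVs, %d sample(s), %d chromosome(s)\n",
              nrow(x), length(unique(x$sample_id)), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Split a catalog by sample
#' @param catalog a `MutationCatalog`.
#' @return named list of `MutationCatalog`, one per sample.
#' @export
split_by_sample <- function(catalog) {
  lapply(split(as.data.frame(catalog), catalog$sample_id),
         function(d) structure(d, class = c("MutationCatalog", "data.frame")))
}
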