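TIMING_BIN_BOUNDS <- c(-4.51712, 30.8225, 44.19, 55.8262, 63.7717, 80.6964)

#' Read a bedGraph track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open,
#'   no header).
#' @return a `TimingTrack`-style data.frame sorted within chromosome.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stopf("bedGraph needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  timing_track(df[1:4])
}

#' Construct a replication-timing track
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `value` (timing in the units of the source profile).
#' @return a `TimingTrack` (sorted, overlap-checked).
#' @export
timing_track <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (cm in unique(df$chrom)) {
    d <- df[df$chrom == cm, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stopf("overlapping timing intervals on %s", cm)
  }
  rownames(df) <- NULL
  structure(df, class = c("TimingTrack", "data.frame"))
}

#' Call left/right replication direction from a timing profile
#'
#' Smooths the timing values with a running mean over `smoothing_window` bp
#' of interval midpoints, takes the finite-difference derivative between
#' consecutive midpoints, and labels the span between them
#' `left`-replicating where the derivative is negative, `right` where
#' positive, and `undefined` where its absolute value is below `tol`
#' (or where a chromosome has a single interval).
#'
#' @param track a `TimingTrack`.
#' @param smoothing_window running-mean window in bp (default 100 kb).
#' @param tol zero-slope tolerance in timing units per bp (default 1e-6).
#' @return a `ReplicationDirectionMap`: data.frame with `chrom`, `start`,
#'   `end` (0-based half-open) and `direction`.
#' @export
call_replication_direction <- function(track, smoothing_window = 1e5,
                                       tol = 1e-6) {
  out <- lapply(split(as.data.frame(track), track$chrom), function(d) {
    d <- d[order(d$start), ]
    if (nrow(d) < 2L)
      return(data.frame(chrom = d$chrom, start = d$start, end = d$end,
                        direction = "undefined", stringsAsFactors = FALSE))
    mid <- (d$start + d$end) / 2
    v <- d$value
    half <- smoothing_window / 2
    sm <- vapply(seq_along(mid), function(i)
      mean(v[mid >= mid[i] - half & mid <= mid[i] + half]), numeric(1))
    deriv <- diff(sm) / diff(mid)
    dir <- ifelse(deriv < -tol, "left",
                  ifelse(deriv > tol, "right", "undefined"))
    data.frame(chrom = d$chrom[1],
               start = d$start[-nrow(d)], end = d$end[-1],
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("ReplicationDirectionMap", "data.frame"))
}

# Direction label of each mutation ("left"/"right"/"undefined"/NA outside).
mutation_direction <- function(catalog, directions) {
  lab <- rep(NA_character_, nrow(catalog))
  for (cm in unique(catalog$chrom)) {
    midx <- which(catalog$chrom == cm)
    d <- directions[directions$chrom == cm, , drop = FALSE]
    if (nrow(d) == 0L) next
    d <- d[order(d$start), ]
    i <- findInterval(catalog$pos[midx] - 1L, d$start)
    ok <- i >= 1L & (catalog$pos[midx] - 1L) < d$end[pmax(i, 1L)]
    lab[midx[ok]] <- d$direction[i[ok]]
  }
  lab
}

#' Replication-strand mutational asymmetry
#'
#' For each of the six pyrimidine-stated mutation types within each
#' replication-direction class, counts the plus-strand pyrimidine-stated
#' occurrences `N` (e.g. C>A) and the complementary purine-stated
#' occurrences `n` (G>T), and reports the asymmetry
#' \deqn{A = \log_2(N / n).}
#' POLE proofreads the leading strand, so left-replicating regions show
#' positive asymmetry for C>A, C>T and T>G and right-replicating regions the
#' mirror pattern. `A` is undefined (NA) when either count is zero unless a
#' pseudocount is requested.
#'
#' @param catalog a `MutationCatalog`.
#' @param directions a `ReplicationDirectionMap`.
#' @param types subset of the six mutation types (default all).
#' @param pseudocount added to both `N` and `n` before the ratio (default 0,
#'   i.e. undefined rather than inflated).
#' @return a `StrandAsymmetryResult`: data.frame with `type`, `direction`,
#'   `N`, `n`, `A`.
#' @export
strand_asymmetry <- function(catalog, directions, types = SUBSTITUTIONS,
                             pseudocount = 0) {
  stopifnot(all(types %in% SUBSTITUTIONS))
  lab <- mutation_direction(catalog, directions)
  res <- list()
  for (dir in c("left", "right")) {
    sel <- !is.na(lab) & lab == dir
    for (ty in types) {
      ref <- substr(ty, 1, 1); alt <- substr(ty, 3, 3)
      N <- sum(sel & catalog$ref == ref & catalog$alt == alt)
      n <- sum(sel & catalog$ref == comp_base(ref) & catalog$alt == comp_base(alt))
      A <- if (N + pseudocount > 0 && n + pseudocount > 0)
        log2((N + pseudocount) / (n + pseudocount)) else NA_real_
      res[[length(res) + 1L]] <- data.frame(type = ty, direction = dir,
                                            N = N, n = n, A = A,
                                            stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("StrandAsymmetryResult", "data.frame"))
}

#' Bin the genome by replication timing and compute mutation density
#'
#' Assigns every covered base to one of five timing bins (default: the
#' late-to-early HepG2-scale boundaries
#' `[-4.51712, 30.8225), [30.8225, 44.19), [44.19, 55.8262),
#' [55.8262, 63.7717), [63.7717, 80.6964]`; all bins half-open on the right
#' except the last, which is closed) and computes mutations per megabase per
#' bin. Intervals with timing outside the boundary union are excluded with a
#' message.
#'
#' @param track a `TimingTrack`.
#' @param catalog a `MutationCatalog`.
#' @param boundaries ordered numeric vector of length `n_bins + 1`.
#' @return data.frame with `bin`, `from`, `to`, `bp`, `mutations`, `rate`
#'   (mut/Mb); bin 1 is latest-replicating.
#' @export
timing_bins <- function(track, catalog, boundaries = TIMING_BIN_BOUNDS) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stopf("boundaries must be strictly increasing")
  nb <- length(boundaries) - 1L
  bin_of_value <- function(v) {
    b <- findInterval(v, boundaries, rightmost.closed = TRUE)
    b[b < 1L | b > nb] <- NA_integer_
    b
  }
  track_bin <- bin_of_value(track$value)
  if (anyNA(track_bin))
    message(sprintf("%d interval(s) with timing outside the bin range excluded",
                    sum(is.na(track_bin))))
  bp <- vapply(seq_len(nb), function(b)
    sum((track$end - track$start)[!is.na(track_bin) & track_bin == b]),
    numeric(1))
  mut_bin <- rep(NA_integer_, nrow(catalog))
  for (cm in unique(catalog$chrom)) {
    midx <- which(catalog$chrom == cm)
    d <- track[track$chrom == cm, , drop = FALSE]
    db <- track_bin[track$chrom == cm]
    if (nrow(d) == 0L) next
    i <- findInterval(catalog$pos[midx] - 1L, d$start)
    ok <- i >= 1L & (catalog$pos[midx] - 1L) < d$end[pmax(i, 1L)]
    mut_bin[midx[ok]] <- db[i[ok]]
  }
  muts <- vapply(seq_len(nb), function(b)
    sum(!is.na(mut_bin) & mut_bin == b), numeric(1))
  data.frame(bin = seq_len(nb),
             from = boundaries[-length(boundaries)], to = boundaries[-1],
             bp = bp, mutations = muts,
             rate = ifelse(bp > 0, 1e6 * muts / bp, NA_real_))
}
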