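# Colocalization statistics for peak sets and binned coverage tracks:
# 1x-coverage normalization, binned correlation with blacklist/outlier
# handling, overlap fractions, upset intersections, profile matrices and
# promoter partitioning. Interval arithmetic goes through GenomicRanges;
# strand is ignored for peak-level operations.

#' Scale a coverage track to 1x genomic coverage (RPGC)
#'
#' All bins are scaled by one global constant so that the genome-wide mean
#' bin value equals 1. Idempotent.
#'
#' @param track A [binned_track()] with at least one non-zero bin.
#' @return The rescaled [binned_track()].
#' @export
rpgc_normalize <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  all_v <- unlist(track$values, use.names = FALSE)
  if (length(all_v) == 0L) stop("track has no bins")
  m <- mean(all_v)
  if (m == 0) stop("cannot normalize an all-zero track")
  track$values <- lapply(track$values, function(v) v / m)
  track
}

#' Fraction of peaks in A overlapping peaks in B
#'
#' Asymmetric by design: the numerator counts peaks of `a` that overlap at
#' least one peak of `b` by `min_bp` or more basepairs.
#'
#' @param a,b `GRanges` peak sets; `a` must be non-empty.
#' @param min_bp Minimum overlap in bp (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, min_bp = 1L) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  if (length(a) == 0L) stop("`a` must be non-empty")
  if (length(b) == 0L) return(0)
  hits <- GenomicRanges::countOverlaps(a, b, minoverlap = as.integer(min_bp),
                                       ignore.strand = TRUE)
  mean(hits > 0L)
}

#' Exclusive intersection counts over merged intervals (upset counts)
#'
#' The union of all input peaks is merged into disjoint intervals; each
#' merged interval is assigned to the exact subset of input sets it
#' intersects (>= 1 bp). Counts therefore sum to the number of merged
#' union intervals.
#'
#' @param sets Named list of two or more `GRanges` peak sets.
#' @return Object of class `upset_counts`: list with `labels` (set names)
#'   and `counts`, a named integer vector keyed by `&`-joined subset
#'   labels.
#' @export
upset_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) stop("need at least 2 peak sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be named")
  }
  stripped <- lapply(sets, function(g) {
    gr <- GenomicRanges::granges(g)
    GenomicRanges::strand(gr) <- "*"
    gr
  })
  u <- GenomicRanges::reduce(unlist(methods::as(stripped, "GRangesList")),
                             ignore.strand = TRUE)
  mem <- vapply(stripped, function(s) {
    IRanges::overlapsAny(u, s, ignore.strand = TRUE)
  }, logical(length(u)))
  if (length(u) == 1L) mem <- matrix(mem, nrow = 1L)
  sig <- apply(mem, 1L, function(z) paste(names(sets)[z], collapse = "&"))
  counts <- table(sig)
  structure(list(labels = names(sets),
                 counts = stats::setNames(as.integer(counts), names(counts))),
            class = "upset_counts")
}

#' @export
print.upset_counts <- function(x, ...) {
  cat("upset_counts over sets:", paste(x$labels, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

# Re-bin a track to a coarser bin size by averaging constituent bins
# (trailing incomplete group dropped).
.rebin_track <- function(track, bin_size) {
  bs <- track$bin_size
  if (bin_size %% bs != 0L) {
    stop("target bin size ", bin_size, " is not a multiple of track bin size ", bs)
  }
  k <- bin_size %/% bs
  if (k == 1L) return(track)
  values <- lapply(track$values, function(v) {
    n2 <- length(v) %/% k
    if (n2 == 0L) return(numeric(0))
    colMeans(matrix(v[seq_len(n2 * k)], nrow = k))
  })
  binned_track(values, bin_size, track$seqlengths)
}

#' Pairwise correlation of coverage tracks on fixed genomic bins
#'
#' Tracks are re-binned to `bin_size` (average of constituent bins), bins
#' intersecting the blacklist are dropped, and, if `remove_outliers` is
#' set, for each pair of tracks bins where either value exceeds its
#' track's `median + outlier_mads * mad` are additionally dropped before
#' the correlation is computed.
#'
#' @param tracks Named list of [binned_track()]s on the same chromosome
#'   space and bin size.
#' @param bin_size Correlation bin size in bp (default 300).
#' @param blacklist Optional `GRanges` of regions to exclude.
#' @param remove_outliers Drop pairwise outlier bins (default `FALSE`).
#' @param outlier_mads Outlier threshold in MADs above the median
#'   (default 200).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Object of class `correlation_matrix`: list with `labels`, the
#'   symmetric matrix `r` (unit diagonal), and `n_bins_used` (bins
#'   surviving the blacklist).
#' @export
track_correlation <- function(tracks, bin_size = 300L, blacklist = NULL,
                              remove_outliers = FALSE, outlier_mads = 200,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.list(tracks) || length(tracks) < 2L) stop("need at least 2 tracks")
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  bin_size <- as.integer(bin_size)
  bss <- vapply(tracks, function(t) t$bin_size, integer(1L))
  if (length(unique(bss)) != 1L) stop("tracks must share a bin size")
  sls <- lapply(tracks, function(t) t$seqlengths)
  if (!all(vapply(sls[-1L], identical, logical(1L), sls[[1L]]))) {
    stop("tracks must share chromosome space")
  }
  reb <- lapply(tracks, .rebin_track, bin_size = bin_size)
  M <- vapply(reb, function(t) unlist(t$values, use.names = FALSE),
              numeric(sum(vapply(reb[[1L]]$values, length, integer(1L)))))
  keep <- rep(TRUE, nrow(M))
  if (!is.null(blacklist) && length(blacklist) > 0L) {
    bins <- .track_bins_granges(reb[[1L]])
    keep <- !IRanges::overlapsAny(bins, blacklist, ignore.strand = TRUE)
  }
  M <- M[keep, , drop = FALSE]
  if (nrow(M) < 2L) stop("fewer than 2 bins survive the blacklist")
  p <- ncol(M)
  r <- diag(1, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      x <- M[, i]; y <- M[, j]
      if (remove_outliers) {
        tx <- stats::median(x) + outlier_mads * stats::mad(x)
        ty <- stats::median(y) + outlier_mads * stats::mad(y)
        ok <- x <= tx & y <= ty
        if (sum(ok) < 2L) stop("fewer than 2 bins survive outlier removal")
        x <- x[ok]; y <- y[ok]
      }
      r[i, j] <- r[j, i] <- stats::cor(x, y, method = method)
    }
  }
  dimnames(r) <- list(names(tracks), names(tracks))
  structure(list(labels = names(tracks), r = r, n_bins_used = nrow(M)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix over", x$n_bins_used, "bins\n")
  print(round(x$r, 3))
  invisible(x)
}

# Mean track value over arbitrary half-open windows [w0, w1) (0-based bp
# coordinates) on one chromosome; basepairs outside the binned region
# contribute zero.
.window_means <- function(track, chrom, w0, w1) {
  bs <- track$bin_size
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome '", chrom, "'")
  nb <- length(v)
  width <- w1 - w0
  out <- numeric(length(w0))
  i0 <- pmax(0, floor(w0 / bs))
  i1 <- pmin(nb - 1, floor((w1 - 1) / bs))
  valid <- which(i1 >= i0 & w1 > 0 & w0 < nb * bs)
  if (length(valid) == 0L) return(out)
  nper <- i1[valid] - i0[valid] + 1
  bi <- sequence(nper) - 1 + rep(i0[valid], nper)
  ov <- pmin(rep(w1[valid], nper), (bi + 1) * bs) -
    pmax(rep(w0[valid], nper), bi * bs)
  ov <- pmax(ov, 0)
  grp <- rep(seq_along(valid), nper)
  mass <- rowsum(v[bi + 1] * ov, group = grp)
  out[valid[as.integer(rownames(mass))]] <- mass[, 1L] / width[valid][as.integer(rownames(mass))]
  out
}

# Build a regions x flank-bins signal matrix around 0-based centers.
.center_matrix <- function(track, chrom, centers0, flank, bin) {
  ncol_ <- as.integer(2 * flank / bin)
  n <- length(centers0)
  w0 <- rep(centers0, each = ncol_) - flank + (rep(seq_len(ncol_), n) - 1L) * bin
  vals <- .window_means(track, chrom, w0, w0 + bin)
  matrix(vals, nrow = n, ncol = ncol_, byrow = TRUE)
}

#' Signal matrix around region centers
#'
#' Each row holds the track signal in `bin`-bp steps across `center -
#' flank .. center + flank` for one region; the center is the midpoint
#' `floor((start + end) / 2)` of the 0-based interval. Positions outside
#' the chromosome contribute zero. `row_order` sorts rows by descending
#' row mean (ties keep input order), the order used to draw heatmaps.
#'
#' @param track A [binned_track()].
#' @param regions Non-empty `GRanges`.
#' @param flank Flank size in bp on each side of the center (default
#'   1000); must be a multiple of `bin`.
#' @param bin Column bin width in bp (default: the track's bin size).
#' @return Object of class `profile_matrix`: list with `matrix`
#'   (`length(regions)` x `2*flank/bin`), `row_order`, `flank`, `bin`.
#' @export
profile_matrix <- function(track, regions, flank = 1000L, bin = NULL) {
  stopifnot(inherits(track, "binned_track"), methods::is(regions, "GRanges"))
  if (length(regions) == 0L) stop("`regions` must be non-empty")
  if (is.null(bin)) bin <- track$bin_size
  flank <- as.integer(flank); bin <- as.integer(bin)
  if (flank %% bin != 0L) stop("`flank` must be a multiple of `bin`")
  chroms <- as.character(GenomicRanges::seqnames(regions))
  s0 <- GenomicRanges::start(regions) - 1L
  e0 <- GenomicRanges::end(regions)
  centers <- (s0 + e0) %/% 2L
  ncol_ <- as.integer(2 * flank / bin)
  m <- matrix(0, nrow = length(regions), ncol = ncol_)
  for (chrom in unique(chroms)) {
    idx <- which(chroms == chrom)
    m[idx, ] <- .center_matrix(track, chrom, centers[idx], flank, bin)
  }
  rm_ <- rowMeans(m)
  structure(list(matrix = m, row_order = order(-rm_, seq_along(rm_)),
                 flank = flank, bin = bin),
            class = "profile_matrix")
}

#' Partition peaks into promoter-proximal and distal
#'
#' A peak is promoter-proximal iff it overlaps `[tss - window, tss +
#' window]` (>= 1 bp) for any TSS; the partition is exhaustive and
#' disjoint.
#'
#' @param hits `GRanges` of peaks or motif hits.
#' @param tss TSS table as returned by [load_tss()].
#' @param window Half-window in bp around the TSS (default 3000).
#' @return List with elements `promoter` and `distal` (`GRanges`).
#' @export
promoter_partition <- function(hits, tss, window = 3000L) {
  stopifnot(methods::is(hits, "GRanges"), is.data.frame(tss))
  if (nrow(tss) == 0L) stop("empty TSS table")
  window <- as.integer(window)
  prom <- GenomicRanges::GRanges(
    seqnames = tss$chrom,
    ranges = IRanges::IRanges(start = pmax(0L, tss$tss - window) + 1L,
                              end = tss$tss + window + 1L)
  )
  is_prom <- IRanges::overlapsAny(hits, prom, ignore.strand = TRUE)
  list(promoter = hits[is_prom], distal = hits[!is_prom])
}

#' Composite (mean) signal around anchor positions
#'
#' Column-wise mean of the anchor-centered signal matrix; rows of
#' minus-strand anchors are flipped so that all columns run 5' to 3'
#' relative to the anchor.
#'
#' @param track A [binned_track()].
#' @param anchors TSS-style table ([load_tss()]): columns `chrom`, `tss`,
#'   `strand`.
#' @param flank Flank in bp on each side; must be a multiple of `bin`.
#' @param bin Column width in bp (default: track bin size).
#' @return Numeric vector of length `2 * flank / bin`.
#' @export
mean_signal_at <- function(track, anchors, flank, bin = NULL) {
  stopifnot(inherits(track, "binned_track"), is.data.frame(anchors))
  if (nrow(anchors) == 0L) stop("empty anchor table")
  if (is.null(bin)) bin <- track$bin_size
  flank <- as.integer(flank); bin <- as.integer(bin)
  if (flank %% bin != 0L) stop("`flank` must be a multiple of `bin`")
  ncol_ <- as.integer(2 * flank / bin)
  m <- matrix(0, nrow = nrow(anchors), ncol = ncol_)
  for (chrom in unique(anchors$chrom)) {
    idx <- which(anchors$chrom == chrom)
    m[idx, ] <- .center_matrix(track, chrom, anchors$tss[idx], flank, bin)
  }
  neg <- which(anchors$strand == "-")
  if (length(neg) > 0L) {
    m[neg, ] <- m[neg, ncol_:1L, drop = FALSE]
  }
  colMeans(m)
}
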