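# Seeded synthetic-data generators with exhaustive ground truth. These
# emulate the statistical structure the analysis stages assume -- genomes
# with planted motifs at known coordinates, peak sets with a controlled
# pairwise overlap fraction, peak-shaped Poisson coverage, and titrations
# drawn from the quadratic binding model -- so every stage can be validated
# end to end against known truth, without external data.

.DNA <- c("A", "C", "G", "T")

# i.i.d. background of length n at the given GC fraction.
.bg_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.DNA, n, replace = TRUE, prob = p), collapse = "")
}

# Draw one motif string from the grammar of `class`. Loops are drawn from
# {A,T} so that tract maximality and tract count are unambiguous: the
# planted string scans as exactly one hit of its class spanning the whole
# string.
.sample_motif <- function(class, n_tracts, tract_len, loop_len) {
  base <- if (class == "C4") "C" else "G"
  tls <- sample(seq(tract_len[1L], tract_len[2L]), n_tracts, replace = TRUE)
  lls <- sample(seq(loop_len[1L], loop_len[2L]), n_tracts - 1L, replace = TRUE)
  parts <- character(2L * n_tracts - 1L)
  parts[seq(1L, by = 2L, length.out = n_tracts)] <-
    vapply(tls, function(k) strrep(base, k), character(1L))
  parts[seq(2L, by = 2L, length.out = n_tracts - 1L)] <-
    vapply(lls, function(k) paste(sample(c("A", "T"), k, replace = TRUE),
                                  collapse = ""), character(1L))
  paste(parts, collapse = "")
}

# Does a candidate background segment contain any hit of the planted
# class, on either strand?
.segment_dirty <- function(seg, class, min_tracts) {
  scan1 <- function(s) {
    if (class == "C4") nrow(scan_c4(s, min_tracts)) > 0L
    else nrow(.scan_g_class(s, class)) > 0L
  }
  scan1(seg) || scan1(revcomp(seg))
}

# Background segment with 8-bp A/T insulators at both ends (so no motif
# can extend or chain across a segment boundary: spacers are capped at 7
# and tract bases cannot continue through the insulator), re-drawn until
# it contains no accidental hit of the planted class on either strand.
.bg_segment <- function(n, gc, class, min_tracts, max_tries = 200L) {
  ins <- function(k) paste(sample(c("A", "T"), k, replace = TRUE), collapse = "")
  if (n <= 16L) return(ins(n))
  for (tries in seq_len(max_tries)) {
    mid <- .bg_seq(n - 16L, gc)
    if (!.segment_dirty(mid, class, min_tracts)) {
      return(paste0(ins(8L), mid, ins(8L)))
    }
  }
  stop("could not draw a motif-free background segment after ",
       max_tries, " attempts; lower `gc` or shorten segments")
}

#' Generate a synthetic genome with planted motifs and exhaustive truth
#'
#' Chromosomes are i.i.d. background at the requested GC content with
#' motifs drawn uniformly from their grammar planted at non-overlapping
#' positions (>= `min_spacing` bp apart) on random strands. Background
#' segments are re-drawn (rejection sampling) until they contain no
#' accidental hit of the planted class on either strand, and carry short
#' A/T insulators at their ends so hits cannot straddle a
#' background/motif boundary. The truth set is therefore exhaustive: a
#' scan of the output at the planted grammar finds exactly the planted
#' intervals.
#'
#' @param chrom_len Length of each chromosome in bp.
#' @param n_motifs Total number of motifs to plant (spread round-robin
#'   across chromosomes).
#' @param class Motif class: `"C4"` or `"canonical4G"`.
#' @param n_chroms Number of chromosomes (default 1).
#' @param gc Background GC fraction (default 0.41, the human genome-wide
#'   value).
#' @param seed Integer RNG seed; output is bit-reproducible.
#' @param n_tracts Tracts per planted motif (default 4).
#' @param tract_len Range of tract lengths (default 3-5).
#' @param loop_len Range of loop lengths (default 1-7).
#' @param min_spacing Minimum background between planted motifs (>= 20).
#' @return Object of class `synth_genome`: list with `genome` (named
#'   character vector), `truth` (sorted stranded `GRanges` with `name` =
#'   class, `score` = tract count), `seqlengths`, `class`, `gc`, `seed`.
#' @export
make_genome <- function(chrom_len, n_motifs, class = c("C4", "canonical4G"),
                        n_chroms = 1L, gc = 0.41, seed = 1L, n_tracts = 4L,
                        tract_len = c(3L, 5L), loop_len = c(1L, 7L),
                        min_spacing = 20L) {
  class <- match.arg(class)
  stopifnot(chrom_len >= 1, n_motifs >= 0, gc >= 0, gc <= 1,
            n_tracts >= 2, min_spacing >= 20)
  n_chroms <- as.integer(n_chroms)
  chrom_len <- as.integer(chrom_len)
  chroms <- paste0("chr", seq_len(n_chroms))
  per_chrom <- tabulate(rep(seq_len(n_chroms), length.out = n_motifs),
                        nbins = n_chroms)
  res <- .with_seed(seed, {
    genome <- character(n_chroms)
    truth <- list()
    for (ci in seq_len(n_chroms)) {
      m <- per_chrom[ci]
      motifs <- character(m)
      strands <- character(m)
      lens <- integer(m)
      for (k in seq_len(m)) {
        ms <- .sample_motif(class, n_tracts, tract_len, loop_len)
        strands[k] <- sample(c("+", "-"), 1L)
        motifs[k] <- if (strands[k] == "+") ms else revcomp(ms)
        lens[k] <- nchar(motifs[k])
      }
      free <- chrom_len - sum(lens) - min_spacing * (m + 1L)
      if (free < 0L) stop("chromosome too short to host the requested motifs")
      extra <- if (m >= 0L) as.integer(stats::rmultinom(1L, free,
                                                        rep(1, m + 1L))) else free
      gaps <- min_spacing + extra
      segs <- character(2L * m + 1L)
      pos <- 0L
      starts <- integer(m)
      for (k in seq_len(m + 1L)) {
        segs[2L * k - 1L] <- .bg_segment(gaps[k], gc, class, n_tracts)
        pos <- pos + gaps[k]
        if (k <= m) {
          segs[2L * k] <- motifs[k]
          starts[k] <- pos
          pos <- pos + lens[k]
        }
      }
      genome[ci] <- paste(segs, collapse = "")
      if (m > 0L) {
        truth[[ci]] <- GenomicRanges::GRanges(
          seqnames = chroms[ci],
          ranges = IRanges::IRanges(start = starts + 1L, end = starts + lens),
          strand = strands,
          name = class, score = rep(as.numeric(n_tracts), m)
        )
      }
    }
    list(genome = genome, truth = truth)
  })
  names(res$genome) <- chroms
  truth <- .sort_granges(.bind_granges(res$truth))
  structure(list(genome = res$genome, truth = truth,
                 seqlengths = stats::setNames(nchar(res$genome), chroms),
                 class = class, gc = gc, seed = as.integer(seed)),
            class = "synth_genome")
}

#' @export
print.synth_genome <- function(x, ...) {
  cat("synth_genome:", length(x$genome), "chromosome(s),",
      sum(nchar(x$genome)), "bp,", length(x$truth), "planted", x$class,
      "motif(s), gc =", x$gc, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Simulate peak-shaped Poisson coverage
#'
#' Per-bin counts are Poisson with rate `background_rate` outside peaks
#' and a triangular profile inside peaks whose in-peak mean rate is
#' exactly `background_rate * enrichment` (apex at the peak center,
#' shoulders decaying to background at the edges).
#'
#' @param peaks `GRanges` of enriched regions.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param bin Bin width in bp (default 50).
#' @param background_rate Mean background counts per bin, > 0 (default 10).
#' @param enrichment Fold enrichment of the in-peak mean over background,
#'   > 1 (default 10).
#' @param seed Integer RNG seed.
#' @return A [binned_track()] of counts.
#' @export
make_coverage <- function(peaks, chrom_sizes, bin = 50L, background_rate = 10,
                          enrichment = 10, seed = 1L) {
  stopifnot(methods::is(peaks, "GRanges"))
  if (background_rate <= 0) stop("`background_rate` must be > 0")
  if (enrichment <= 1) stop("`enrichment` must be > 1")
  bin <- as.integer(bin)
  pk_chrom <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(pk_chrom %in% names(chrom_sizes))) {
    stop("peaks on chromosomes absent from `chrom_sizes`")
  }
  if (any(GenomicRanges::end(peaks) > chrom_sizes[pk_chrom])) {
    stop("peaks exceed chromosome bounds")
  }
  values <- .with_seed(seed, {
    lapply(names(chrom_sizes), function(chrom) {
      nb <- chrom_sizes[[chrom]] %/% bin
      lambda <- rep(background_rate, nb)
      idx <- which(pk_chrom == chrom)
      for (i in idx) {
        s0 <- GenomicRanges::start(peaks)[i] - 1L
        e0 <- GenomicRanges::end(peaks)[i]
        b0 <- s0 %/% bin
        b1 <- min((e0 - 1L) %/% bin, nb - 1L)
        if (b1 < b0) next
        bb <- b0:b1
        centers <- (bb + 0.5) * bin
        half <- (e0 - s0) / 2
        w <- pmax(0, 1 - abs(centers - (s0 + e0) / 2) / half)
        if (sum(w) > 0) w <- w * length(w) / sum(w)
        lambda[bb + 1L] <- background_rate +
          background_rate * (enrichment - 1) * w
      }
      stats::rpois(nb, lambda)
    })
  })
  names(values) <- names(chrom_sizes)
  binned_track(values, bin, chrom_sizes)
}

#' Construct a pair of peak sets with an exact overlap fraction
#'
#' Exactly `round(frac_overlap * n_a)` peaks of A intersect (>= 1 bp) a
#' peak of B; all remaining peaks of either set are pairwise disjoint, so
#' [overlap_fraction()] on the output recovers `frac_overlap` up to the
#' `1/n_a` rounding granularity.
#'
#' @param n_a,n_b Number of peaks in A and B.
#' @param frac_overlap Target fraction of A-peaks overlapping B, in
#'   `[0, 1]`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param seed Integer RNG seed.
#' @param width Peak width in bp (default 250).
#' @return List with `GRanges` elements `a` and `b`.
#' @export
make_peak_pair <- function(n_a, n_b, frac_overlap, chrom_sizes, seed = 1L,
                           width = 250L) {
  stopifnot(n_a >= 1, n_b >= 0, frac_overlap >= 0, frac_overlap <= 1)
  width <- as.integer(width)
  if (width < 2L) stop("`width` must be >= 2")
  k <- round(frac_overlap * n_a)
  if (k > n_b) stop("`frac_overlap` requires more B peaks than `n_b`")
  m <- n_a + n_b - k  # total slots
  stride <- 2L * width + 10L
  cells <- do.call(rbind, lapply(names(chrom_sizes), function(chrom) {
    nc <- chrom_sizes[[chrom]] %/% stride
    if (nc == 0L) return(NULL)
    data.frame(chrom = chrom, pos = (seq_len(nc) - 1L) * stride,
               stringsAsFactors = FALSE)
  }))
  if (is.null(cells) || nrow(cells) < m) {
    stop("chromosome space cannot host ", m, " non-overlapping peak slots")
  }
  .with_seed(seed, {
    take <- cells[sample(nrow(cells), m), , drop = FALSE]
    type <- sample(rep(c("pair", "loneA", "loneB"),
                       c(k, n_a - k, n_b - k)))
    half <- width %/% 2L
    a_idx <- type %in% c("pair", "loneA")
    b_pair <- type == "pair"
    b_lone <- type == "loneB"
    a <- GenomicRanges::GRanges(
      seqnames = take$chrom[a_idx],
      ranges = IRanges::IRanges(start = take$pos[a_idx] + 1L, width = width),
      name = "A", score = 0
    )
    b_starts <- c(take$pos[b_pair] + half, take$pos[b_lone])
    b_chroms <- c(take$chrom[b_pair], take$chrom[b_lone])
    b <- if (length(b_starts) > 0L) {
      GenomicRanges::GRanges(
        seqnames = b_chroms,
        ranges = IRanges::IRanges(start = b_starts + 1L, width = width),
        name = "B", score = 0
      )
    } else .empty_granges()
    list(a = .sort_granges(a), b = .sort_granges(b))
  })
}

#' Simulate an EMSA titration from the quadratic binding model
#'
#' Bound fractions are the closed-form [bound_fraction()] values at the
#' given protein gradient plus additive Gaussian noise, clipped to
#' `[0, 1]`. The default gradient is the standard EMSA design
#' 0/1/3/10/30/100/300/1000 nM.
#'
#' @param Kd Planted dissociation constant (nM).
#' @param T0 Total DNA concentration (nM, default 20).
#' @param X Protein concentration gradient (nM).
#' @param noise_sd Gaussian noise SD on the bound fraction (>= 0).
#' @param seed Integer RNG seed.
#' @return A [titration_series()]; the planted constant is kept in
#'   attribute `kd_true`.
#' @export
make_titration <- function(Kd, T0 = 20, X = c(0, 1, 3, 10, 30, 100, 300, 1000),
                           noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  y0 <- bound_fraction(T0, X, Kd)
  y <- if (noise_sd > 0) {
    .with_seed(seed, pmin(pmax(y0 + stats::rnorm(length(X), 0, noise_sd), 0), 1))
  } else y0
  ts <- titration_series(X, y, T0)
  attr(ts, "kd_true") <- Kd
  ts
}
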