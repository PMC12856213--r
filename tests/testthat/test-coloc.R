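# Colocalization statistics: normalization, overlaps, upsets, correlation,
# profiles, promoter partitioning.

mk_track <- function(values, bin = 100L) {
  sl <- vapply(values, function(v) length(v) * bin, numeric(1))
  binned_track(values, bin, sl)
}

test_that("RPGC normalization scales the genome-wide mean to one", {
  expect_equal(rpgc_normalize(mk_track(list(chr1 = c(2, 2, 2))))$values$chr1,
               c(1, 1, 1))
  expect_equal(rpgc_normalize(mk_track(list(chr1 = c(0, 4))))$values$chr1,
               c(0, 2))
  tr <- mk_track(list(chr1 = c(0.5, 1.5, 1)))
  expect_equal(rpgc_normalize(rpgc_normalize(tr))$values$chr1,
               rpgc_normalize(tr)$values$chr1, tolerance = 1e-12)
  expect_error(rpgc_normalize(mk_track(list(chr1 = c(0, 0)))), "all-zero")
})

test_that("overlap_fraction counts A-peaks touching B and matches brute force", {
  a <- read_bed_text <- function(lines) {
    f <- withr::local_tempfile(.local_envir = parent.frame())
    writeLines(lines, f)
    read_bed(f)
  }
  A <- a(c("chr1\t0\t10", "chr1\t100\t110", "chr2\t0\t5"))
  expect_equal(overlap_fraction(A, A), 1)
  B <- a(c("chr1\t50\t60"))
  expect_equal(overlap_fraction(A, B), 0)
  expect_error(overlap_fraction(A[0], B), "non-empty")

  set.seed(12)
  for (i in 1:10) {
    x <- random_peaks(60, 50000)
    y <- random_peaks(40, 50000)
    expect_equal(overlap_fraction(x, y), oracle_overlap_fraction(x, y))
    expect_equal(overlap_fraction(x, y, min_bp = 50),
                 oracle_overlap_fraction(x, y, min_bp = 50))
    # monotone nondecreasing as intervals are added to B
    expect_gte(overlap_fraction(x, c(y, random_peaks(10, 50000))),
               overlap_fraction(x, y))
  }
})

test_that("upset counts assign merged intervals to exact subsets", {
  gr <- function(s, e) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = s + 1L, end = e))
  u <- upset_counts(list(A = gr(0, 10), B = gr(5, 15)))
  expect_equal(u$counts, c("A&B" = 1L))
  u2 <- upset_counts(list(A = gr(0, 10), B = gr(20, 30)))
  expect_equal(sort(names(u2$counts)), c("A", "B"))
  expect_equal(unname(u2$counts[c("A", "B")]), c(1L, 1L))
  u3 <- upset_counts(list(A = gr(3, 9), B = gr(3, 9), C = gr(3, 9)))
  expect_equal(u3$counts, c("A&B&C" = 1L))
  expect_error(upset_counts(list(A = gr(0, 1))), "at least 2")
})

test_that("upset counts conserve mass and match brute force on random sets", {
  set.seed(23)
  for (i in 1:8) {
    sets <- list(A = random_peaks(50, 30000), B = random_peaks(30, 30000),
                 C = random_peaks(20, 30000))
    u <- upset_counts(sets)
    o <- oracle_upset(sets)
    expect_equal(u$counts[sort(names(u$counts))], o[sort(names(o))])
    merged <- GenomicRanges::reduce(unlist(methods::as(
      lapply(sets, GenomicRanges::granges), "GRangesList")))
    expect_equal(sum(u$counts), length(merged))
  }
})

test_that("track correlation is affine-invariant, symmetric, unit-diagonal", {
  set.seed(3)
  v <- stats::rpois(2000, 4)
  t1 <- mk_track(list(chr1 = v), 100L)
  t2 <- mk_track(list(chr1 = v * 5), 100L)          # positive rescaling
  t3 <- mk_track(list(chr1 = stats::rpois(2000, 4)), 100L)
  cm <- track_correlation(list(a = t1, b = t2, c = t3), bin_size = 300L)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["a", "b"], 1)
  expect_lt(abs(cm$r["a", "c"]), 0.1)
  expect_error(track_correlation(list(a = t1)), "at least 2")
  expect_error(track_correlation(list(a = t1, b = mk_track(list(chr1 = v), 70L))),
               "bin size")
})

test_that("blacklisted bins and pairwise outliers are excluded", {
  set.seed(8)
  v1 <- stats::rpois(3000, 4)
  v2 <- stats::rpois(3000, 4)
  # one common huge artifact bin induces spurious correlation
  v1[100] <- 1e5; v2[100] <- 1e5
  t1 <- mk_track(list(chr1 = v1), 100L)
  t2 <- mk_track(list(chr1 = v2), 100L)
  naive <- track_correlation(list(a = t1, b = t2), bin_size = 300L)
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9901, 10200))
  cleaned <- track_correlation(list(a = t1, b = t2), bin_size = 300L,
                               blacklist = bl)
  expect_lt(cleaned$n_bins_used, naive$n_bins_used)
  expect_lt(abs(cleaned$r["a", "b"]), abs(naive$r["a", "b"]))
  robust <- track_correlation(list(a = t1, b = t2), bin_size = 300L,
                              remove_outliers = TRUE)
  expect_lt(abs(robust$r["a", "b"]), abs(naive$r["a", "b"]))
})

test_that("profile matrices sample flanks around region centers", {
  tr <- mk_track(list(chr1 = rep(1, 100)), 100L)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3001, 6001),
                                                             c(3200, 6200)))
  pm <- profile_matrix(tr, regions, flank = 1000L, bin = 100L)
  expect_equal(dim(pm$matrix), c(2L, 20L))
  expect_true(all(pm$matrix == 1))
  expect_equal(pm$row_order, 1:2)

  # a triangular peak centered on its region peaks at the central columns
  v <- rep(0, 100)
  v[21:39] <- 10 - abs(seq(-9, 9))
  tr2 <- mk_track(list(chr1 = v), 100L)
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2951, 3050))
  pm2 <- profile_matrix(tr2, reg, flank = 1000L, bin = 100L)
  prof <- pm2$matrix[1, ]
  expect_equal(which.max(prof), 10L)  # column covering the center
  expect_equal(prof, v[21:40])        # columns read the underlying bins

  # rows are ordered by descending mean; ties keep input order
  v3 <- rep(0, 100); v3[30] <- 2; v3[60] <- 5
  tr3 <- mk_track(list(chr1 = v3), 100L)
  reg3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2951, 5951),
                                                          c(2960, 5960)))
  pm3 <- profile_matrix(tr3, reg3, flank = 500L, bin = 100L)
  expect_equal(pm3$row_order, c(2L, 1L))
  means <- rowMeans(pm3$matrix)[pm3$row_order]
  expect_true(all(diff(means) <= 0))
  # out-of-chromosome flank contributes zero
  edge <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  pme <- profile_matrix(tr, edge, flank = 1000L, bin = 100L)
  expect_true(all(pme$matrix[1, 1:9] == 0))
  expect_error(profile_matrix(tr, edge[0]), "non-empty")
})

test_that("promoter partitioning is exhaustive, disjoint, and edge-exact", {
  tss <- data.frame(chrom = "chr1", tss = 10000L, strand = "+", gene = "g1")
  gr <- function(s, w) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = s + 1L, width = w))
  # 1-bp hit at TSS + 2999 is inside the +/-3 kb window
  p <- promoter_partition(gr(12999, 1), tss)
  expect_equal(length(p$promoter), 1L)
  # hit starting at TSS + 3002 is outside
  p2 <- promoter_partition(gr(13002, 50), tss)
  expect_equal(length(p2$distal), 1L)
  # a hit spanning the window edge overlaps by >= 1 bp
  p3 <- promoter_partition(gr(12950, 200), tss)
  expect_equal(length(p3$promoter), 1L)

  set.seed(44)
  hits <- random_peaks(100, 100000)
  pp <- promoter_partition(hits, tss)
  expect_equal(length(pp$promoter) + length(pp$distal), length(hits))
  expect_equal(length(GenomicRanges::intersect(pp$promoter, pp$distal)), 0L)
  expect_error(promoter_partition(hits, tss[0, ]), "empty")
})

test_that("composite anchor signal is strand-aware", {
  v <- rep(0, 100)
  v[35] <- 4  # asymmetric mark left of the anchor at bin 41
  tr <- mk_track(list(chr1 = v), 100L)
  plus <- data.frame(chrom = "chr1", tss = 4050L, strand = "+", gene = "g")
  minus <- data.frame(chrom = "chr1", tss = 4050L, strand = "-", gene = "g")
  sp <- mean_signal_at(tr, plus, flank = 1000L)
  sm <- mean_signal_at(tr, minus, flank = 1000L)
  expect_equal(sm, rev(sp))
  expect_false(isTRUE(all.equal(sp, sm)))  # the mark is asymmetric
  # constant track gives a constant composite
  expect_true(all(mean_signal_at(mk_track(list(chr1 = rep(2, 100)), 100L),
                                 plus, flank = 1000L) == 2))
  # a single anchor equals its own profile row
  reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4001, 4100))
  pm <- profile_matrix(tr, reg, flank = 1000L, bin = 100L)
  expect_equal(sp, pm$matrix[1, ])
  expect_error(mean_signal_at(tr, plus[0, ], flank = 1000L), "empty")
})
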