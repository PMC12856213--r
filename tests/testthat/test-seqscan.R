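# Recognition-grammar scanners: tracts, units, C4 chains, PQS classes.

test_that("find_tracts returns maximal runs at or above the length floor", {
  tr <- find_tracts("CCCTCCC", "C", 3)
  expect_equal(tr$start, c(0L, 4L))
  expect_equal(tr$end, c(3L, 7L))
  # a 7-run is one maximal tract, not several overlapping ones
  expect_equal(find_tracts("CCCCCCC", "C", 3),
               data.frame(start = 0L, end = 7L, length = 7L))
  expect_equal(nrow(find_tracts("GGGG", "C", 3)), 0L)
  expect_equal(find_tracts("GGGG", "G", 3)$end, 4L)
  expect_error(find_tracts("CCC", "C", 0), "min_len")
  # case and U normalization flow through
  expect_equal(find_tracts("cccUccc", "C", 3)$start, c(0L, 4L))
})

test_that("unit grammar accepts CCCN1-7CCC and lone C7+, rejects weaker forms", {
  expect_equal(nrow(scan_units("CCCTCCC")), 1L)
  expect_equal(scan_units("CCCTCCC")$end, 7L)
  expect_equal(nrow(scan_units("CCTCCC")), 0L)   # first tract too short
  expect_equal(nrow(scan_units("CCCCCCC")), 1L)  # lone 7-run binds
  expect_equal(nrow(scan_units("CCCCCC")), 0L)   # lone 6-run does not
  for (k in 1:7) {
    expect_equal(nrow(scan_units(paste0("CCC", strrep("T", k), "CCC"))), 1L,
                 info = paste("spacer", k))
  }
  expect_equal(nrow(scan_units(paste0("CCC", strrep("T", 8), "CCC"))), 0L)
  # N in the spacer disqualifies the unit (no motif across a gap)
  expect_equal(nrow(scan_units("CCCNCCC")), 0L)
  # pairing is preferred over the lone-run rule and consumes both tracts
  u <- scan_units("CCCCCCCTCCC")
  expect_equal(nrow(u), 1L)
  expect_equal(u$n_tracts, 2L)
  expect_equal(u$end, 11L)
})

test_that("C4 chains require enough C3+ tracts with 1-7 nt loops", {
  h <- scan_c4("CCCTAACCCTAACCCTAACCC", min_tracts = 4)
  expect_equal(nrow(h), 1L)
  expect_equal(h$n_tracts, 4L)
  expect_equal(h$spacers[[1L]], c(3L, 3L, 3L))
  expect_equal(c(h$start, h$end), c(0L, 21L))

  expect_equal(nrow(scan_c4("CCCTCCC", min_tracts = 4)), 0L)
  two <- scan_c4("CCCTCCC", min_tracts = 2)
  expect_equal(nrow(two), 1L)  # two tracts suffice for probe binding
  expect_equal(two$n_tracts, 2L)
  expect_error(scan_c4("CCC", min_tracts = 5), "min_tracts")
  expect_error(scan_c4("CCXQ"), "illegal")
})

test_that("PQS worked examples: telomeric repeat and thrombin aptamer", {
  tel <- "GGGTTAGGGTTAGGGTTAGGG"
  h <- scan_pqs(tel, "canonical4G")
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(c(h$start, h$end), c(0L, 21L))
  # strand duality: the reverse complement carries the same hit on "-"
  hr <- scan_pqs(revcomp(tel), "canonical4G")
  expect_equal(nrow(hr), 1L)
  expect_equal(hr$strand, "-")
  expect_equal(c(hr$start, hr$end), c(0L, 21L))

  tba <- "GGTTGGTGTGGTTGG"
  expect_equal(nrow(scan_pqs(tba, "twoQuartet")), 1L)
  expect_equal(nrow(scan_pqs(tba, "canonical4G")), 0L)
})

test_that("GVBQ, long-loop and bulged grammars match their definitions", {
  # exactly one GG vacancy among three intact G3+ tracts
  gv <- "GGGTGGGTGGTGGG"
  h <- scan_pqs(gv, "GVBQ")
  expect_equal(nrow(h[h$strand == "+", ]), 1L)
  expect_equal(nrow(scan_pqs("GGGTGGGTGGGTGGG", "GVBQ")), 0L)  # no vacancy
  # one loop must reach 8-15 nt; a canonical motif is not long-loop
  ll <- paste0("GGG", strrep("T", 10), "GGGTGGGTGGG")
  expect_equal(nrow(scan_pqs(ll, "longLoop15")), 1L)
  expect_equal(nrow(scan_pqs("GGGTTAGGGTTAGGGTTAGGG", "longLoop15")), 0L)
  # one tract split by a short non-G bulge
  bu <- "GGGTGGGAGGGTGGAGGG"
  h <- scan_pqs(bu, "bulged")
  expect_equal(nrow(h[h$strand == "+", ]), 1L)
  expect_equal(h$end[h$strand == "+"] - h$start[h$strand == "+"], 18L)
  # four intact tracts offer no bulge to place
  expect_equal(nrow(scan_pqs("GGGTGGGAGGGTGGG", "bulged")), 0L)
  expect_error(scan_pqs("GGG", "noSuchClass"), "arg")
})

test_that("scanners agree with brute-force enumeration on random sequences", {
  set.seed(421)
  classes <- c("canonical4G", "twoQuartet", "GVBQ", "longLoop15", "bulged")
  for (i in 1:40) {
    s <- random_seq(500)
    if (i %% 7 == 0) {  # sprinkle Ns to exercise gap handling
      pos <- sample.int(490, 5)
      substr(s, pos[1], pos[1] + 2) <- "NNN"
    }
    for (mt in c(2L, 4L)) {
      expect_identical(hits_key(scan_c4(s, mt)), hits_key(oracle_scan_c4(s, mt)),
                       info = paste("C4", mt, "seq", i))
    }
    for (cl in classes) {
      expect_identical(hits_key(scan_pqs(s, cl)), hits_key(oracle_scan_pqs(s, cl)),
                       info = paste(cl, "seq", i))
    }
  }
})

test_that("strand duality links C4 on a sequence to canonical G4 on its complement", {
  set.seed(99)
  for (i in 1:25) {
    s <- random_seq(800)
    L <- nchar(s)
    c4 <- scan_c4(s, 4)
    g4 <- scan_pqs(revcomp(s), "canonical4G")
    g4p <- g4[g4$strand == "+", , drop = FALSE]
    mirrored <- data.frame(start = L - g4p$end, end = L - g4p$start)
    mirrored <- mirrored[order(mirrored$start), , drop = FALSE]
    expect_equal(c4[, c("start", "end")], mirrored,
                 ignore_attr = TRUE, info = paste("seq", i))
  }
})

test_that("hit sets are sorted, non-overlapping per strand, with legal spacers", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_seq(600, probs = c(A = 0.15, C = 0.35, G = 0.35, T = 0.15))
    for (mt in c(2L, 3L, 4L)) {
      h <- scan_c4(s, mt)
      expect_true(all(diff(h$start) > 0))
      if (nrow(h) > 1L) expect_true(all(h$start[-1L] >= h$end[-nrow(h)]))
      expect_true(all(unlist(h$spacers) >= 1 & unlist(h$spacers) <= 7))
      expect_true(all(h$n_tracts >= mt))
      # hit span runs from first tract start to last tract end
      expect_equal(h$start, vapply(h$tract_starts, min, integer(1)))
      expect_equal(h$end, vapply(h$tract_ends, max, integer(1)))
    }
    h <- scan_pqs(s, "longLoop15")
    expect_true(all(unlist(h$spacers) >= 1 & unlist(h$spacers) <= 15))
  }
})

test_that("stricter tract requirements give nested hit sets", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_seq(600, probs = c(A = 0.15, C = 0.4, G = 0.15, T = 0.3))
    h4 <- scan_c4(s, 4)
    h2 <- scan_c4(s, 2)
    if (nrow(h4) == 0L) next
    contained <- vapply(seq_len(nrow(h4)), function(k) {
      any(h2$start <= h4$start[k] & h2$end >= h4$end[k])
    }, logical(1))
    expect_true(all(contained))
  }
})

test_that("hits_to_peakset maps hits onto genomic coordinates", {
  h <- scan_c4("CCCTAACCCTAACCCTAACCC", 4)
  gr <- hits_to_peakset(h, "chr7", offset = 100L)
  expect_equal(GenomicRanges::start(gr) - 1L, 100L)
  expect_equal(GenomicRanges::end(gr), 121L)
  expect_equal(gr$name, "C4")
  expect_equal(gr$score, 4)
  expect_equal(length(hits_to_peakset(scan_c4("AAAA", 4), "chr1")), 0L)
  expect_error(hits_to_peakset(h, "chr1", offset = -1), "non-negative")
})
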