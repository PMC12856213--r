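# DNA recognition grammars for C-rich single-stranded DNA and putative
# G-quadruplex sequences (PQS).
#
# The probe-recognizable building block is a maximal cytosine run
# ("C-tract"). Two C3+ tracts joined by a 1-7 nt spacer form the minimal
# recognition unit (CCCN1-7CCC); a lone C-run of >= 7 also binds. A full
# C4 motif is a chain of >= 2 (typically 4) C3+ tracts with 1-7 nt loops --
# the complement of a canonical G4. PQS classes are scanned on the G-rich
# strand of both orientations and reported in plus-strand coordinates.
#
# All hit coordinates are 0-based half-open offsets into the scanned
# sequence. Tracts are maximal runs; spacers between consecutive tracts
# may contain the tract base only in runs too short to be a tract
# themselves. Hits never contain N (tracts cannot, and spacers with N are
# rejected), so motifs are not called across assembly gaps.

# ---- tract discovery --------------------------------------------------

#' Find maximal single-base runs (tracts) in a sequence
#'
#' @param seq DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param base Tract base, `"C"` or `"G"`.
#' @param min_len Minimum run length (>= 1).
#' @return `data.frame` with 0-based half-open columns `start`, `end`, and
#'   `length`, one row per maximal run of `base` with length >= `min_len`,
#'   left to right.
#' @examples
#' find_tracts("CCCTCCC", "C", 3)
#' @export
find_tracts <- function(seq, base = c("C", "G"), min_len = 3L) {
  base <- match.arg(base)
  if (!is.numeric(min_len) || length(min_len) != 1L || min_len < 1) {
    stop("`min_len` must be an integer >= 1")
  }
  s <- .check_seq(seq)
  .runs(s, base, as.integer(min_len))
}

.runs <- function(s, base, min_len) {
  m <- gregexpr(sprintf("%s{%d,}", base, min_len), s)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len, length = len)
}

# ---- chain machinery --------------------------------------------------

# For consecutive tract rows, is the gap a legal loop? (length within
# bounds, no N in the spacer)
.gap_ok <- function(s, tr, loop_min, loop_max) {
  n <- nrow(tr)
  if (n < 2L) return(logical(0))
  gap <- tr$start[-1L] - tr$end[-n]
  sp <- substring(s, tr$end[-n] + 1L, tr$start[-1L])
  gap >= loop_min & gap <= loop_max & !grepl("N", sp, fixed = TRUE)
}

.hits_df <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(
      start = integer(0), end = integer(0), strand = character(0),
      n_tracts = integer(0), variant_class = character(0),
      tract_starts = I(list()), tract_ends = I(list()), spacers = I(list())
    ))
  }
  out <- data.frame(
    start = vapply(rows, `[[`, integer(1L), "start"),
    end = vapply(rows, `[[`, integer(1L), "end"),
    strand = vapply(rows, `[[`, character(1L), "strand"),
    n_tracts = vapply(rows, `[[`, integer(1L), "n_tracts"),
    variant_class = vapply(rows, `[[`, character(1L), "variant_class"),
    tract_starts = I(lapply(rows, `[[`, "tract_starts")),
    tract_ends = I(lapply(rows, `[[`, "tract_ends")),
    spacers = I(lapply(rows, `[[`, "spacers"))
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

.chain_row <- function(tr, idx, class, strand = "+") {
  list(
    start = tr$start[idx[1L]],
    end = tr$end[idx[length(idx)]],
    strand = strand,
    n_tracts = length(idx),
    variant_class = class,
    tract_starts = tr$start[idx],
    tract_ends = tr$end[idx],
    spacers = if (length(idx) > 1L) {
      tr$start[idx[-1L]] - tr$end[idx[-length(idx)]]
    } else integer(0)
  )
}

# Maximal-chain scan: tracts are chained while consecutive gaps are legal
# loops; each maximal chain with >= min_tracts tracts (and passing
# chain_filter on its loop lengths, if given) is one hit. Chains are
# disjoint by construction, so hits are non-overlapping and leftmost-greedy
# with maximal tract count.
.scan_chains <- function(s, base, min_run, loop_min, loop_max, min_tracts,
                         class, chain_filter = NULL) {
  tr <- .runs(s, base, min_run)
  n <- nrow(tr)
  if (n == 0L) return(.hits_df(list()))
  ok <- .gap_ok(s, tr, loop_min, loop_max)
  id <- cumsum(c(TRUE, !ok))
  rows <- list()
  for (idx in split(seq_len(n), id)) {
    if (length(idx) < min_tracts) next
    gaps <- if (length(idx) > 1L) tr$start[idx[-1L]] - tr$end[idx[-length(idx)]] else integer(0)
    if (!is.null(chain_filter) && !chain_filter(gaps)) next
    rows[[length(rows) + 1L]] <- .chain_row(tr, idx, class)
  }
  .hits_df(rows)
}

# Greedy non-overlap selection over candidate windows: leftmost start
# first, ties broken by longer span, then by tract-start order; no re-scan
# inside a consumed hit.
.select_windows <- function(rows) {
  if (length(rows) == 0L) return(.hits_df(list()))
  starts <- vapply(rows, `[[`, integer(1L), "start")
  ends <- vapply(rows, `[[`, integer(1L), "end")
  key3 <- vapply(rows, function(r) paste(r$tract_starts, collapse = ","), character(1L))
  ord <- order(starts, -ends, key3)
  sel <- list()
  last_end <- -1L
  for (i in ord) {
    if (starts[i] >= last_end) {
      sel[[length(sel) + 1L]] <- rows[[i]]
      last_end <- ends[i]
    }
  }
  .hits_df(sel)
}

# ---- CK13 units -------------------------------------------------------

#' Scan a sequence for minimal probe-recognition units
#'
#' A unit is either two maximal C3+ tracts joined by a 1-7 nt spacer
#' (`CCCN1-7CCC`) or a lone maximal C-run of length >= 7 (a 6-run does
#' not qualify). Scanning is leftmost-greedy and hits do not overlap;
#' when a tract can both pair with its successor and stand alone, the
#' two-tract (longer) unit wins.
#'
#' @param seq DNA string.
#' @return Hit `data.frame` (0-based half-open `start`/`end`, `strand`,
#'   `n_tracts`, `variant_class = "unit"`, tract coordinates, spacer
#'   lengths).
#' @examples
#' scan_units("CCCTCCC")   # one unit
#' scan_units("CCTCCC")    # none: first tract too short
#' @export
scan_units <- function(seq) {
  s <- .check_seq(seq)
  tr <- .runs(s, "C", 3L)
  n <- nrow(tr)
  rows <- list()
  if (n > 0L) {
    ok <- .gap_ok(s, tr, 1L, 7L)
    i <- 1L
    while (i <= n) {
      if (i < n && ok[i]) {
        rows[[length(rows) + 1L]] <- .chain_row(tr, c(i, i + 1L), "unit")
        i <- i + 2L
      } else if (tr$length[i] >= 7L) {
        rows[[length(rows) + 1L]] <- .chain_row(tr, i, "unit")
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  .hits_df(rows)
}

# ---- C4 ---------------------------------------------------------------

#' Scan a sequence for C4 motifs
#'
#' A C4 motif is a chain of consecutive maximal C3+ tracts separated by
#' 1-7 nt loops. `min_tracts = 4` corresponds to the full complement of a
#' canonical G4; probe binding requires a minimum of two tracts. Chains are
#' maximal (the scan prefers the largest tract count), so the hit set at
#' `min_tracts = 4` is a subset of the hit set at `min_tracts = 2`.
#'
#' @param seq DNA string (hits are reported on the scanned strand).
#' @param min_tracts Minimum number of C-tracts: 2, 3 or 4.
#' @return Hit `data.frame` as in [scan_units()], `variant_class = "C4"`.
#' @examples
#' scan_c4("CCCTAACCCTAACCCTAACCC", min_tracts = 4)
#' @export
scan_c4 <- function(seq, min_tracts = 4L) {
  if (!is.numeric(min_tracts) || length(min_tracts) != 1L ||
      !min_tracts %in% c(2L, 3L, 4L)) {
    stop("`min_tracts` must be 2, 3 or 4")
  }
  s <- .check_seq(seq)
  .scan_chains(s, "C", 3L, 1L, 7L, as.integer(min_tracts), "C4")
}

# ---- PQS classes ------------------------------------------------------

.pqs_classes <- c("canonical4G", "twoQuartet", "GVBQ", "longLoop15", "bulged")

# Scan one orientation (G-rich strand) for a PQS class.
.scan_g_class <- function(s, variant_class) {
  switch(variant_class,
    canonical4G = .scan_chains(s, "G", 3L, 1L, 7L, 4L, "canonical4G"),
    twoQuartet = .scan_chains(s, "G", 2L, 1L, 7L, 4L, "twoQuartet"),
    longLoop15 = .scan_chains(s, "G", 3L, 1L, 15L, 4L, "longLoop15",
                              chain_filter = function(gaps) any(gaps >= 8L)),
    GVBQ = .scan_gvbq(s),
    bulged = .scan_bulged(s)
  )
}

# G-vacancy-bearing quadruplex: four consecutive candidate tracts (maximal
# G2+ runs) with 1-7 nt loops, exactly one of which is a GG (length 2), the
# other three G3+.
.scan_gvbq <- function(s) {
  tr <- .runs(s, "G", 2L)
  n <- nrow(tr)
  if (n < 4L) return(.hits_df(list()))
  ok <- .gap_ok(s, tr, 1L, 7L)
  rows <- list()
  for (i in seq_len(n - 3L)) {
    if (!all(ok[i:(i + 2L)])) next
    lens <- tr$length[i:(i + 3L)]
    if (sum(lens == 2L) == 1L && sum(lens >= 3L) == 3L) {
      rows[[length(rows) + 1L]] <- .chain_row(tr, i:(i + 3L), "GVBQ")
    }
  }
  .select_windows(rows)
}

# Bulged quadruplex: windows of four tract objects with 1-7 nt loops, of
# which exactly one is a composite tract -- two maximal G-runs separated by
# a 1-3 nt non-G bulge, combined length >= 3, with at least one side
# shorter than 3 (otherwise the pair is two intact tracts) -- and the other
# three are intact maximal G3+ runs. Loops may not contain an intact G3+
# run (an intact tract is never skipped) nor N.
.bulged_objects <- function(s) {
  runs <- .runs(s, "G", 1L)
  n <- nrow(runs)
  objs <- list()
  for (i in seq_len(n)) {
    if (runs$length[i] >= 3L) {
      objs[[length(objs) + 1L]] <- list(start = runs$start[i], end = runs$end[i],
                                        comp = FALSE)
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      b <- runs$start[i + 1L] - runs$end[i]
      if (b < 1L || b > 3L) next
      gap <- substring(s, runs$end[i] + 1L, runs$start[i + 1L])
      if (grepl("N", gap, fixed = TRUE)) next
      la <- runs$length[i]; lb <- runs$length[i + 1L]
      if (la + lb >= 3L && min(la, lb) <= 2L) {
        objs[[length(objs) + 1L]] <- list(start = runs$start[i],
                                          end = runs$end[i + 1L], comp = TRUE)
      }
    }
  }
  if (length(objs) == 0L) return(objs)
  objs[order(vapply(objs, `[[`, integer(1L), "start"),
             vapply(objs, `[[`, integer(1L), "end"))]
}

.bulged_loop_ok <- function(s, from_end, to_start) {
  g <- to_start - from_end
  if (g < 1L || g > 7L) return(FALSE)
  sp <- substring(s, from_end + 1L, to_start)
  !grepl("N", sp, fixed = TRUE) && !grepl("GGG", sp, fixed = TRUE)
}

.scan_bulged <- function(s) {
  objs <- .bulged_objects(s)
  m <- length(objs)
  if (m < 4L) return(.hits_df(list()))
  starts <- vapply(objs, `[[`, integer(1L), "start")
  ends <- vapply(objs, `[[`, integer(1L), "end")
  comp <- vapply(objs, `[[`, logical(1L), "comp")
  rows <- list()
  extend <- function(path, ncomp) {
    k <- length(path)
    if (k == 4L) {
      if (ncomp == 1L) {
        idx <- path
        rows[[length(rows) + 1L]] <<- list(
          start = starts[idx[1L]], end = ends[idx[4L]], strand = "+",
          n_tracts = 4L, variant_class = "bulged",
          tract_starts = starts[idx], tract_ends = ends[idx],
          spacers = starts[idx[-1L]] - ends[idx[-4L]]
        )
      }
      return(invisible(NULL))
    }
    last <- path[k]
    nxt <- which(starts > ends[last] & starts <= ends[last] + 7L)
    for (j in nxt) {
      nc <- ncomp + comp[j]
      if (nc > 1L) next
      if (!.bulged_loop_ok(s, ends[last], starts[j])) next
      extend(c(path, j), nc)
    }
    invisible(NULL)
  }
  for (i in seq_len(m)) extend(i, as.integer(comp[i]))
  .select_windows(rows)
}

#' Scan both strands of a sequence for a PQS class
#'
#' G-rich grammars are scanned on the given sequence and on its reverse
#' complement; minus-strand hits are reported in plus-strand coordinates
#' with `strand = "-"`. Hits are non-overlapping within one strand.
#'
#' Classes: `canonical4G` (>= 4 maximal G3+ tracts, loops 1-7),
#' `twoQuartet` (>= 4 G2+ tracts, loops 1-7), `GVBQ` (four tracts, exactly
#' one GG among three G3+, loops 1-7), `longLoop15` (>= 4 G3+ tracts,
#' loops 1-15 with at least one loop >= 8, so disjoint from
#' `canonical4G`), `bulged` (four G3+-equivalent tracts of which exactly
#' one is split by a 1-3 nt non-G bulge).
#'
#' @param seq DNA string.
#' @param variant_class One of `"canonical4G"`, `"twoQuartet"`, `"GVBQ"`,
#'   `"longLoop15"`, `"bulged"`.
#' @return Hit `data.frame` as in [scan_units()]; coordinates on the
#'   scanned (+) strand, `strand` giving the G-rich strand.
#' @examples
#' scan_pqs("GGGTTAGGGTTAGGGTTAGGG", "canonical4G")
#' @export
scan_pqs <- function(seq, variant_class) {
  variant_class <- match.arg(variant_class, .pqs_classes)
  s <- .check_seq(seq)
  L <- nchar(s)
  plus <- .scan_g_class(s, variant_class)
  minus <- .scan_g_class(revcomp(s), variant_class)
  if (nrow(minus) > 0L) {
    new_start <- L - minus$end
    new_end <- L - minus$start
    ts <- lapply(seq_len(nrow(minus)), function(i) rev(L - minus$tract_ends[[i]]))
    te <- lapply(seq_len(nrow(minus)), function(i) rev(L - minus$tract_starts[[i]]))
    sp <- lapply(minus$spacers, rev)
    minus$start <- new_start
    minus$end <- new_end
    minus$tract_starts <- I(ts)
    minus$tract_ends <- I(te)
    minus$spacers <- I(sp)
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  out[order(out$start, out$strand), , drop = FALSE]
}

# ---- conversion -------------------------------------------------------

#' Convert motif hits to a genomic peak set
#'
#' @param hits Hit `data.frame` from a scan of one sequence.
#' @param chrom Chromosome name to assign.
#' @param offset Non-negative 0-based offset of the scanned sequence on
#'   `chrom`.
#' @return Sorted `GRanges` with `name` = variant class and `score` =
#'   number of tracts.
#' @export
hits_to_peakset <- function(hits, chrom, offset = 0L) {
  stopifnot(is.data.frame(hits), is.character(chrom), length(chrom) == 1L)
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0) {
    stop("`offset` must be a non-negative integer")
  }
  offset <- as.integer(offset)
  if (nrow(hits) == 0L) return(.empty_granges())
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = hits$start + offset + 1L,
                              end = hits$end + offset),
    strand = chartr(".", "*", hits$strand),
    name = hits$variant_class,
    score = as.numeric(hits$n_tracts)
  )
  .sort_granges(gr)
}

#' Scan a genome for a motif class on both strands
#'
#' For `class = "C4"` the C-rich grammar is scanned on the forward
#' sequence and on its reverse complement (mirrored back), so a planted
#' motif is found once, on the strand carrying the C-rich pattern. Other
#' classes delegate to [scan_pqs()], which is already double-stranded.
#'
#' @param genome Named character vector of chromosome sequences (as
#'   returned by [read_fasta()] or [make_genome()]).
#' @param class `"C4"`, `"unit"`, or a PQS class accepted by [scan_pqs()].
#' @param min_tracts Minimum tract count for `class = "C4"`.
#' @return Sorted `GRanges` of hits with strand, `name` = class,
#'   `score` = tract count.
#' @export
scan_genome <- function(genome, class = "C4", min_tracts = 4L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  pieces <- lapply(names(genome), function(chrom) {
    s <- .check_seq(genome[[chrom]])
    if (class == "C4") {
      fwd <- scan_c4(s, min_tracts)
      rev_ <- scan_c4(revcomp(s), min_tracts)
      L <- nchar(s)
      if (nrow(rev_) > 0L) {
        ns <- L - rev_$end
        rev_$end <- L - rev_$start
        rev_$start <- ns
        rev_$strand <- "-"
      }
      hits <- rbind(fwd, rev_)
    } else if (class == "unit") {
      hits <- scan_units(s)
    } else {
      hits <- scan_pqs(s, class)
    }
    hits_to_peakset(hits, chrom, 0L)
  })
  .sort_granges(.bind_granges(pieces))
}
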