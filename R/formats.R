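# Readers and writers for the standard formats the workflow touches, plus
# the shared binned-coverage container. All file coordinates are 0-based
# half-open (BED convention); in-memory interval sets are GRanges.

#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T,N}` is an error. Record ids are the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per record.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L) stop("`path` must be a single path")
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  s <- chartr("U", "T", toupper(as.character(x)))
  for (i in seq_along(s)) {
    if (nchar(s[[i]]) == 0L) stop("empty record: ", ids[[i]])
    if (grepl("[^ACGTN]", s[[i]])) {
      bad <- unique(strsplit(gsub("[ACGTN]", "", s[[i]]), "", fixed = TRUE)[[1L]])
      stop("record '", ids[[i]], "' contains illegal characters: ",
           paste(bad, collapse = ", "))
    }
  }
  names(s) <- ids
  s
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

.split_bed_lines <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < min_cols) {
      stop("line ", lineno[[i]], ": expected at least ", min_cols,
           " tab-separated fields")
    }
  }
  list(fields = fields, lineno = lineno)
}

.parse_coord <- function(x, lineno, what) {
  if (!grepl("^-?[0-9]+$", x)) {
    stop("line ", lineno, ": non-integer ", what, " coordinate '", x, "'")
  }
  as.integer(x)
}

#' Read a BED3+ file as a sorted GRanges
#'
#' Intervals are validated (`0 <= start < end`, integer coordinates) and
#' returned sorted by (chrom, start, end). A sixth column is honored as
#' strand; otherwise strand is unspecified (`*`). Columns 4 and 5 populate
#' `name` and `score`.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` (1-based closed internally; exactly the BED
#'   intervals) with metadata columns `name` and `score`.
#' @export
read_bed <- function(path) {
  p <- .split_bed_lines(path, 3L)
  if (length(p$fields) == 0L) return(.empty_granges())
  n <- length(p$fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  nm <- character(n); sc <- numeric(n); strand <- character(n)
  for (i in seq_len(n)) {
    f <- p$fields[[i]]; ln <- p$lineno[[i]]
    chrom[i] <- f[[1L]]
    s0[i] <- .parse_coord(f[[2L]], ln, "start")
    e0[i] <- .parse_coord(f[[3L]], ln, "end")
    if (s0[i] < 0L) stop("line ", ln, ": negative start coordinate")
    if (e0[i] <= s0[i]) stop("line ", ln, ": end <= start")
    nm[i] <- if (length(f) >= 4L) f[[4L]] else "."
    sc[i] <- if (length(f) >= 5L && f[[5L]] != ".") {
      v <- suppressWarnings(as.numeric(f[[5L]]))
      if (is.na(v)) stop("line ", ln, ": non-numeric score '", f[[5L]], "'")
      v
    } else 0
    strand[i] <- if (length(f) >= 6L) {
      if (!f[[6L]] %in% c("+", "-", ".")) {
        stop("line ", ln, ": invalid strand '", f[[6L]], "'")
      }
      f[[6L]]
    } else "."
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = s0 + 1L, end = e0),
    strand = chartr(".", "*", strand),
    name = nm, score = sc
  )
  .sort_granges(gr)
}

#' Write a GRanges to a BED6 file
#'
#' Round trips with [read_bed()] are the identity on
#' (chrom, start, end, strand) as well as name and score.
#'
#' @param peaks A `GRanges`; metadata columns `name` and `score` are used
#'   when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(methods::is(peaks, "GRanges"))
  mc <- S4Vectors::mcols(peaks)
  nm <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", length(peaks))
  sc <- if ("score" %in% names(mc)) as.numeric(mc$score) else rep(0, length(peaks))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = nm,
    score = sc,
    strand = chartr("*", ".", as.character(GenomicRanges::strand(peaks))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a `chrom<TAB>length` table.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  if (any(tb$size <= 0L)) stop("chromosome sizes must be positive")
  stats::setNames(tb$size, tb$chrom)
}

#' Fixed-bin coverage track
#'
#' A `binned_track` holds one non-negative coverage value per fixed-width
#' genomic bin. The trailing partial bin of each chromosome is dropped, so
#' every bin has exactly `bin_size` bp and chromosome `c` has
#' `floor(seqlengths[c] / bin_size)` bins.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin width in bp.
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, seqlengths) {
  stopifnot(is.list(values), !is.null(names(values)),
            is.numeric(bin_size), length(bin_size) == 1L, bin_size >= 1,
            is.numeric(seqlengths), !is.null(names(seqlengths)))
  bin_size <- as.integer(bin_size)
  if (!setequal(names(values), names(seqlengths))) {
    stop("names of `values` and `seqlengths` must match")
  }
  values <- values[names(seqlengths)]
  for (chrom in names(values)) {
    v <- values[[chrom]]
    nb <- seqlengths[[chrom]] %/% bin_size
    if (length(v) != nb) {
      stop("chromosome ", chrom, ": expected ", nb, " bins, got ", length(v))
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("chromosome ", chrom, ": bin values must be finite and >= 0")
    }
  }
  structure(list(values = values, bin_size = bin_size,
                 seqlengths = stats::setNames(as.integer(seqlengths),
                                              names(seqlengths))),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- sum(vapply(x$values, length, integer(1L)))
  cat("binned_track:", length(x$values), "chromosome(s),",
      nb, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

# GRanges of the bins of a track (used for blacklist overlap).
.track_bins_granges <- function(track) {
  bs <- track$bin_size
  pieces <- lapply(names(track$values), function(chrom) {
    nb <- length(track$values[[chrom]])
    if (nb == 0L) return(NULL)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = (seq_len(nb) - 1L) * bs + 1L, width = bs))
  })
  do.call(c, pieces[!vapply(pieces, is.null, logical(1L))])
}

#' Read a bedGraph file onto fixed bins
#'
#' Segment values are regridded onto fixed `bin_size` bins by
#' coverage-weighted mean, with uncovered basepairs contributing zero, so
#' total mass (value x covered width) is conserved on fully covered
#' regions. Overlapping segments on one chromosome are an error.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes) {
  p <- .split_bed_lines(path, 4L)
  bin_size <- as.integer(bin_size)
  n <- length(p$fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n); val <- numeric(n)
  for (i in seq_len(n)) {
    f <- p$fields[[i]]; ln <- p$lineno[[i]]
    chrom[i] <- f[[1L]]
    s0[i] <- .parse_coord(f[[2L]], ln, "start")
    e0[i] <- .parse_coord(f[[3L]], ln, "end")
    val[i] <- suppressWarnings(as.numeric(f[[4L]]))
    if (is.na(val[i])) stop("line ", ln, ": non-numeric value '", f[[4L]], "'")
    if (val[i] < 0) stop("line ", ln, ": negative coverage value")
    if (s0[i] < 0L || e0[i] <= s0[i]) stop("line ", ln, ": invalid interval")
    if (!chrom[i] %in% names(chrom_sizes)) {
      stop("line ", ln, ": unknown chromosome '", chrom[i], "'")
    }
    if (e0[i] > chrom_sizes[[chrom[i]]]) {
      stop("line ", ln, ": interval exceeds chromosome length")
    }
  }
  values <- lapply(names(chrom_sizes), function(cr) {
    nb <- chrom_sizes[[cr]] %/% bin_size
    v <- numeric(nb)
    idx <- which(chrom == cr)
    if (length(idx) == 0L || nb == 0L) return(v)
    idx <- idx[order(s0[idx])]
    ss <- s0[idx]; ee <- e0[idx]; vv <- val[idx]
    if (length(idx) > 1L && any(ss[-1L] < ee[-length(ee)])) {
      stop("overlapping bedGraph segments on chromosome ", cr)
    }
    # clip to the full-bin region (trailing partial bin dropped)
    lim <- nb * bin_size
    ee <- pmin(ee, lim)
    keep <- ss < ee
    ss <- ss[keep]; ee <- ee[keep]; vv <- vv[keep]
    if (length(ss) == 0L) return(v)
    i0 <- ss %/% bin_size
    i1 <- (ee - 1L) %/% bin_size
    nper <- i1 - i0 + 1L
    bi <- sequence(nper) - 1L + rep(i0, nper)
    ov <- pmin(rep(ee, nper), (bi + 1L) * bin_size) -
      pmax(rep(ss, nper), bi * bin_size)
    mass <- rowsum(rep(vv, nper) * ov, group = bi)
    v[as.integer(rownames(mass)) + 1L] <- mass[, 1L] / bin_size
    v
  })
  names(values) <- names(chrom_sizes)
  binned_track(values, bin_size, chrom_sizes)
}

#' Write a binned track as a bedGraph file
#'
#' Runs of equal-valued bins are merged into single segments; zero-valued
#' bins are omitted (they read back as zero).
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  bs <- track$bin_size
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                       starts[keep] * bs, ends[keep] * bs,
                       format(r$values[keep], scientific = FALSE, trim = TRUE)),
               con)
  }
  invisible(path)
}

#' Load a TSS table from a BED-like gene file
#'
#' The transcription start site of a `+` gene is its start coordinate; for
#' a `-` gene it is `end - 1` (0-based, half-open convention). A strand
#' column is mandatory.
#'
#' @param path Path to a BED6-like gene table (name in column 4, strand in
#'   column 6).
#' @return `data.frame` with columns `chrom`, `tss` (0-based position),
#'   `strand`, `gene`.
#' @export
load_tss <- function(path) {
  p <- .split_bed_lines(path, 3L)
  n <- length(p$fields)
  if (n == 0L) {
    return(data.frame(chrom = character(0), tss = integer(0),
                      strand = character(0), gene = character(0)))
  }
  chrom <- character(n); tss <- integer(n); strand <- character(n); gene <- character(n)
  for (i in seq_len(n)) {
    f <- p$fields[[i]]; ln <- p$lineno[[i]]
    if (length(f) < 6L) stop("line ", ln, ": strand column (6) is required")
    if (!f[[6L]] %in% c("+", "-")) {
      stop("line ", ln, ": gene strand must be '+' or '-'")
    }
    s0 <- .parse_coord(f[[2L]], ln, "start")
    e0 <- .parse_coord(f[[3L]], ln, "end")
    if (s0 < 0L || e0 <= s0) stop("line ", ln, ": invalid interval")
    chrom[i] <- f[[1L]]
    strand[i] <- f[[6L]]
    tss[i] <- if (f[[6L]] == "+") s0 else e0 - 1L
    gene[i] <- f[[4L]]
  }
  data.frame(chrom = chrom, tss = tss, strand = strand, gene = gene,
             stringsAsFactors = FALSE)
}
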