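# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Normalize and validate a single DNA sequence string: uppercase, U -> T,
# alphabet restricted to A/C/G/T/N.
.check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single character string")
  }
  s <- chartr("U", "T", toupper(seq))
  if (nchar(s) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", s)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", s), "", fixed = TRUE)[[1L]])
    stop("illegal characters in sequence: ", paste(bad, collapse = ", "))
  }
  s
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`
#'   (case-insensitive; `U` is read as `T`).
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' revcomp("GGGTTAGGG")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  s <- vapply(seq, .check_seq, character(1L), USE.NAMES = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Sorted GRanges in (chrom, start, end) order with alphabetical seqlevels.
.sort_granges <- function(gr) {
  if (length(gr) == 0L) return(gr)
  GenomeInfoDb_levels <- sort(unique(as.character(GenomicRanges::seqnames(gr))))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(as.character(GenomicRanges::seqnames(gr)),
                      levels = GenomeInfoDb_levels),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    S4Vectors::mcols(gr)
  )
  ord <- order(as.integer(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[ord]
}

# Concatenate GRanges that may live on disjoint seqlevel sets.
.bind_granges <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1L))]
  lst <- lst[vapply(lst, length, integer(1L)) > 0L]
  if (length(lst) == 0L) return(.empty_granges())
  if (length(lst) == 1L) return(lst[[1L]])
  suppressWarnings(do.call(c, lst))  # disjoint seqlevels are expected here
}

.empty_granges <- function() {
  GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(), strand = character(0),
    name = character(0), score = numeric(0)
  )
}
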