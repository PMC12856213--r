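# Independent oracles used to cross-check the package implementation.
# These deliberately take a different computational route: run finding via
# rle() over character vectors (the package scanners use regex matching),
# explicit loop-based enumeration of candidate windows, and a root-finding
# equilibrium solver for the binding model.

# ---- sequences --------------------------------------------------------

random_seq <- function(n, probs = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

oracle_runs <- function(seq, base, min_len) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == base & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

oracle_spacer <- function(seq, e, s) substr(seq, e + 1L, s)

oracle_gap_ok <- function(seq, e, s, loop_min, loop_max) {
  g <- s - e
  g >= loop_min && g <= loop_max &&
    !grepl("N", oracle_spacer(seq, e, s), fixed = TRUE)
}

# Maximal chains of tracts under a loop-length bound; one hit per chain
# with >= min_tracts tracts (optionally filtered on its loop lengths).
oracle_chain_hits <- function(seq, base, min_run, loop_min, loop_max,
                              min_tracts, gap_filter = NULL) {
  tr <- oracle_runs(seq, base, min_run)
  n <- nrow(tr)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && oracle_gap_ok(seq, tr$end[j], tr$start[j + 1L],
                                  loop_min, loop_max)) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_tracts) {
      gaps <- if (j > i) tr$start[(i + 1L):j] - tr$end[i:(j - 1L)] else integer(0)
      if (is.null(gap_filter) || gap_filter(gaps)) {
        out[[length(out) + 1L]] <- data.frame(start = tr$start[i],
                                              end = tr$end[j],
                                              n_tracts = j - i + 1L)
      }
    }
    i <- j + 1L
  }
  if (length(out) == 0L) {
    data.frame(start = integer(0), end = integer(0), n_tracts = integer(0))
  } else do.call(rbind, out)
}

# Greedy non-overlap selection over candidate windows: leftmost start,
# longer span on ties.
oracle_select <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$start, -cand$end), , drop = FALSE]
  sel <- list()
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      sel[[length(sel) + 1L]] <- cand[i, , drop = FALSE]
      last_end <- cand$end[i]
    }
  }
  do.call(rbind, sel)
}

# G-vacancy windows: four consecutive G2+ runs with 1-7 nt loops, exactly
# one run of length 2, the rest >= 3.
oracle_gvbq <- function(seq) {
  tr <- oracle_runs(seq, "G", 2L)
  n <- nrow(tr)
  cand <- list()
  if (n >= 4L) {
    for (i in 1L:(n - 3L)) {
      ok <- TRUE
      for (k in i:(i + 2L)) {
        if (!oracle_gap_ok(seq, tr$end[k], tr$start[k + 1L], 1L, 7L)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      lens <- tr$length[i:(i + 3L)]
      if (sum(lens == 2L) == 1L && sum(lens >= 3L) == 3L) {
        cand[[length(cand) + 1L]] <- data.frame(start = tr$start[i],
                                                end = tr$end[i + 3L],
                                                n_tracts = 4L)
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), n_tracts = integer(0)))
  }
  oracle_select(do.call(rbind, cand))
}

# Bulged windows: tract objects are intact G3+ runs plus composites (two
# maximal G runs split by a 1-3 nt non-G bulge, combined length >= 3, at
# least one side < 3); windows of four objects with 1-7 nt loops that
# contain no N and no intact G3+ run, exactly one composite.
oracle_bulged_objects <- function(seq) {
  runs <- oracle_runs(seq, "G", 1L)
  n <- nrow(runs)
  objs <- list()
  for (i in seq_len(n)) {
    if (runs$length[i] >= 3L) {
      objs[[length(objs) + 1L]] <- c(start = runs$start[i], end = runs$end[i],
                                     comp = 0L)
    }
  }
  if (n >= 2L) {
    for (i in 1L:(n - 1L)) {
      b <- runs$start[i + 1L] - runs$end[i]
      sp <- oracle_spacer(seq, runs$end[i], runs$start[i + 1L])
      if (b >= 1L && b <= 3L && !grepl("N", sp, fixed = TRUE) &&
          runs$length[i] + runs$length[i + 1L] >= 3L &&
          min(runs$length[i], runs$length[i + 1L]) <= 2L) {
        objs[[length(objs) + 1L]] <- c(start = runs$start[i],
                                       end = runs$end[i + 1L], comp = 1L)
      }
    }
  }
  if (length(objs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), comp = integer(0)))
  }
  d <- as.data.frame(do.call(rbind, objs))
  d[order(d$start, d$end), , drop = FALSE]
}

oracle_bulged <- function(seq) {
  objs <- oracle_bulged_objects(seq)
  m <- nrow(objs)
  empty <- data.frame(start = integer(0), end = integer(0), n_tracts = integer(0))
  if (m < 4L) return(empty)
  loop_ok <- function(e, s) {
    g <- s - e
    sp <- oracle_spacer(seq, e, s)
    g >= 1L && g <= 7L && !grepl("N", sp, fixed = TRUE) &&
      !grepl("GGG", sp, fixed = TRUE)
  }
  succ <- lapply(seq_len(m), function(i) {
    Filter(function(j) objs$start[j] > objs$end[i] && loop_ok(objs$end[i], objs$start[j]),
           seq_len(m))
  })
  cand <- list()
  for (i in seq_len(m)) {
    for (j in succ[[i]]) {
      for (k in succ[[j]]) {
        for (l in succ[[k]]) {
          if (objs$comp[i] + objs$comp[j] + objs$comp[k] + objs$comp[l] == 1L) {
            cand[[length(cand) + 1L]] <- data.frame(start = objs$start[i],
                                                    end = objs$end[l],
                                                    n_tracts = 4L)
          }
        }
      }
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- unique(do.call(rbind, cand))
  oracle_select(cand)
}

oracle_g_class <- function(seq, class) {
  switch(class,
    canonical4G = oracle_chain_hits(seq, "G", 3L, 1L, 7L, 4L),
    twoQuartet = oracle_chain_hits(seq, "G", 2L, 1L, 7L, 4L),
    longLoop15 = oracle_chain_hits(seq, "G", 3L, 1L, 15L, 4L,
                                   gap_filter = function(g) any(g >= 8L)),
    GVBQ = oracle_gvbq(seq),
    bulged = oracle_bulged(seq)
  )
}

oracle_revcomp <- function(seq) {
  ch <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[ch], collapse = "")
}

# Both-strand PQS oracle in plus-strand coordinates.
oracle_scan_pqs <- function(seq, class) {
  L <- nchar(seq)
  plus <- oracle_g_class(seq, class)
  if (nrow(plus) > 0L) plus$strand <- "+"
  minus <- oracle_g_class(oracle_revcomp(seq), class)
  if (nrow(minus) > 0L) {
    ns <- L - minus$end
    minus$end <- L - minus$start
    minus$start <- ns
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  if (nrow(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_tracts = integer(0), strand = character(0)))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

oracle_scan_c4 <- function(seq, min_tracts) {
  oracle_chain_hits(seq, "C", 3L, 1L, 7L, min_tracts)
}

# ---- binding model ----------------------------------------------------

# Mass-action equilibrium for the 1:1 complex: solve
# (T0 - B)(X - B) = Kd * B for the complex concentration B by bracketed
# root finding plus Newton polish, and return the bound fraction B / T0.
oracle_bound_fraction <- function(T0, X, Kd) {
  if (X == 0) return(0)
  f <- function(B) (T0 - B) * (X - B) - Kd * B
  up <- min(T0, X)
  B <- stats::uniroot(f, c(0, up), tol = 1e-14 * max(1, up))$root
  for (i in 1:4) {
    fp <- -(X - B) - (T0 - B) - Kd
    step <- f(B) / fp
    if (!is.finite(step)) break
    B <- B - step
  }
  B / T0
}

# ---- intervals --------------------------------------------------------

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

oracle_overlap_fraction <- function(a, b, min_bp = 1L) {
  A <- gr_to_df(a); B <- gr_to_df(b)
  hit <- logical(nrow(A))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      if (A$chrom[i] != B$chrom[j]) next
      ov <- min(A$end[i], B$end[j]) - max(A$start[i], B$start[j])
      if (ov >= min_bp) {
        hit[i] <- TRUE
        break
      }
    }
  }
  mean(hit)
}

oracle_upset <- function(sets) {
  all_df <- do.call(rbind, lapply(sets, gr_to_df))
  merged <- list()
  for (chrom in sort(unique(all_df$chrom))) {
    d <- all_df[all_df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_s <- d$start[1L]; cur_e <- d$end[1L]
    for (i in seq_len(nrow(d))[-1L]) {
      if (d$start[i] <= cur_e) {  # book-ended intervals merge (bedtools default)
        cur_e <- max(cur_e, d$end[i])
      } else {
        merged[[length(merged) + 1L]] <- c(chrom = chrom, start = cur_s, end = cur_e)
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(chrom = chrom, start = cur_s, end = cur_e)
  }
  counts <- list()
  for (mi in merged) {
    members <- character(0)
    for (nm in names(sets)) {
      d <- gr_to_df(sets[[nm]])
      touch <- FALSE
      for (j in seq_len(nrow(d))) {
        if (d$chrom[j] == mi[["chrom"]] &&
            min(as.integer(mi[["end"]]), d$end[j]) -
            max(as.integer(mi[["start"]]), d$start[j]) >= 1L) {
          touch <- TRUE
          break
        }
      }
      if (touch) members <- c(members, nm)
    }
    key <- paste(members, collapse = "&")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random peak set on one chromosome, possibly overlapping intervals.
random_peaks <- function(n, chrom_len, max_width = 500L, chrom = "chr1") {
  s <- sample.int(chrom_len - max_width, n)
  w <- sample.int(max_width - 1L, n) + 1L
  c4kit:::.sort_granges(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = s + 1L, width = w), name = ".", score = 0
  ))
}

hits_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  strand <- if ("strand" %in% names(df)) df$strand else "+"
  sort(paste(df$start, df$end, strand, df$n_tracts, sep = ":"))
}
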