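#' Intra-genomic repeat detection and assembly-difficulty classification
#'
#' Bacterial genomes differ widely in how hard they are to assemble from long
#' reads, and the decisive factor is the intra-genomic repeat structure: the
#' number of repeated locus pairs and, above all, the length of the longest
#' repeat relative to the multi-copy rDNA operon (typically 6-7 kb). These
#' functions detect repeat pairs above length/identity thresholds by k-mer
#' seeded self-comparison and classify genomes into difficulty classes
#' I/II/III.
#'
#' @name repeat_complexity
NULL

# -- diagonal machinery -------------------------------------------------------

# Matches along the diagonal pairing x[i] with y[i + d]; N never matches.
diagonal_matches <- function(xc, yc, d) {
  nx <- length(xc); ny <- length(yc)
  i0 <- max(1L, 1L - d)
  i1 <- min(nx, ny - d)
  if (i1 - i0 + 1L < 1L) return(NULL)
  ii <- i0:i1
  a <- xc[ii]; b <- yc[ii + d]
  list(offset = i0 - 1L, m = a == b & a != "N" & b != "N",
       nbar = a == "N" | b == "N")
}

# Maximum-scoring segment of the logical match vector m under match = +1,
# mismatch = -penalty scoring. The mild penalty (default 3) lets extension
# run through the occasional mismatch inside a diverged repeat copy while
# unrelated flanking sequence (~25% identity) has strongly negative drift and
# stops extension, like an aligner's X-drop. Segment endpoints are always
# matches. Ties: longer segment, then smaller start.
max_scoring_segment <- function(m, penalty = 3) {
  v <- ifelse(m, 1, -penalty)
  pre <- cumsum(v)
  pre0 <- c(0, pre[-length(pre)])
  pm <- cummin(pre0)                    # min prefix strictly before j
  gains <- pre - pm
  best <- max(gains)
  if (best <= 1e-9) return(NULL)
  ends <- which(gains >= best - 1e-9)
  # for each candidate end, segment starts where the prefix minimum occurred
  pre_full <- c(0, pre)
  starts <- vapply(ends, function(j) {
    which(abs(pre_full[1:j] - pm[j]) <= 1e-9)[1]
  }, integer(1))
  lens <- ends - starts + 1L
  pick <- which(lens == max(lens))
  pick <- pick[which.min(starts[pick])]
  c(start = starts[pick], end = ends[pick], score = best)
}

# All disjoint maximal positive-scoring segments that pass both the length
# and the identity threshold (identity = matches / columns on the final
# segment), via recursive max-subarray decomposition. Recursion into the
# flanks continues while extracted segments are at least min_len long, so
# several repeats sharing one diagonal are all found; sub-min_len score blips
# in unrelated sequence terminate it.
qualifying_segments <- function(m, min_len, min_id, penalty = 3) {
  out <- list()
  queue <- list(c(1L, length(m)))
  while (length(queue)) {
    rng <- queue[[1]]; queue <- queue[-1]
    lo <- rng[1]; hi <- rng[2]
    if (hi - lo + 1L < min_len) next
    seg <- max_scoring_segment(m[lo:hi], penalty)
    if (is.null(seg)) next
    s <- lo + seg[["start"]] - 1L; e <- lo + seg[["end"]] - 1L
    if (e - s + 1L >= min_len) {
      if (mean(m[s:e]) >= min_id - 1e-9) {
        out[[length(out) + 1L]] <- c(s, e)
      }
      queue <- c(queue, list(c(lo, s - 1L)), list(c(e + 1L, hi)))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Break a diagonal at runs of >= n_break consecutive N columns and extract
# qualifying segments per chunk.
diagonal_repeat_segments <- function(dm, min_len, min_id, n_break = 10L) {
  m <- dm$m
  r <- rle(dm$nbar)
  cut <- r$values & r$lengths >= n_break
  segs <- NULL
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  chunk_start <- 1L
  bounds <- list()
  for (q in seq_along(r$lengths)) {
    if (cut[q]) {
      if (starts[q] - 1L >= chunk_start) {
        bounds[[length(bounds) + 1L]] <- c(chunk_start, starts[q] - 1L)
      }
      chunk_start <- ends[q] + 1L
    }
  }
  if (chunk_start <= length(m)) {
    bounds[[length(bounds) + 1L]] <- c(chunk_start, length(m))
  }
  for (b in bounds) {
    ss <- qualifying_segments(m[b[1]:b[2]], min_len, min_id)
    if (!is.null(ss)) segs <- rbind(segs, ss + b[1] - 1L)
  }
  segs
}

# k-mer position table (kmer, pos), N-containing k-mers excluded.
kmer_index <- function(chars, k) {
  n <- length(chars)
  if (n < k) {
    return(data.frame(kmer = character(0), pos = integer(0)))
  }
  s <- paste(chars, collapse = "")
  pos <- 1:(n - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  data.frame(kmer = km[keep], pos = pos[keep], stringsAsFactors = FALSE)
}

# Candidate diagonals from shared k-mers between two indexed sequences
# (vectorized join; one entry per distinct offset).
seeded_diagonals <- function(ix, iy, same = FALSE) {
  m <- merge(ix, iy, by = "kmer")
  ds <- unique(m$pos.y - m$pos.x)
  if (same) ds <- ds[ds > 0L]          # self-diagonal and mirror image excluded
  sort(ds)
}

segments_to_pairs <- function(segs, dm_offset, d, rep_a, rep_b, n_b,
                              orientation) {
  if (is.null(segs)) return(NULL)
  out <- lapply(seq_len(nrow(segs)), function(r) {
    i <- segs[r, 1] + dm_offset        # 1-based column index in x
    j <- segs[r, 2] + dm_offset
    len <- j - i + 1L
    a_start <- i - 1L; a_end <- j      # 0-based half-open in x
    if (orientation == "forward") {
      b_start <- i + d - 1L; b_end <- j + d
    } else {
      # y was revcomp(b): y position p maps to b position n_b - p (0-based)
      b_start <- n_b - (j + d)
      b_end <- n_b - (i + d) + 1L
    }
    data.frame(replicon_a = rep_a, a_start = a_start, a_end = a_end,
               replicon_b = rep_b, b_start = b_start, b_end = b_end,
               orientation = orientation, aln_length = len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

compare_pair <- function(xc, yc, ix, iy, rep_a, rep_b, same, orientation,
                         min_len, min_id) {
  ds <- seeded_diagonals(ix, iy, same = same)
  res <- NULL
  for (d in ds) {
    dm <- diagonal_matches(xc, yc, d)
    if (is.null(dm) || length(dm$m) < min_len) next
    segs <- diagonal_repeat_segments(dm, min_len, min_id)
    pp <- segments_to_pairs(segs, dm$offset, d, rep_a, rep_b,
                            n_b = length(yc), orientation = orientation)
    if (!is.null(pp)) {
      ident <- vapply(seq_len(nrow(segs)), function(r) {
        mean(dm$m[segs[r, 1]:segs[r, 2]])
      }, numeric(1))
      pp$identity <- ident
      res <- rbind(res, pp)
    }
  }
  res
}

canonicalize_pairs <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  swap <- df$replicon_a > df$replicon_b |
    (df$replicon_a == df$replicon_b & df$a_start > df$b_start)
  if (any(swap)) {
    tmp <- df[swap, c("replicon_b", "b_start", "b_end")]
    df[swap, c("replicon_b", "b_start", "b_end")] <-
      df[swap, c("replicon_a", "a_start", "a_end")]
    df[swap, c("replicon_a", "a_start", "a_end")] <- tmp
  }
  self <- df$replicon_a == df$replicon_b &
    df$a_start == df$b_start & df$a_end == df$b_end
  df <- df[!self, , drop = FALSE]
  df <- unique(df)
  df[order(df$replicon_a, df$a_start, df$b_start, df$orientation), ,
     drop = FALSE]
}

#' Find intra-genomic repeat pairs
#'
#' Detects all pairs of distinct loci whose sequences align at or above the
#' length and identity thresholds, in forward and reverse-complement
#' orientation. Detection is k-mer seeded: diagonals sharing an exact k-mer
#' are scanned exhaustively and, per diagonal, the maximal positive-scoring
#' segments under match +1 / mismatch -id/(1-id) scoring are reported
#' (disjoint, best-first), then filtered to length >= \code{min_length}; a
#' segment scores positive exactly when its identity (matches / alignment
#' columns) exceeds \code{min_identity}, and extension past a repeat boundary
#' stops like an aligner's X-drop. Alignments contained in a longer reported
#' alignment of the same locus pair are thereby discarded. Ns never match and
#' alignments are broken at runs of 10 or more Ns.
#'
#' @param genome named character vector, list, or
#'   [Biostrings::DNAStringSet] of replicon sequences.
#' @param min_length minimum alignment length in bp (default 500).
#' @param min_identity minimum identity fraction (default 0.95).
#' @param scope `"per_replicon"` compares each replicon against itself only
#'   (the convention used when chromosome repeat content is reported
#'   separately from plasmids); `"combined"` also compares replicons against
#'   each other.
#' @param k seed k-mer size (default 21).
#' @param rotate if `TRUE`, each replicon is virtually doubled so that
#'   repeats spanning the origin of a circular sequence are caught; loci are
#'   reported modulo the replicon length.
#' @return data.frame with columns `replicon_a`, `a_start`, `a_end`,
#'   `replicon_b`, `b_start`, `b_end`, `orientation`, `aln_length`,
#'   `identity`. Coordinates are 0-based half-open; pairs are canonically
#'   ordered (`a_start <= b_start`) and sorted.
#' @export
find_repeat_pairs <- function(genome, min_length = 500L, min_identity = 0.95,
                              scope = c("per_replicon", "combined"),
                              k = 21L, rotate = FALSE) {
  scope <- match.arg(scope)
  reps <- as_replicons(genome)
  stopifnot(min_length >= k, min_identity > 0, min_identity <= 1)
  base_len <- nchar(reps)
  if (rotate) reps <- setNames(paste0(reps, reps), names(reps))

  chars <- lapply(reps, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  rc_chars <- lapply(reps, function(s) strsplit(revcomp(s), "")[[1]])
  idx <- lapply(chars, kmer_index, k = k)
  rc_idx <- lapply(rc_chars, kmer_index, k = k)

  out <- NULL
  rn <- names(reps)
  for (a in seq_along(rn)) {
    # self, forward
    out <- rbind(out, compare_pair(chars[[a]], chars[[a]], idx[[a]], idx[[a]],
                                   rn[a], rn[a], same = TRUE,
                                   orientation = "forward",
                                   min_len = min_length,
                                   min_id = min_identity))
    # self, reverse complement (pairs show up twice; deduped downstream)
    out <- rbind(out, compare_pair(chars[[a]], rc_chars[[a]], idx[[a]],
                                   rc_idx[[a]], rn[a], rn[a], same = FALSE,
                                   orientation = "reverse_complement",
                                   min_len = min_length,
                                   min_id = min_identity))
    if (scope == "combined" && a < length(rn)) {
      for (b in (a + 1L):length(rn)) {
        out <- rbind(out, compare_pair(chars[[a]], chars[[b]], idx[[a]],
                                       idx[[b]], rn[a], rn[b], same = FALSE,
                                       orientation = "forward",
                                       min_len = min_length,
                                       min_id = min_identity))
        out <- rbind(out, compare_pair(chars[[a]], rc_chars[[b]], idx[[a]],
                                       rc_idx[[b]], rn[a], rn[b],
                                       same = FALSE,
                                       orientation = "reverse_complement",
                                       min_len = min_length,
                                       min_id = min_identity))
      }
    }
  }
  empty <- data.frame(replicon_a = character(0), a_start = integer(0),
                      a_end = integer(0), replicon_b = character(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), aln_length = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  if (rotate) {
    n <- base_len[out$replicon_a]
    # keep each origin-wrapped pair once, anchored in the first copy
    keep <- out$a_start < n
    out <- out[keep, , drop = FALSE]
    nb <- base_len[out$replicon_b]
    wrap <- out$b_start >= nb
    out$b_start[wrap] <- out$b_start[wrap] - nb[wrap]
    out$b_end[wrap] <- out$b_end[wrap] - nb[wrap]
  }
  out <- canonicalize_pairs(out)
  rownames(out) <- NULL
  out
}

#' Summarize repeat pairs into a per-genome profile
#'
#' @param pairs data.frame from [find_repeat_pairs()].
#' @param genome_id label for the genome.
#' @param rdna_ceiling,count_threshold passed to [classify_complexity()].
#' @return one-row data.frame: `genome_id`, `n_pairs`, `max_len`,
#'   `complexity_class`.
#' @export
summarize_repeats <- function(pairs, genome_id, rdna_ceiling = 7000L,
                              count_threshold = 100L) {
  n_pairs <- if (is.null(pairs)) 0L else nrow(pairs)
  max_len <- if (n_pairs == 0L) 0L else max(pairs$aln_length)
  data.frame(genome_id = genome_id, n_pairs = n_pairs, max_len = max_len,
             complexity_class = classify_complexity(n_pairs, max_len,
                                                    rdna_ceiling,
                                                    count_threshold),
             stringsAsFactors = FALSE)
}

#' Classify genome assembly difficulty from its repeat profile
#'
#' Class III: the longest repeat exceeds the rDNA-operon ceiling (such
#' repeats can only be resolved with very long reads). Class II: more than
#' `count_threshold` repeat pairs but none longer than the ceiling. Class I:
#' everything else (few repeats, longest at most rDNA-operon sized).
#'
#' @param n_pairs number of repeat pairs (vectorized).
#' @param max_len length of the longest repeat in bp (vectorized).
#' @param rdna_ceiling rDNA-operon length ceiling in bp (default 7000).
#' @param count_threshold repeat-pair count threshold (default 100).
#' @return character vector over `"I"`, `"II"`, `"III"`.
#' @export
classify_complexity <- function(n_pairs, max_len, rdna_ceiling = 7000L,
                                count_threshold = 100L) {
  if (any(n_pairs < 0) || any(max_len < 0)) {
    stop("n_pairs and max_len must be non-negative")
  }
  ifelse(max_len > rdna_ceiling, "III",
         ifelse(n_pairs > count_threshold, "II", "I"))
}

#' Per-species summary of repeat profiles
#'
#' Groups genome repeat profiles by species, reporting the mean number of
#' repeat pairs and the per-class histogram with percentages. Species
#' represented by a single genome are excluded.
#'
#' @param profiles data.frame with columns `genome_id`, `n_pairs`,
#'   `complexity_class` (as from [summarize_repeats()]).
#' @param species_of named character vector mapping genome_id to species.
#' @return list with `species` (per-species means and class counts) and
#'   `class_percentages` (over all retained genomes).
#' @export
species_repeat_summary <- function(profiles, species_of) {
  if (is.null(profiles) || nrow(profiles) == 0L) stop("no profiles")
  miss <- setdiff(profiles$genome_id, names(species_of))
  if (length(miss)) stop("no species assigned for: ", miss[1])
  profiles$species <- unname(species_of[profiles$genome_id])
  keep <- names(which(table(profiles$species) >= 2L))
  profiles <- profiles[profiles$species %in% keep, , drop = FALSE]
  classes <- c("I", "II", "III")
  sp <- lapply(split(profiles, profiles$species), function(d) {
    cc <- table(factor(d$complexity_class, levels = classes))
    data.frame(species = d$species[1], n_genomes = nrow(d),
               mean_n_pairs = mean(d$n_pairs),
               class_I = as.integer(cc["I"]), class_II = as.integer(cc["II"]),
               class_III = as.integer(cc["III"]), stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, sp)
  rownames(sp) <- NULL
  cc_all <- table(factor(profiles$complexity_class, levels = classes))
  pct <- setNames(100 * as.vector(cc_all) / nrow(profiles), classes)
  list(species = sp, class_percentages = pct)
}

#' Write repeat pairs to TSV
#' @param pairs data.frame from [find_repeat_pairs()].
#' @param path output file.
#' @export
write_repeat_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
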