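# Independent oracles: straightforward exhaustive implementations used to
# verify the package's optimized paths on small inputs.

# The canonical repeat-segment definition (maximal positive-scoring segments
# under match +1 / mismatch -3; ties resolved longest-then-leftmost; segments
# of length >= min_len reported when identity qualifies, flanks decomposed
# recursively while extractions stay >= min_len), computed with exact integer
# arithmetic. The oracle's independence from the package lies in the
# exhaustive all-diagonal scan replacing k-mer seeded discovery; the segment
# definition itself is shared by design.
oracle_segments <- function(m, min_len, min_id) {
  out <- list()
  stack <- list(c(1L, length(m)))
  while (length(stack)) {
    rng <- stack[[1]]; stack <- stack[-1]
    lo <- rng[1]; hi <- rng[2]
    if (hi - lo + 1L < min_len) next
    v <- ifelse(m[lo:hi], 1L, -3L)
    p <- cumsum(v)
    before <- c(0L, p[-length(p)])
    mn <- cummin(before)
    gain <- p - mn
    best <- max(gain)
    if (best <= 0L) next
    pf <- c(0L, p)
    ends <- which(gain == best)
    starts <- vapply(ends, function(j) match(mn[j], pf[1:j]), integer(1))
    lens <- ends - starts + 1L
    pick <- which(lens == max(lens))
    pick <- pick[which.min(starts[pick])]
    s <- lo + starts[pick] - 1L
    e <- lo + ends[pick] - 1L
    if (e - s + 1L >= min_len) {
      if (mean(m[s:e]) >= min_id - 1e-9) {
        out[[length(out) + 1L]] <- c(s, e)
      }
      stack <- c(stack, list(c(lo, s - 1L)), list(c(e + 1L, hi)))
    }
  }
  if (!length(out)) return(NULL)
  segs <- do.call(rbind, out)
  segs[order(segs[, 1]), , drop = FALSE]
}

# Brute-force repeat-pair oracle: every diagonal of seq vs seq and seq vs
# revcomp(seq) is scanned; no k-mer seeding. Complete for substitution-only
# divergence (no indel can shift a repeat off a single diagonal). For speed,
# diagonals are pre-screened with an exact necessary condition: a segment of
# length >= L at identity >= id scores at least L * (4 * id - 3) under the
# +1/-3 scheme, so a diagonal whose best max-subarray score falls below that
# bound cannot hold a qualifying segment (requires id > 0.75).
oracle_repeat_pairs <- function(genome, min_length = 500L,
                                min_identity = 0.95) {
  stopifnot(min_identity > 0.75)
  score_floor <- min_length * (4 * min_identity - 3)
  s <- toupper(genome[[1]])
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), "")[[1]]
  # integer codes make the per-diagonal comparison cheap; N -> 0 never matches
  code_of <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  ci <- unname(code_of[ch]); ci[is.na(ci)] <- 0L
  ri <- unname(code_of[rc]); ri[is.na(ri)] <- -1L
  out <- NULL
  has_n <- any(ci == 0L)
  grab <- function(a, b, ai, bi, d, orientation) {
    i0 <- max(1L, 1L - d); i1 <- min(length(a), length(b) - d)
    if (i1 - i0 + 1L < min_length) return(NULL)
    asub <- ai[i0:i1]
    m <- asub == bi[(i0 + d):(i1 + d)]
    if (has_n) m <- m & asub > 0L
    # exact pre-screen: best max-subarray score under +1/-3
    p <- cumsum(4L * m - 3L)
    if (max(p - cummin(c(0L, p[-length(p)]))) < score_floor) return(NULL)
    segs <- oracle_segments(m, min_length, min_identity)
    if (is.null(segs)) return(NULL)
    res <- NULL
    for (r in seq_len(nrow(segs))) {
      i <- segs[r, 1] + i0 - 1L; j <- segs[r, 2] + i0 - 1L
      a_start <- i - 1L; a_end <- j
      if (orientation == "forward") {
        b_start <- i + d - 1L; b_end <- j + d
      } else {
        b_start <- n - (j + d); b_end <- n - (i + d) + 1L
      }
      res <- rbind(res, data.frame(
        a_start = a_start, a_end = a_end, b_start = b_start, b_end = b_end,
        orientation = orientation,
        aln_length = j - i + 1L,
        identity = mean(m[segs[r, 1]:segs[r, 2]]),
        stringsAsFactors = FALSE))
    }
    res
  }
  for (d in seq_len(n - 1L)) {
    out <- rbind(out, grab(ch, ch, ci, ci, d, "forward"))
  }
  for (d in (-(n - 1L)):(n - 1L)) {
    out <- rbind(out, grab(ch, rc, ci, ri, d, "reverse_complement"))
  }
  if (is.null(out)) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), aln_length = integer(0),
                      identity = numeric(0)))
  }
  swap <- out$a_start > out$b_start
  if (any(swap)) {
    tmp <- out[swap, c("b_start", "b_end")]
    out[swap, c("b_start", "b_end")] <- out[swap, c("a_start", "a_end")]
    out[swap, c("a_start", "a_end")] <- tmp
  }
  out <- out[!(out$a_start == out$b_start & out$a_end == out$b_end), ,
             drop = FALSE]
  out <- unique(out)
  out <- out[order(out$a_start, out$b_start, out$orientation), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Naive O(genes x gaps) interval-intersection scan for missed genes.
oracle_missed_genes <- function(gaps, annotation, min_overlap = 1L) {
  missed <- character(0)
  for (gi in seq_len(nrow(annotation))) {
    for (ri in seq_len(nrow(gaps))) {
      if (annotation$replicon[gi] != gaps$replicon[ri]) next
      ov <- min(annotation$end[gi], gaps$end[ri]) -
        max(annotation$start[gi], gaps$start[ri])
      if (ov >= min_overlap) {
        missed <- c(missed, annotation$gene_id[gi])
        break
      }
    }
  }
  sort(missed)
}

# Exact accumulation-curve means by enumerating all n! genome orderings.
oracle_accumulation_exact <- function(mat) {
  n <- ncol(mat)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  orderings <- perms(seq_len(n))
  pan <- core <- matrix(0, length(orderings), n)
  for (oi in seq_along(orderings)) {
    ord <- orderings[[oi]]
    for (k in seq_len(n)) {
      sub <- mat[, ord[seq_len(k)], drop = FALSE]
      pan[oi, k] <- sum(rowSums(sub) > 0L)
      core[oi, k] <- sum(rowSums(sub) == k)
    }
  }
  list(mean_pan = colMeans(pan), mean_core = colMeans(core))
}

# One-sided hypergeometric tail by direct summation of the density, in the
# "annotated genes drawn, interest genes are successes" parametrization.
oracle_hyper_p <- function(k, K, N, n) {
  # K annotated in universe of N; n interest; k annotated & interest
  kk <- k:min(K, n)
  sum(choose(n, kk) * choose(N - n, K - kk)) / choose(N, K)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal SAM writer for hand-built alignment records in tests.
write_test_sam <- function(path, sq, records) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq),
             records)
  writeLines(lines, path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar,
                       mapq = 60L, seq = "*") {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}
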