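#' Pan-genome profiling
#'
#' Protein-coding genes from a set of strain genomes are clustered at high
#' identity without paralog splitting; the resulting presence/absence matrix
#' is partitioned into core (present in all strains), accessory (a proper
#' subset of at least two) and strain-unique clusters, with randomized
#' gene-accumulation curves and COG functional cross-tabulations.
#'
#' @name pangenome
NULL

aa_words <- function(s, w = 4L) {
  n <- nchar(s)
  if (n < w) return(s)
  unique(substring(s, 1:(n - w + 1L), w:n))
}

aa_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- c(Biostrings::AA_ALPHABET)
      m <- matrix(-1L, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 2L
      mat <<- m
    }
    mat
  }
})

# Global alignment identity = matches / alignment columns (gaps included).
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = aa_submat(), gapOpening = 5, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / cols
}

# Identity check with a cheap lower bound: for equal-length sequences the
# gap-free (Hamming) identity is a valid global-alignment identity, so
# passing it decides immediately; otherwise fall back to the full alignment.
identity_at_least <- function(a, b, min_identity) {
  if (nchar(a) == nchar(b)) {
    ham <- mean(strsplit(a, "", fixed = TRUE)[[1]] ==
                  strsplit(b, "", fixed = TRUE)[[1]])
    if (ham >= min_identity - 1e-9) return(TRUE)
  }
  global_identity(a, b) >= min_identity - 1e-9
}

#' Greedy protein clustering without paralog splitting
#'
#' Proteins are sorted by length (descending, gene id ascending on ties) and
#' scanned once: each joins the first existing cluster whose representative
#' it matches at `min_identity` over a global alignment, provided the shorter
#' sequence is at least `min_coverage` of the longer; otherwise it founds a
#' new cluster. Several genes of one genome may share a cluster (paralogs are
#' not split). A short-word (4-mer) prefilter against representatives keeps
#' the scan near-linear; clusters are still verified by alignment and scanned
#' in creation order, so the greedy first-match semantics are preserved.
#'
#' @param genes data.frame with columns genome_id, gene_id, protein.
#' @param min_identity minimum identity fraction (default 0.95).
#' @param min_coverage minimum length ratio shorter/longer (default 0.90).
#' @param word_overlap_min minimum shared-word fraction for the prefilter.
#' @return data.frame: cluster_id, representative, genome_id, gene_id (one
#'   row per gene; every gene in exactly one cluster).
#' @export
cluster_proteins <- function(genes, min_identity = 0.95,
                             min_coverage = 0.90,
                             word_overlap_min = 0.4) {
  if (is.null(genes) || nrow(genes) == 0L) stop("no proteins to cluster")
  stopifnot(all(c("genome_id", "gene_id", "protein") %in% names(genes)))
  if (any(is.na(genes$protein) | !nzchar(genes$protein))) {
    stop("empty protein sequence")
  }
  ord <- order(-nchar(genes$protein), genes$gene_id)
  genes <- genes[ord, , drop = FALSE]

  rep_seq <- character(0)
  rep_len <- integer(0)
  rep_words <- list()
  word_index <- new.env(parent = emptyenv())   # word -> cluster ids
  assign_of <- integer(nrow(genes))

  for (i in seq_len(nrow(genes))) {
    p <- genes$protein[i]
    np <- nchar(p)
    words <- aa_words(p)
    # candidate clusters sharing enough words with p
    hits <- unlist(mget(words, envir = word_index,
                        ifnotfound = list(NULL)), use.names = FALSE)
    cand <- if (is.null(hits)) integer(0) else {
      tally <- tabulate(hits, nbins = length(rep_seq))
      which(tally >= word_overlap_min * length(words))
    }
    # coverage on the longer sequence; representatives are never shorter
    cand <- cand[np / rep_len[cand] >= min_coverage]
    placed <- 0L
    for (ci in sort(cand)) {              # creation order
      if (identity_at_least(p, rep_seq[ci], min_identity)) {
        placed <- ci
        break
      }
    }
    if (placed == 0L) {
      rep_seq <- c(rep_seq, p)
      rep_len <- c(rep_len, np)
      ci <- length(rep_seq)
      for (w in words) {
        word_index[[w]] <- c(word_index[[w]], ci)
      }
      placed <- ci
    }
    assign_of[i] <- placed
  }

  # representative = founding gene of each cluster
  founders <- genes$gene_id[match(seq_along(rep_seq), assign_of)]
  data.frame(cluster_id = sprintf("cluster%05d", assign_of),
             representative = founders[assign_of],
             genome_id = genes$genome_id, gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Presence/absence matrix from cluster membership
#'
#' @param clusters data.frame from [cluster_proteins()].
#' @param genome_ids optional full set of genomes (columns), for genomes that
#'   contributed no gene.
#' @return logical matrix, clusters x genomes.
#' @export
presence_absence_matrix <- function(clusters, genome_ids = NULL) {
  if (is.null(genome_ids)) genome_ids <- sort(unique(clusters$genome_id))
  ids <- unique(clusters$cluster_id)
  m <- matrix(FALSE, length(ids), length(genome_ids),
              dimnames = list(ids, genome_ids))
  m[cbind(clusters$cluster_id, clusters$genome_id)] <- TRUE
  m
}

#' Partition a presence/absence matrix into core, accessory and unique
#'
#' Core clusters occur in all genomes, unique clusters in exactly one
#' (attributed to that genome), accessory clusters in between.
#'
#' @param matrix logical presence/absence matrix (clusters x genomes).
#' @return list: `core`, `accessory`, `unique` (character vectors of cluster
#'   ids), `unique_by_genome` (named list), `counts` (named integer with
#'   pan/core/accessory/unique).
#' @export
partition <- function(matrix) {
  n <- ncol(matrix)
  rs <- rowSums(matrix)
  if (any(rs == 0L)) stop("cluster present in no genome")
  core <- rownames(matrix)[rs == n]
  uniq <- rownames(matrix)[rs == 1L]
  acc <- rownames(matrix)[rs > 1L & rs < n]
  ubg <- lapply(colnames(matrix), function(g) {
    uniq[matrix[uniq, g]]
  })
  names(ubg) <- colnames(matrix)
  list(core = core, accessory = acc, unique = uniq, unique_by_genome = ubg,
       counts = c(pan = nrow(matrix), core = length(core),
                  accessory = length(acc), unique = length(uniq)))
}

#' Randomized pan/core gene-accumulation curves
#'
#' Genomes are added in random order; after each addition the pan genome
#' (clusters in at least one genome so far) and core genome (clusters in all
#' genomes so far) are recomputed. Means over `n_iterations` random orderings
#' are reported. At the final step the values are exact regardless of order.
#'
#' @param matrix logical presence/absence matrix.
#' @param n_iterations number of random orderings (default 10).
#' @param seed integer RNG seed governing all iterations.
#' @return list: `k` (1..n), `mean_pan`, `mean_core`, `pan` and `core`
#'   (iteration x k matrices), `n_iterations`, `seed`.
#' @export
accumulation_curves <- function(matrix, n_iterations = 10L, seed = 1L) {
  n <- ncol(matrix)
  stopifnot(n >= 2L)
  set.seed(seed)
  pan <- core <- base::matrix(0L, n_iterations, n)
  for (it in seq_len(n_iterations)) {
    ord <- sample.int(n)
    cum_any <- rep(FALSE, nrow(matrix))
    cum_all <- rep(TRUE, nrow(matrix))
    for (k in seq_len(n)) {
      col <- matrix[, ord[k]]
      cum_any <- cum_any | col
      cum_all <- cum_all & col
      pan[it, k] <- sum(cum_any)
      core[it, k] <- sum(cum_all)
    }
  }
  list(k = seq_len(n), mean_pan = colMeans(pan), mean_core = colMeans(core),
       pan = pan, core = core, n_iterations = n_iterations, seed = seed)
}

#' Best-hit COG assignment
#'
#' Per gene, the hit with the smallest e-value at or below `e_max` wins
#' (ties: first row in file order); its COG category letters are assigned.
#' Genes with no qualifying hit are `"none"`.
#'
#' @param hit_table data.frame with columns gene_id, subject, e_value,
#'   cog_letters.
#' @param e_max e-value cutoff; hits above it are not considered (default
#'   0.001).
#' @return named character vector gene_id -> category letters or `"none"`.
#' @export
assign_cog <- function(hit_table, e_max = 0.001) {
  need <- c("gene_id", "e_value", "cog_letters")
  if (!all(need %in% names(hit_table))) stop("malformed hit table")
  ev <- suppressWarnings(as.numeric(hit_table$e_value))
  if (anyNA(ev)) {
    stop("malformed e-value at line ", which(is.na(ev))[1])
  }
  hit_table$e_value <- ev
  all_genes <- unique(hit_table$gene_id)
  ht <- hit_table[ev <= e_max, , drop = FALSE]
  ht <- ht[order(ht$e_value), , drop = FALSE]   # stable: ties keep file order
  best <- ht[!duplicated(ht$gene_id), , drop = FALSE]
  out <- setNames(rep("none", length(all_genes)), all_genes)
  out[best$gene_id] <- best$cog_letters
  out
}

COG_CLASSES <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O", "C", "G",
                 "E", "F", "H", "I", "P", "Q", "S")

#' COG cross-tabulation of pan-genome categories
#'
#' Each cluster is categorized via its representative gene's COG assignment;
#' multi-letter assignments count once per letter; unassigned clusters fall
#' in the "none" row. Columns are the pan-genome categories plus one column
#' per genome (counting each genome's member genes via their cluster's
#' representative).
#'
#' @param part output of [partition()].
#' @param clusters data.frame from [cluster_proteins()].
#' @param assignments named vector from [assign_cog()] (keyed by gene id).
#' @return list: `counts` (letters+none x columns), `percentages` (same
#'   shape, column percentages over the column total).
#' @export
cog_crosstab <- function(part, clusters, assignments) {
  cl_rep <- clusters[!duplicated(clusters$cluster_id),
                     c("cluster_id", "representative")]
  cl_cog <- setNames(
    ifelse(cl_rep$representative %in% names(assignments),
           unname(assignments[cl_rep$representative]), "none"),
    cl_rep$cluster_id)
  cat_of <- setNames(rep(NA_character_, length(cl_cog)), names(cl_cog))
  cat_of[part$core] <- "core"
  cat_of[part$accessory] <- "accessory"
  cat_of[part$unique] <- "unique"

  rows <- c(COG_CLASSES, "none")
  genomes <- sort(unique(clusters$genome_id))
  cols <- c(genomes, "core", "accessory", "unique")
  counts <- matrix(0L, length(rows), length(cols),
                   dimnames = list(rows, cols))
  add <- function(col, letters_vec) {
    for (letters in letters_vec) {
      if (identical(letters, "none") || is.na(letters)) {
        counts["none", col] <<- counts["none", col] + 1L
      } else {
        for (l in strsplit(letters, "", fixed = TRUE)[[1]]) {
          if (l %in% rows) counts[l, col] <<- counts[l, col] + 1L
        }
      }
    }
  }
  for (cc in c("core", "accessory", "unique")) {
    add(cc, cl_cog[names(cat_of)[!is.na(cat_of) & cat_of == cc]])
  }
  for (g in genomes) {
    gg <- clusters[clusters$genome_id == g, , drop = FALSE]
    add(g, cl_cog[gg$cluster_id])
  }
  totals <- c(vapply(genomes, function(g)
    sum(clusters$genome_id == g), integer(1)),
    core = length(part$core), accessory = length(part$accessory),
    unique = length(part$unique))
  pct <- sweep(counts, 2, pmax(totals, 1L), "/") * 100
  list(counts = counts, percentages = pct, column_totals = totals)
}

ROARY_META_COLS <- 14L

#' Read a Roary gene_presence_absence.csv into a presence/absence matrix
#'
#' The standard layout has 14 metadata columns ("Gene" ... "Avg group size
#' nuc") followed by one column per genome whose cells name the member genes
#' (empty = absent).
#'
#' @param path CSV file.
#' @return logical matrix, clusters x genomes.
#' @export
read_roary_presence_absence <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) <= ROARY_META_COLS) stop("no genome columns found")
  genomes <- names(x)[(ROARY_META_COLS + 1L):ncol(x)]
  m <- as.matrix(x[, genomes, drop = FALSE])
  pa <- !is.na(m) & nzchar(m)
  rownames(pa) <- x[[1]]
  pa
}
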