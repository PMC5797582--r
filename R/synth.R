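#' Seeded synthetic-data generators
#'
#' Every stage of the pipeline can be exercised without downloads: these
#' generators produce genomes with planted repeat families, families of
#' related strain genomes with a designed core/accessory/unique structure and
#' frameshifted pseudogenes, fabricated domain-hit tables with a planted
#' enriched GO term, read mixtures at controlled proportions, and the
#' corresponding alignments. All randomness flows from one integer seed per
#' call; outputs are byte-identical across runs. The mutation model is
#' substitution-only, which keeps expected sequence identities analytic.
#'
#' @name synth
NULL

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitution-only mutation to a different symbol of the given alphabet.
# A fixed count of round(rate * length) positions is substituted (rather than
# a Bernoulli draw per site), so the realized divergence of every copy equals
# the nominal rate and planted identities are exact, not merely expected.
mutate_string <- function(s, rate, alphabet = DNA_BASES) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- round(rate * length(ch))
  if (k == 0L) return(s)
  hit <- sample.int(length(ch), k)
  for (i in hit) {
    ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a genome with planted repeat families
#'
#' A uniform-random backbone in which each family plants `copies` copies of
#' one random template segment at non-overlapping positions; every copy after
#' the first is mutated by substitutions at `mut_rate`. `c` copies of one
#' family yield `choose(c, 2)` expected repeat pairs.
#'
#' @param backbone_length backbone length in bp.
#' @param families list of `list(copies =, length =, mut_rate =)` entries.
#' @param seed integer RNG seed.
#' @param max_tries placement retries before giving up.
#' @return list with `genome` (named character vector, one replicon `"chr"`)
#'   and `truth` (data.frame: family, copy, start, end; 0-based half-open).
#' @export
make_repeat_genome <- function(backbone_length, families = list(), seed,
                               max_tries = 1000L) {
  set.seed(seed)
  planted <- sum(vapply(families, function(f) f$copies * f$length,
                        numeric(1)))
  if (planted > backbone_length / 2) {
    stop("total planted sequence exceeds half the backbone")
  }
  backbone <- strsplit(random_dna(backbone_length), "", fixed = TRUE)[[1]]
  occupied <- logical(backbone_length)
  truth <- NULL
  for (fi in seq_along(families)) {
    f <- families[[fi]]
    template <- random_dna(f$length)
    for (ci in seq_len(f$copies)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        s <- sample.int(backbone_length - f$length + 1L, 1L)
        span <- s:(s + f$length - 1L)
        if (!any(occupied[span])) {
          copy <- if (ci == 1L) template else
            mutate_string(template, f$mut_rate)
          backbone[span] <- strsplit(copy, "", fixed = TRUE)[[1]]
          occupied[span] <- TRUE
          truth <- rbind(truth, data.frame(
            family = fi, copy = ci, start = s - 1L, end = s + f$length - 1L,
            stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place repeat copy without overlap")
    }
  }
  if (is.null(truth)) {
    truth <- data.frame(family = integer(0), copy = integer(0),
                        start = integer(0), end = integer(0))
  }
  list(genome = c(chr = paste(backbone, collapse = "")), truth = truth)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# One codon per amino acid (translation table 11), for back-translation.
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

back_translate <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste0("ATG", paste(CODON_OF[ch], collapse = ""), "TAA")
}

#' Generate a family of related strain genomes with known pan-genome truth
#'
#' Ancestral gene clusters are designed as random proteins (independent
#' between clusters, so between-cluster identity is far below any clustering
#' threshold). Core clusters are given to every strain, accessory clusters to
#' random subsets of 2..(n-1) strains, unique clusters to a single strain.
#' Each strain's copy is mutated at the amino-acid level at
#' `within_cluster_mut` (expected within-cluster identity
#' `>= 1 - 2 * within_cluster_mut`). A fraction of genes is turned into
#' frameshift pseudogenes by deleting one base at a random internal codon.
#'
#' @param n_strains number of strains.
#' @param n_core,n_accessory,n_unique_per_strain cluster counts by category.
#' @param gene_length_mean,gene_length_sd nucleotide gene length distribution
#'   (bp; rounded to whole codons, minimum 150 bp).
#' @param within_cluster_mut per-residue substitution rate applied to each
#'   strain's copy of a cluster protein (default 0.01).
#' @param pseudogene_fraction fraction of genes frameshifted into pseudogenes.
#' @param seed integer RNG seed.
#' @return list with per-strain `genes` (data.frame: genome_id, gene_id,
#'   cluster, replicon, start, end, strand, kind, nucleotide, protein),
#'   `genomes` (named character vector of concatenated strain sequences),
#'   `truth` (data.frame: cluster, category, n_present, presence) and
#'   `pseudogenes` (character vector of gene ids).
#' @export
make_strain_family <- function(n_strains, n_core, n_accessory,
                               n_unique_per_strain,
                               gene_length_mean = 900,
                               gene_length_sd = 200,
                               within_cluster_mut = 0.01,
                               pseudogene_fraction = 0, seed) {
  stopifnot(n_strains >= 2, n_accessory == 0 || n_strains >= 3)
  set.seed(seed)
  strains <- sprintf("S%02d", seq_len(n_strains))
  n_clusters <- n_core + n_accessory + n_unique_per_strain * n_strains
  lens_nt <- pmax(150, round(stats::rnorm(n_clusters, gene_length_mean,
                                          gene_length_sd)))
  lens_aa <- pmax(30L, as.integer(lens_nt %/% 3L) - 2L)

  cluster_id <- sprintf("clu%04d", seq_len(n_clusters))
  category <- c(rep("core", n_core), rep("accessory", n_accessory),
                rep("unique", n_unique_per_strain * n_strains))
  ancestral <- vapply(lens_aa, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))

  presence <- vector("list", n_clusters)
  for (i in seq_len(n_clusters)) {
    presence[[i]] <- switch(
      category[i],
      core = strains,
      # size drawn via an index so a length-one range (n_strains == 3) does
      # not trigger sample()'s scalar expansion to 1:2
      accessory = {
        sizes <- seq.int(2L, n_strains - 1L)
        sample(strains, sizes[sample.int(length(sizes), 1L)])
      },
      unique = strains[(i - n_core - n_accessory - 1L) %%
                         n_strains + 1L])
  }

  genes <- NULL
  for (i in seq_len(n_clusters)) {
    for (st in presence[[i]]) {
      prot <- mutate_string(ancestral[i], within_cluster_mut,
                            alphabet = AA20)
      genes <- rbind(genes, data.frame(
        genome_id = st, cluster = cluster_id[i], category = category[i],
        protein = prot, stringsAsFactors = FALSE))
    }
  }
  genes <- genes[order(genes$genome_id, genes$cluster), , drop = FALSE]
  genes$gene_id <- paste0(genes$genome_id, "_", genes$cluster)
  genes$nucleotide <- vapply(genes$protein, back_translate, character(1),
                             USE.NAMES = FALSE)
  genes$kind <- "CDS"

  # frameshift pseudogenes: delete 1 bp at a random internal codon
  n_pseudo <- round(pseudogene_fraction * nrow(genes))
  pseudo_idx <- if (n_pseudo > 0) sample(nrow(genes), n_pseudo) else integer(0)
  for (i in pseudo_idx) {
    nt <- genes$nucleotide[i]
    ncod <- nchar(nt) %/% 3L
    cod <- sample(2:(ncod - 1L), 1L)
    pos <- (cod - 1L) * 3L + sample(3L, 1L)
    genes$nucleotide[i] <- paste0(substr(nt, 1L, pos - 1L),
                                  substr(nt, pos + 1L, nchar(nt)))
    genes$kind[i] <- "pseudogene"
    genes$protein[i] <- NA_character_
  }

  # assemble strain sequences: genes separated by random spacers
  genomes <- character(0)
  coords <- NULL
  for (st in strains) {
    g <- genes[genes$genome_id == st, , drop = FALSE]
    pos <- 0L
    pieces <- character(0)
    for (r in seq_len(nrow(g))) {
      spacer <- random_dna(sample(50:150, 1L))
      pieces <- c(pieces, spacer, g$nucleotide[r])
      start <- pos + nchar(spacer)
      end <- start + nchar(g$nucleotide[r])
      coords <- rbind(coords, data.frame(
        gene_id = g$gene_id[r], replicon = st, start = start, end = end,
        strand = "+", stringsAsFactors = FALSE))
      pos <- end
    }
    pieces <- c(pieces, random_dna(sample(50:150, 1L)))
    genomes[st] <- paste(pieces, collapse = "")
  }
  genes <- merge(genes, coords, by = "gene_id", sort = FALSE)
  genes <- genes[order(genes$genome_id, genes$start),
                 c("genome_id", "gene_id", "cluster", "category", "replicon",
                   "start", "end", "strand", "kind", "nucleotide", "protein")]
  rownames(genes) <- NULL

  truth <- data.frame(cluster = cluster_id, category = category,
                      n_present = lengths(presence),
                      presence = vapply(presence, paste, character(1),
                                        collapse = ","),
                      stringsAsFactors = FALSE)
  list(genes = genes, genomes = genomes, truth = truth,
       pseudogenes = genes$gene_id[genes$kind == "pseudogene"])
}

#' Fabricate a small GO DAG for testing
#'
#' Builds a biological-process ontology with one root, a layer of
#' intermediate terms and `n_leaves` leaf terms, each leaf `is_a` one random
#' intermediate, each intermediate `is_a` the root.
#'
#' @param n_leaves number of leaf terms.
#' @param n_intermediate number of intermediate terms.
#' @param seed integer RNG seed.
#' @return a `go_dag` (see [go_dag()]).
#' @export
make_toy_go_dag <- function(n_leaves, n_intermediate = 5L, seed) {
  set.seed(seed)
  root <- "GO:0008150"
  mids <- sprintf("GO:%07d", 1000 + seq_len(n_intermediate))
  leaves <- sprintf("GO:%07d", 2000 + seq_len(n_leaves))
  edges <- rbind(
    data.frame(child = mids, parent = root, stringsAsFactors = FALSE),
    data.frame(child = leaves, parent = sample(mids, n_leaves, replace = TRUE),
               stringsAsFactors = FALSE))
  terms <- data.frame(
    id = c(root, mids, leaves),
    name = c("biological_process", paste0("process_", seq_along(mids)),
             paste0("leaf_process_", seq_along(leaves))),
    namespace = "BP", stringsAsFactors = FALSE)
  go_dag(terms, edges)
}

#' Fabricate domain-hit tables with a planted enriched term
#'
#' Given a strain family, emits a domain-hit table (query, domain, e_value),
#' a domain-to-GO map and a toy DAG in which one leaf term `T*` is attached
#' (via its domain) to `planted_frac_interest` of the pseudogenes but only
#' `planted_frac_background` of the intact CDSs; remaining leaf terms are
#' attached to genes uniformly at random as background.
#'
#' @param genes data.frame with columns `gene_id` and `kind` (as from
#'   [make_strain_family()]).
#' @param n_background_terms number of unenriched leaf terms.
#' @param planted_frac_interest,planted_frac_background attachment
#'   probabilities of the planted term among pseudogenes / CDSs (defaults
#'   0.8 and 0.1: odds ratio 36 by construction).
#' @param background_rate attachment probability of each background term.
#' @param seed integer RNG seed.
#' @return list: `hits` (data.frame query/domain/e_value), `domain2go`
#'   (data.frame domain/go_id), `dag`, `planted_term`.
#' @export
make_domain_hits <- function(genes, n_background_terms = 20L,
                             planted_frac_interest = 0.8,
                             planted_frac_background = 0.1,
                             background_rate = 0.15, seed) {
  dag <- make_toy_go_dag(n_leaves = n_background_terms + 1L, seed = seed)
  set.seed(seed + 1L)
  leaves <- setdiff(dag$terms$id, c("GO:0008150", unique(dag$edges$parent)))
  planted <- leaves[1]
  background <- leaves[-1]
  domains <- setNames(sprintf("PF%05d", seq_along(leaves)), leaves)
  domain2go <- data.frame(domain = unname(domains), go_id = names(domains),
                          stringsAsFactors = FALSE)
  is_pseudo <- genes$kind == "pseudogene"
  hits <- NULL
  p_planted <- ifelse(is_pseudo, planted_frac_interest,
                      planted_frac_background)
  take <- stats::runif(nrow(genes)) < p_planted
  if (any(take)) {
    hits <- data.frame(query = genes$gene_id[take],
                       domain = domains[[planted]],
                       e_value = 10^-stats::runif(sum(take), 15, 40),
                       stringsAsFactors = FALSE)
  }
  for (b in background) {
    take <- stats::runif(nrow(genes)) < background_rate
    if (any(take)) {
      hits <- rbind(hits, data.frame(
        query = genes$gene_id[take], domain = domains[[b]],
        e_value = 10^-stats::runif(sum(take), 15, 40),
        stringsAsFactors = FALSE))
    }
  }
  list(hits = hits, domain2go = domain2go, dag = dag, planted_term = planted)
}

#' Simulate a strain-mixture read set
#'
#' Reads are drawn from the given genomes at the given proportions, start
#' positions uniform, strand random, with i.i.d. substitution errors.
#'
#' @param genomes named character vector of strain genome sequences (one
#'   replicon per strain).
#' @param proportions numeric vector summing to 1, one entry per genome.
#' @param n_reads number of reads.
#' @param read_length read length in bp (default 151).
#' @param error_rate per-base substitution error rate.
#' @param seed integer RNG seed.
#' @return data.frame: read_id, source, start (0-based), strand, seq
#'   (sequenced, with errors), seq_true (error-free).
#' @export
make_mixture_reads <- function(genomes, proportions, n_reads,
                               read_length = 151L, error_rate = 0, seed) {
  stopifnot(length(genomes) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (read_length > min(nchar(genomes))) {
    stop("read length exceeds a genome length")
  }
  set.seed(seed)
  src <- sample(names(genomes), n_reads, replace = TRUE, prob = proportions)
  reads <- data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
                      source = src, stringsAsFactors = FALSE)
  reads$start <- vapply(src, function(g) {
    sample.int(nchar(genomes[[g]]) - read_length + 1L, 1L)
  }, integer(1)) - 1L
  reads$strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  fwd <- substring(genomes[src], reads$start + 1L,
                   reads$start + read_length)
  reads$seq_true <- ifelse(reads$strand == "+", fwd,
                           vapply(fwd, revcomp, character(1),
                                  USE.NAMES = FALSE))
  reads$seq <- if (error_rate > 0) {
    vapply(reads$seq_true, mutate_string, character(1), rate = error_rate,
           USE.NAMES = FALSE)
  } else {
    reads$seq_true
  }
  rownames(reads) <- NULL
  reads
}

#' Exact-matching toy aligner
#'
#' Emits a SAM record for every panel genome that contains a read's
#' error-free sequence (either strand): the first hit as the primary
#' alignment, further hits as secondary alignments; reads matching no genome
#' get an unmapped record. This gives metagenome attribution a ground-truth
#' aligner free of heuristics.
#'
#' @param reads data.frame from [make_mixture_reads()] (uses `read_id`,
#'   `seq_true`).
#' @param genomes named character vector of genome sequences; names are used
#'   as SAM reference names (one replicon per genome).
#' @param path output SAM file.
#' @return the path, invisibly.
#' @export
align_trivially <- function(reads, genomes, path) {
  width <- unique(nchar(reads$seq_true))
  stopifnot(length(width) == 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$seq_true))
  hits <- vector("list", nrow(reads))
  for (gi in seq_along(genomes)) {
    g <- names(genomes)[gi]
    for (strand in c("+", "-")) {
      subj <- Biostrings::DNAString(
        if (strand == "+") genomes[[gi]] else revcomp(genomes[[gi]]))
      mi <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(mi)
      idx <- which(cnt > 0)
      for (r in idx) {
        p <- IRanges::start(mi[[r]])[1]
        pos <- if (strand == "+") p else nchar(genomes[[gi]]) - p - width + 2L
        hits[[r]] <- rbind(hits[[r]], data.frame(
          rname = g, pos = pos, rev = strand == "-",
          stringsAsFactors = FALSE))
      }
    }
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genomes), nchar(genomes)))
  recs <- vector("list", nrow(reads))
  for (r in seq_len(nrow(reads))) {
    h <- hits[[r]]
    if (is.null(h)) {
      recs[[r]] <- paste(reads$read_id[r], 4L, "*", 0L, 0L, "*", "*",
                         0L, 0L, reads$seq_true[r], "*", sep = "\t")
      next
    }
    h <- h[!duplicated(h$rname), , drop = FALSE]   # one record per genome
    j <- seq_len(nrow(h))
    flag <- ifelse(h$rev, 16L, 0L) + ifelse(j > 1L, 256L, 0L)
    recs[[r]] <- paste(reads$read_id[r], flag, h$rname, h$pos,
                       ifelse(j > 1L, 0L, 60L), paste0(width, "M"),
                       "*", 0L, 0L, reads$seq_true[r], "*", sep = "\t")
  }
  writeLines(c(header, unlist(recs)), path)
  invisible(path)
}

#' Fabricate draft-contig alignments with planted deletions
#'
#' Emulates mapping a short-read draft assembly back to its complete
#' reference: the draft is the reference minus the given deletion blocks, so
#' each kept block becomes one perfectly mapped contig. Returns a SAM file
#' plus the planted uncovered fraction.
#'
#' @param reference_lengths named integer vector of replicon lengths.
#' @param deletions data.frame: replicon, start, end (0-based half-open,
#'   non-overlapping per replicon).
#' @param path output SAM file.
#' @return list: `path`, `uncovered_fraction`.
#' @export
make_draft_alignments <- function(reference_lengths, deletions, path) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(reference_lengths),
                     reference_lengths))
  ctg <- 0L
  for (rep in names(reference_lengths)) {
    L <- reference_lengths[[rep]]
    del <- deletions[deletions$replicon == rep, , drop = FALSE]
    del <- del[order(del$start), , drop = FALSE]
    covered <- if (nrow(del)) {
      starts <- c(0L, del$end)
      ends <- c(del$start, L)
      data.frame(start = starts, end = ends)[starts < ends, , drop = FALSE]
    } else {
      data.frame(start = 0L, end = L)
    }
    for (r in seq_len(nrow(covered))) {
      ctg <- ctg + 1L
      len <- covered$end[r] - covered$start[r]
      lines <- c(lines, paste(sprintf("contig%04d", ctg), 0L, rep,
                              covered$start[r] + 1L, 60L,
                              paste0(len, "M"), "*", 0L, 0L, "*", "*",
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  frac <- sum(pmax(deletions$end - deletions$start, 0)) /
    sum(reference_lengths)
  list(path = path, uncovered_fraction = unname(frac))
}
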