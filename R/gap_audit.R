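#' Draft-assembly gap auditing
#'
#' Short-read draft assemblies of repeat-rich genomes leave parts of the true
#' genome uncovered. Given alignments of draft contigs against the complete
#' reference, these functions compute per-base coverage, extract
#' zero-coverage gaps, and report the annotated genes and pseudogenes falling
#' into them, cross-classified by pan-genome category (core / accessory /
#' unique).
#'
#' @name gap_audit
NULL

sam_to_bam <- function(sam) {
  if (grepl("\\.bam$", sam)) return(sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Per-base coverage from contig alignments
#'
#' Coverage is accumulated from primary alignments only (secondary and
#' supplementary records are excluded so one contig is not counted twice),
#' over the reference-consuming CIGAR operations.
#'
#' @param sam path to a SAM (or BAM) file of contigs mapped to the reference.
#' @param reference_lengths named integer vector of replicon lengths.
#' @return named [S4Vectors::RleList]-like list of integer coverage Rle, one
#'   per reference replicon.
#' @export
coverage_from_alignments <- function(sam, reference_lengths) {
  bam <- sam_to_bam(sam)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  used <- unique(as.character(GenomicAlignments::seqnames(gal)))
  missing <- setdiff(used, names(reference_lengths))
  if (length(missing)) {
    stop("alignment target not in reference: '", missing[1], "'")
  }
  cov <- GenomicAlignments::coverage(gal)
  out <- lapply(names(reference_lengths), function(rep) {
    L <- reference_lengths[[rep]]
    if (rep %in% names(cov)) {
      r <- cov[[rep]]
      if (length(r) < L) r <- c(r, S4Vectors::Rle(0L, L - length(r)))
      if (length(r) > L) stop("alignments extend past reference on '",
                              rep, "'")
      r
    } else {
      S4Vectors::Rle(0L, L)
    }
  })
  names(out) <- names(reference_lengths)
  out
}

#' Per-base coverage from a BED-like depth file
#'
#' Accepts a precomputed coverage table (columns: replicon, start, end,
#' depth; 0-based half-open) as a substitute for contig alignments.
#'
#' @param path TSV file with the four columns above (no header).
#' @param reference_lengths named integer vector of replicon lengths.
#' @return as [coverage_from_alignments()].
#' @export
coverage_from_bed <- function(path, reference_lengths) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("replicon", "start", "end", "depth"),
                           stringsAsFactors = FALSE)
  out <- lapply(names(reference_lengths), function(rep) {
    L <- reference_lengths[[rep]]
    v <- integer(L)
    b <- bed[bed$replicon == rep, , drop = FALSE]
    for (r in seq_len(nrow(b))) {
      v[(b$start[r] + 1L):b$end[r]] <- v[(b$start[r] + 1L):b$end[r]] +
        b$depth[r]
    }
    S4Vectors::Rle(v)
  })
  names(out) <- names(reference_lengths)
  out
}

#' Maximal zero-coverage gaps
#'
#' @param coverage list of per-replicon coverage Rle
#'   (from [coverage_from_alignments()]).
#' @param min_gap_len drop gaps shorter than this many bp (default 1, i.e.
#'   keep all).
#' @return data.frame: replicon, start, end (0-based half-open), length;
#'   sorted, non-overlapping.
#' @export
zero_coverage_gaps <- function(coverage, min_gap_len = 1L) {
  out <- lapply(names(coverage), function(rep) {
    ir <- methods::as(coverage[[rep]] == 0L, "IRanges")
    ir <- ir[IRanges::width(ir) >= min_gap_len]
    if (!length(ir)) return(NULL)
    data.frame(replicon = rep, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), length = IRanges::width(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  }
  out[order(out$replicon, out$start), , drop = FALSE]
}

#' Audit annotated genes against coverage gaps
#'
#' A gene is "missed" iff it overlaps at least `min_overlap` bp of a single
#' gap. Headline counts cover CDSs and pseudogenes; RNA features are reported
#' separately. Genes absent from the category map are `"unassigned"`.
#'
#' @param gaps data.frame from [zero_coverage_gaps()].
#' @param annotation gene table: data.frame with columns gene_id, replicon,
#'   start, end (0-based half-open), strand, kind (`CDS`, `pseudogene`,
#'   `rRNA`, `tRNA`, `other`), product (optional).
#' @param categories named character vector gene_id -> `core` / `accessory` /
#'   `unique`.
#' @param replicon_lengths named integer vector (for the uncovered fraction).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return list: `gaps`, `n_gaps`, `mean_gap_len`, `uncovered_fraction`,
#'   `missed_genes` (annotation rows + `category`), `counts` (kind x
#'   category table over CDS/pseudogene), `missed_rna` count.
#' @export
audit <- function(gaps, annotation, categories = character(0),
                  replicon_lengths, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  if (nrow(gaps)) {
    gap_gr <- GenomicRanges::GRanges(
      gaps$replicon, IRanges::IRanges(gaps$start + 1L, gaps$end))
    gene_gr <- GenomicRanges::GRanges(
      annotation$replicon,
      IRanges::IRanges(annotation$start + 1L, annotation$end))
    hit <- GenomicRanges::findOverlaps(gene_gr, gap_gr,
                                       minoverlap = min_overlap)
    missed_idx <- sort(unique(S4Vectors::queryHits(hit)))
  } else {
    missed_idx <- integer(0)
  }
  missed <- annotation[missed_idx, , drop = FALSE]
  missed$category <- ifelse(missed$gene_id %in% names(categories),
                            unname(categories[missed$gene_id]), "unassigned")
  headline <- missed[missed$kind %in% c("CDS", "pseudogene"), , drop = FALSE]
  counts <- table(kind = factor(headline$kind,
                                levels = c("CDS", "pseudogene")),
                  category = factor(headline$category,
                                    levels = c("core", "accessory", "unique",
                                               "unassigned")))
  list(gaps = gaps,
       n_gaps = nrow(gaps),
       mean_gap_len = if (nrow(gaps)) mean(gaps$length) else 0,
       uncovered_fraction = sum(gaps$length) / sum(replicon_lengths),
       missed_genes = missed,
       counts = counts,
       missed_rna = sum(missed$kind %in% c("rRNA", "tRNA")))
}

#' One-call gap audit from a SAM file
#'
#' @inheritParams coverage_from_alignments
#' @inheritParams audit
#' @inheritParams zero_coverage_gaps
#' @return as [audit()].
#' @export
gap_audit <- function(sam, reference_lengths, annotation,
                      categories = character(0), min_overlap = 1L,
                      min_gap_len = 1L) {
  cov <- coverage_from_alignments(sam, reference_lengths)
  gaps <- zero_coverage_gaps(cov, min_gap_len)
  audit(gaps, annotation, categories, reference_lengths, min_overlap)
}
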