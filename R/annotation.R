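#' Gene annotation tables
#'
#' The pipeline's internal annotation format is a flat gene table with
#' 0-based half-open coordinates: gene_id, replicon, start, end, strand,
#' kind (CDS / pseudogene / rRNA / tRNA / other), product. GFF3 conversion
#' (1-based inclusive on disk) goes through rtracklayer.
#'
#' @name annotation
NULL

GENE_TABLE_COLS <- c("gene_id", "replicon", "start", "end", "strand", "kind")

validate_gene_table <- function(genes) {
  miss <- setdiff(GENE_TABLE_COLS, names(genes))
  if (length(miss)) stop("gene table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    stop("gene coordinates must satisfy 0 <= start < end")
  }
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  invisible(genes)
}

#' Read a flat gene table TSV
#' @param path TSV with header (gene_id, replicon, start, end, strand, kind,
#'   product).
#' @return validated data.frame.
#' @export
read_gene_table <- function(path) {
  validate_gene_table(utils::read.table(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE,
                                        quote = ""))
}

#' Write a flat gene table TSV
#' @param genes gene table data.frame.
#' @param path output file.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Keeps gene-like features (CDS, pseudogene, rRNA, tRNA) and converts to the
#' internal 0-based half-open gene table.
#'
#' @param path GFF3 file.
#' @return gene table data.frame.
#' @export
read_gff3_genes <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 input")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "pseudogene", "rRNA", "tRNA")
  gr <- gr[keep]
  ids <- if (!is.null(gr$ID)) gr$ID else paste0("feature_", seq_along(gr))
  genes <- data.frame(
    gene_id = ids,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = as.character(gr$type),
    product = if (!is.null(gr$product)) gr$product else NA_character_,
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  validate_gene_table(genes)
}

#' Write gene features to GFF3
#' @param genes gene table data.frame.
#' @param path output file.
#' @export
write_gff3_genes <- function(genes, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GFF3 output")
  }
  validate_gene_table(genes)
  gr <- GenomicRanges::GRanges(
    genes$replicon,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$type <- genes$kind
  gr$ID <- genes$gene_id
  gr$source <- "helvepan"
  gr$phase <- ifelse(genes$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene-category map TSV (gene_id, category)
#' @param path TSV with header.
#' @return named character vector gene_id -> category.
#' @export
read_category_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  setNames(x$category, x$gene_id)
}
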