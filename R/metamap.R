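#' Strain-resolved metagenome read attribution
#'
#' A starter-culture metagenome aligned against a panel of reference genomes
#' (in report-all mode, so multi-mapping is visible) is turned into a
#' species-level composition, group-exclusive read counts corrected for group
#' size, and per-genome unique-read tallies. A read hitting m distinct
#' genomes contributes 1/m to each of them ("proportional" attribution);
#' neither genome count nor genome size is corrected for at the species
#' level.
#'
#' @name metamap
NULL

#' Load per-read target-genome sets from a SAM file
#'
#' Unmapped and supplementary records are dropped; secondary alignments are
#' retained because they carry the multi-target information. Per read, the
#' set of distinct genomes hit is returned (duplicate hits to one genome
#' collapse).
#'
#' @param sam path to SAM or BAM.
#' @param replicon2genome optional named character vector mapping SAM
#'   reference names to panel genome ids (default: reference names are the
#'   genome ids).
#' @param by_fragment if `TRUE`, paired-end mates are merged into one
#'   fragment whose target set is the intersection of the mates' sets
#'   (non-paired reads keep their own set).
#' @return list: `read_targets` (named list read -> character vector of
#'   genome ids), `n_unmapped` (reads with no surviving alignment).
#' @export
load_alignments <- function(sam, replicon2genome = NULL,
                            by_fragment = FALSE) {
  bam <- sam_to_bam(sam)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  rn <- as.character(x$rname)
  if (!is.null(replicon2genome)) {
    unknown <- setdiff(unique(rn), names(replicon2genome))
    if (length(unknown)) stop("no genome mapping for replicon '",
                              unknown[1], "'")
    rn <- unname(replicon2genome[rn])
  }
  key <- x$qname
  if (by_fragment) {
    mate <- ifelse(bitwAnd(x$flag, 128L) > 0L, "/2", "/1")
    paired <- bitwAnd(x$flag, 1L) > 0L
    mate[!paired] <- ""
    per_mate <- lapply(split(rn, paste0(key, mate)), unique)
    frag <- sub("/[12]$", "", names(per_mate))
    read_targets <- lapply(split(per_mate, frag), function(sets) {
      if (length(sets) == 1L) sets[[1]] else Reduce(intersect, sets)
    })
    # a fragment whose mates share no target is counted as unmapped
    empty <- lengths(read_targets) == 0L
    n_empty <- sum(empty)
    read_targets <- read_targets[!empty]
  } else {
    read_targets <- lapply(split(rn, key), unique)
    n_empty <- 0L
  }
  up <- Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  un <- Rsamtools::scanBam(bam, param = up)[[1]]$qname
  if (by_fragment) un <- sub("/[12]$", "", un)
  n_unmapped <- length(setdiff(unique(un), names(read_targets))) + n_empty
  list(read_targets = read_targets, n_unmapped = n_unmapped)
}

#' Read a reference-panel table
#' @param path TSV with header columns genome_id, species, group, length.
#' @return data.frame.
#' @export
read_panel <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

check_panel <- function(read_targets, panel) {
  if (anyDuplicated(panel$genome_id)) stop("panel genome ids must be unique")
  unknown <- setdiff(unique(unlist(read_targets)), panel$genome_id)
  if (length(unknown)) stop("alignment to genome not in panel: '",
                            unknown[1], "'")
}

#' Species-level composition by proportional attribution
#'
#' A read hitting m distinct genomes contributes 1/m to each; contributions
#' are summed per species. Fractions are over mapped plus unmapped reads,
#' with an explicit `"unmapped"` slice.
#'
#' @param read_targets named list from [load_alignments()].
#' @param panel data.frame with columns genome_id, species, group.
#' @param n_unmapped number of unmapped reads.
#' @return list: `species_counts` (named numeric, sums to the number of
#'   mapped reads), `species_fractions` (includes `"unmapped"`),
#'   `genome_counts` (fractional counts per genome).
#' @export
species_composition <- function(read_targets, panel, n_unmapped = 0L) {
  check_panel(read_targets, panel)
  species_of <- setNames(panel$species, panel$genome_id)
  gcount <- setNames(numeric(nrow(panel)), panel$genome_id)
  for (tg in read_targets) {
    w <- 1 / length(tg)
    gcount[tg] <- gcount[tg] + w
  }
  scount <- tapply(gcount, species_of[names(gcount)], sum)
  scount <- setNames(as.numeric(scount), names(scount))
  total <- length(read_targets) + n_unmapped
  frac <- c(scount, unmapped = n_unmapped) / total
  list(species_counts = scount, species_fractions = frac,
       genome_counts = gcount)
}

#' Group-exclusive read counts with group-size correction
#'
#' A read is exclusive to a group iff every genome it hits belongs to that
#' group. The normalized count divides the raw count by the number of
#' genomes in the group, correcting for unequal panel sizes (e.g. three
#' in-house strains vs eight public strains).
#'
#' @inheritParams species_composition
#' @return data.frame: group, n_genomes, raw, normalized.
#' @export
group_exclusive_counts <- function(read_targets, panel) {
  check_panel(read_targets, panel)
  group_of <- setNames(panel$group, panel$genome_id)
  groups <- unique(panel$group)
  sizes <- table(panel$group)[groups]
  if (any(sizes == 0L)) stop("group with zero genomes")
  raw <- setNames(numeric(length(groups)), groups)
  for (tg in read_targets) {
    g <- unique(group_of[tg])
    if (length(g) == 1L) raw[g] <- raw[g] + 1
  }
  data.frame(group = groups, n_genomes = as.integer(sizes),
             raw = as.numeric(raw),
             normalized = as.numeric(raw) / as.integer(sizes),
             stringsAsFactors = FALSE)
}

#' Per-genome counts of uniquely mapping reads
#'
#' @inheritParams species_composition
#' @return named integer vector over all panel genomes (zeros included).
#' @export
unique_read_counts <- function(read_targets, panel) {
  check_panel(read_targets, panel)
  counts <- setNames(integer(nrow(panel)), panel$genome_id)
  single <- read_targets[lengths(read_targets) == 1L]
  if (length(single)) {
    tb <- table(unlist(single))
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

#' Full attribution of a metagenome alignment
#'
#' @inheritParams load_alignments
#' @param panel data.frame with columns genome_id, species, group.
#' @return list: `species_counts`, `species_fractions`, `genome_counts`,
#'   `group_exclusive`, `unique_per_genome`, `n_mapped`, `n_unmapped`.
#' @export
attribute_reads <- function(sam, panel, replicon2genome = NULL,
                            by_fragment = FALSE) {
  al <- load_alignments(sam, replicon2genome, by_fragment)
  comp <- species_composition(al$read_targets, panel, al$n_unmapped)
  c(comp,
    list(group_exclusive = group_exclusive_counts(al$read_targets, panel),
         unique_per_genome = unique_read_counts(al$read_targets, panel),
         n_mapped = length(al$read_targets),
         n_unmapped = al$n_unmapped))
}
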