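#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input the downstream analyses consume,
# with ground truth, under results/data/.

suppressPackageStartupMessages(library(helvepan))

SEED <- 1L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

## genome with planted repeat families -----------------------------------------
g <- make_repeat_genome(
  backbone_length = 50000L,
  families = list(list(copies = 3L, length = 800L, mut_rate = 0.02),
                  list(copies = 2L, length = 1500L, mut_rate = 0)),
  seed = SEED)
write_fasta(g$genome, file.path(data_dir, "repeat_genome.fasta"))
write.table(g$truth, file.path(data_dir, "repeat_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## strain family with known pan-genome structure -------------------------------
fam <- make_strain_family(n_strains = 5L, n_core = 140L, n_accessory = 80L,
                          n_unique_per_strain = 15L,
                          pseudogene_fraction = 0.05, seed = SEED + 1L)
write_fasta(fam$genomes, file.path(data_dir, "strain_genomes.fasta"))
write.table(fam$genes, file.path(data_dir, "strain_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fam$truth, file.path(data_dir, "strain_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(fam$pseudogenes, file.path(data_dir, "pseudogenes.txt"))

## domain hits with a planted enriched GO term ---------------------------------
fam_e <- make_strain_family(3L, 40L, 10L, 2L, pseudogene_fraction = 0.25,
                            seed = SEED + 2L)
write.table(fam_e$genes, file.path(data_dir, "enrich_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(fam_e$pseudogenes, file.path(data_dir, "enrich_pseudogenes.txt"))
dh <- make_domain_hits(fam_e$genes, seed = SEED + 2L)
write.table(dh$hits, file.path(data_dir, "domain_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dh$domain2go, file.path(data_dir, "domain2go.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
edges <- dh$dag$edges
edges$namespace <- "BP"
write.table(edges, file.path(data_dir, "go_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(dh$planted_term, file.path(data_dir, "planted_term.txt"))

## strain-mixture metagenome ----------------------------------------------------
set.seed(SEED + 3L)
mix_genomes <- vapply(1:3, function(i) {
  paste(sample(c("A", "C", "G", "T"), 50000L, replace = TRUE), collapse = "")
}, character(1))
names(mix_genomes) <- c("FAM01", "FAM02", "PUB01")
reads <- make_mixture_reads(mix_genomes, c(0.6, 0.3, 0.1), 10000L,
                            seed = SEED + 4L)
write.table(reads[, c("read_id", "source", "start", "strand")],
            file.path(data_dir, "mixture_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
align_trivially(reads, mix_genomes, file.path(data_dir, "mixture.sam"))
panel <- data.frame(genome_id = names(mix_genomes),
                    species = c("L.helveticus", "L.helveticus",
                                "S.thermophilus"),
                    group = c("FAM", "FAM", "PUBLIC"),
                    length = nchar(mix_genomes))
write.table(panel, file.path(data_dir, "panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## draft assembly with planted deletions ---------------------------------------
st <- names(fam$genomes)[1]
genes_st <- fam$genes[fam$genes$genome_id == st, ]
set.seed(SEED + 5L)
victim <- sort(sample(seq_len(nrow(genes_st) - 1L), 2L))
victim <- victim[c(TRUE, diff(victim) > 2L)]      # keep blocks disjoint
deletions <- data.frame(replicon = st,
                        start = genes_st$start[victim],
                        end = genes_st$end[victim])
d <- make_draft_alignments(setNames(nchar(fam$genomes[st]), st), deletions,
                           file.path(data_dir, "draft.sam"))
write.table(deletions, file.path(data_dir, "draft_deletions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
annotation <- genes_st[, c("gene_id", "replicon", "start", "end", "strand",
                           "kind")]
write_gene_table(annotation, file.path(data_dir, "draft_annotation.tsv"))
write.table(data.frame(gene_id = genes_st$gene_id,
                       category = genes_st$category),
            file.path(data_dir, "draft_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("simulated inputs written to", data_dir, "\n")
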