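#!/usr/bin/env Rscript

# Stage 6: audit the simulated short-read draft against its reference:
# zero-coverage gaps, uncovered fraction, missed genes by category.

suppressPackageStartupMessages(library(helvepan))

data_dir <- "results/data"
out_dir <- "results"

annotation <- read_gene_table(file.path(data_dir, "draft_annotation.tsv"))
categories <- read_category_map(file.path(data_dir, "draft_categories.tsv"))
genomes <- read_genome_fasta(file.path(data_dir, "strain_genomes.fasta"))
rep_id <- unique(annotation$replicon)
lens <- setNames(nchar(genomes[rep_id]), rep_id)

res <- gap_audit(file.path(data_dir, "draft.sam"), lens, annotation,
                 categories)
write.table(res$gaps, file.path(out_dir, "gaps.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$missed_genes, file.path(out_dir, "missed_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(kind = rownames(res$counts), as.data.frame.matrix(res$counts)),
            file.path(out_dir, "missed_gene_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

deletions <- read.table(file.path(data_dir, "draft_deletions.tsv"),
                        header = TRUE, sep = "\t", stringsAsFactors = FALSE)
planted_frac <- sum(deletions$end - deletions$start) / sum(lens)
cat(sprintf("gaps: %d, uncovered fraction %.5f (planted %.5f)\n",
            res$n_gaps, res$uncovered_fraction, planted_frac))
cat(sprintf("missed genes: %d (%s)\n", nrow(res$missed_genes),
            paste(res$missed_genes$category, collapse = ", ")))
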