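---
title: "Methods: repeat-aware comparative genomics with helvepan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware comparative genomics with helvepan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

helvepan implements five analysis stages for families of closely related
bacterial strains — intra-genomic repeat profiling, draft-assembly gap
auditing, pan-genome construction, pseudogene GO enrichment, and
strain-resolved metagenome attribution — together with seeded generators
that produce every input with known ground truth. This vignette states the
model behind each stage, the defaults and why they are what they are, and
the limits of what the synthetic validation shows.

```{r setup}
library(helvepan)
```

## Repeat detection and complexity classes

**Problem.** Whether a bacterial genome can be finished from a given read
length is governed by its intra-genomic repeat structure: the number of
repeated locus pairs and, decisively, the length of the longest repeat
relative to the multi-copy rDNA operon (6–7 kb).

**Model.** A repeat pair is a pair of distinct loci, in forward or
reverse-complement orientation, whose ungapped alignment has length
$L \ge 500$ bp and identity $\mathrm{id} = m / L \ge 0.95$, where $m$ counts
matching columns. Detection is seeded: positions sharing an exact $k$-mer
($k = 21$) define candidate diagonals; every candidate diagonal is scanned
exhaustively and its maximal positive-scoring segments under
match $+1$ / mismatch $-3$ are extracted (disjoint, best-first, recursing
into the flanks), then filtered by the length and identity thresholds.

Why $+1/-3$: unrelated sequence matches at $\approx 25\%$, so its expected
per-column score is $0.25 - 3 \cdot 0.75 = -2$ and extension drifts strongly
downward outside a repeat, stopping like an aligner's X-drop; inside a
diverged copy at $\ge 95\%$ identity the drift is $+0.8$ per column, so
occasional mismatches are crossed. We deliberately decouple the extension
score from the identity threshold: an extension penalty tuned so that
segments score positive exactly at the threshold either dilutes exact
repeats out to the threshold identity or trims diverged copies below the
minimum length — both observed before settling on this design.

Why $k = 21$: a seed must survive inside the repeat. A 500 bp copy pair at
95% identity has, at worst-case even spacing of its $\le 25$ mismatches, a
guaranteed exact run of $\lfloor 500 / 26 \rfloor = 19$ bp, and in the
substitution models used here the expected longest shared run is far above
21; meanwhile a random 21-mer coincidence ($4^{-21}$ per position pair) is
negligible even genome-wide, keeping the candidate diagonal set small.
Sensitivity falls only for repeats so diverged they no longer qualify.

`N` never matches, and alignments are broken at runs of 10 or more `N`s, so
assembly gaps cannot bridge repeats. `rotate = TRUE` doubles each replicon
to catch origin-spanning repeats in circular sequences.

**Classification.** With $n$ repeat pairs and longest repeat $\ell$:
class III if $\ell > 7000$ bp (beyond the rDNA-operon ceiling; only very
long reads resolve it), class II if $n > 100$, class I otherwise.

```{r repeats}
g <- make_repeat_genome(
  20000L,
  families = list(list(copies = 3L, length = 600L, mut_rate = 0.02)),
  seed = 7L)
pairs <- find_repeat_pairs(g$genome)
pairs[, c("a_start", "a_end", "b_start", "b_end", "aln_length", "identity")]
summarize_repeats(pairs, "demo")
```

**Validation.** The test suite compares the seeded detector against a
brute-force oracle that scans *all* diagonals of the sequence against itself
and its reverse complement — no seeding — and applies the same canonical
segment definition. Because the generators are substitution-only, no repeat
can leave its diagonal, making the oracle complete. Agreement is exact on
every tested genome.

## Draft-assembly gap audit

Contig alignments against the complete reference (SAM/BAM; primary records
only, so one contig is never counted twice) are converted to per-base
coverage over the reference-consuming CIGAR operations. Maximal
zero-coverage runs are the gaps; a gene is *missed* when it overlaps a gap
by at least `min_overlap` (default 1) bp. Missed CDSs and pseudogenes are
cross-classified by pan-genome category; RNA genes are reported separately.
Tested against planted deletions (exact missed-gene sets) and a naive
interval-intersection oracle.

## Pan-genome construction

**Clustering.** Proteins are sorted by decreasing length (gene id breaks
ties) and greedily assigned to the first existing cluster whose
*representative* (founding, hence longest, member) they match at
$\ge 95\%$ global-alignment identity (identity $=$ matches / alignment
columns, gaps counted) with length coverage shorter/longer $\ge 0.90$;
otherwise they found a new cluster. Paralogs are not split: several genes of
one genome may share a cluster, and presence/absence counts genomes, not
genes. A 4-mer amino-acid word prefilter (candidates must share $\ge 40\%$
of the query's words with the representative) keeps the scan near-linear;
at the 0.95/0.90 operating point a qualifying representative always passes
the word filter for the sequence lengths used here, so greedy first-match
semantics are preserved, and every candidate is still verified by alignment
(equal-length pairs take a gap-free fast path, which is exact because a
gap-free identity at or above the threshold is attainable by the global
alignment).

**Partition.** With $n$ genomes, a cluster present in all $n$ is *core*, in
exactly one is *unique* (attributed to that genome), otherwise *accessory*;
$|\mathrm{pan}| = |\mathrm{core}| + |\mathrm{accessory}| + |\mathrm{unique}|$
always.

**Accumulation curves.** Genomes are added in random order; after each
addition the pan (union) and core (intersection) sizes are recorded; means
over 10 random orderings (the study's convention) are reported, and the
final point is order-independent. Tested against exhaustive enumeration of
all $n!$ orderings for small $n$.

**COG cross-tab.** Per gene, the hit with the smallest e-value at or below
$10^{-3}$ wins (first-in-file on ties); clusters take their representative's
letters, multi-letter assignments count once per letter. Roary-format
`gene_presence_absence.csv` matrices can be imported directly for full-scale
runs.

```{r pangenome}
fam <- make_strain_family(n_strains = 3L, n_core = 20L, n_accessory = 8L,
                          n_unique_per_strain = 3L, seed = 11L)
cl <- cluster_proteins(fam$genes)
part <- partition(presence_absence_matrix(cl))
part$counts
table(fam$truth$category)
```

## Pseudogene GO enrichment

Pseudogenes carry frameshifts, so domains may sit in any frame: sequences
are six-frame translated (bacterial code, table 11; internal stops kept)
before domain scanning. Hits are kept only below a strict
$e < 10^{-10}$ (duplicate query–domain pairs from different frames collapse
to the best), mapped to GO via a pfam2go-style table, and propagated to all
ancestors (true-path rule). For a universe of $N$ genes with $n$ of
interest and a term annotating $K$ genes, $k$ of them interesting, the
classic one-sided Fisher p-value is the hypergeometric tail
$P(X \ge k)$. The *elim* variant processes terms children-before-parents
and removes the genes of any term significant at `elim_alpha` (default
0.01) from its ancestors before testing them, decorrelating nested terms.
Rankings are reported without multiple-testing correction (a
Benjamini–Hochberg column is attached for information), following common
topology-aware GO-testing practice.

```{r enrichment}
fam_e <- make_strain_family(3L, 40L, 10L, 2L, pseudogene_fraction = 0.25,
                            seed = 45L)
dh <- make_domain_hits(fam_e$genes, seed = 45L)
ann <- annotate_go(filter_hits(dh$hits), dh$domain2go, dh$dag)
universe <- setNames(rep(list(character(0)), nrow(fam_e$genes)),
                     fam_e$genes$gene_id)
universe[names(ann)] <- ann
head(go_enrichment(universe, fam_e$pseudogenes, dh$dag), 3)
dh$planted_term
```

## Metagenome attribution

Alignments in report-all mode are loaded keeping secondary records (they
carry the multi-mapping information) and dropping unmapped and supplementary
ones. A read hitting $m$ distinct genomes contributes $1/m$ to each
("proportional" attribution, the minimal reading of the source method);
contributions are summed per species, and fractions are taken over mapped
plus unmapped reads. A read is *group-exclusive* when every genome it hits
belongs to one group; the normalized count divides by the group's genome
count, correcting for unequal panel sizes. Unique-read counts require a
target set of size one. Conservation
$\sum_s \mathrm{count}_s = \#\mathrm{mapped}$ holds exactly on any input.
Paired-end mates are independent reads unless `by_fragment = TRUE`
intersects the mates' target sets.

## Synthetic data: what it shows and what it does not

All generators flow from one integer seed and are byte-identical across
runs. Mutations are substitution-only, and a **fixed count**
$\mathrm{round}(\mathrm{rate} \cdot L)$ of positions is substituted rather
than a per-site Bernoulli draw: the generators' contract is *controlled*
identity, and with Bernoulli noise short genes frequently realize
within-cluster identities below the clustering threshold, making the
planted partition an invalid truth. With fixed counts, pairwise divergence
is bounded by twice the nominal rate, so planted truths are exact.

Typical validated problem sizes (one CPU): repeat detection on 50 kb
replicons in well under a second; 5-genome families of ~1,000 genes
clustered in ~1 s; 10,000-read mixtures attributed in seconds. Real genomes
(2 Mb, 12 strains) scale within minutes.

Limitations: no indel mutations or structural variation, so the repeat
oracle's completeness argument (repeats stay on one diagonal) holds only
for synthetic data; no realistic read-error profiles; clustering identity
is verified against representatives only (CD-HIT-style greediness, not
average linkage); enrichment p-values assume the usual independent-sampling
null of Fisher's test. Pseudogenes are excluded from clustering (they have
no intact protein), so in families with planted pseudogenes the observed
core is smaller than the planted one — each core cluster with a
pseudogenized member demotes to accessory, which is the phenomenon the gap
and enrichment stages are about, not an error.
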