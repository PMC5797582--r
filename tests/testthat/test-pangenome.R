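toy_genes <- function(proteins, genomes, ids = NULL) {
  data.frame(genome_id = genomes,
             gene_id = if (is.null(ids)) {
               sprintf("g%02d", seq_along(proteins))
             } else ids,
             protein = proteins, stringsAsFactors = FALSE)
}

test_that("identical proteins across genomes form one cluster", {
  set.seed(1)
  p <- paste(sample(c("A", "G", "L", "S", "K"), 120, replace = TRUE),
             collapse = "")
  cl <- cluster_proteins(toy_genes(rep(p, 3), c("G1", "G2", "G3")))
  expect_equal(length(unique(cl$cluster_id)), 1L)
  m <- presence_absence_matrix(cl)
  expect_equal(dim(m), c(1L, 3L))
  expect_true(all(m))
})

test_that("proteins at 90% identity split at a 95% threshold", {
  set.seed(2)
  a <- paste(sample(c("A", "G", "L", "S", "K"), 200, replace = TRUE),
             collapse = "")
  ch <- strsplit(a, "")[[1]]
  flip <- seq(1, 200, by = 10)            # exactly 10% of positions
  ch[flip] <- ifelse(ch[flip] == "W", "Y", "W")
  b <- paste(ch, collapse = "")
  cl <- cluster_proteins(toy_genes(c(a, b), c("G1", "G2")),
                         min_identity = 0.95)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  cl90 <- cluster_proteins(toy_genes(c(a, b), c("G1", "G2")),
                           min_identity = 0.90)
  expect_equal(length(unique(cl90$cluster_id)), 1L)
})

test_that("paralogs are not split and presence counts genomes once", {
  set.seed(3)
  p <- paste(sample(c("A", "G", "L", "S", "K"), 150, replace = TRUE),
             collapse = "")
  genes <- toy_genes(rep(p, 4), c("G1", "G1", "G2", "G3"))
  cl <- cluster_proteins(genes)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 4L)
  m <- presence_absence_matrix(cl)
  expect_equal(sum(m), 3L)                # presence = 3 genomes
})

test_that("coverage gate keeps a short fragment out of a long cluster", {
  set.seed(4)
  long <- paste(sample(c("A", "G", "L", "S", "K"), 300, replace = TRUE),
                collapse = "")
  frag <- substr(long, 1, 150)            # identical but 50% coverage
  cl <- cluster_proteins(toy_genes(c(long, frag), c("G1", "G2")),
                         min_coverage = 0.9)
  expect_equal(length(unique(cl$cluster_id)), 2L)
})

test_that("clustering is invariant to input row order", {
  fam <- make_strain_family(3L, 15L, 5L, 2L, seed = 21L)
  cl1 <- cluster_proteins(fam$genes)
  shuffled <- fam$genes[sample(nrow(fam$genes)), ]
  cl2 <- cluster_proteins(shuffled)
  # compare the partitions as sets of member sets
  sets1 <- unname(lapply(split(cl1$gene_id, cl1$cluster_id), sort))
  sets2 <- unname(lapply(split(cl2$gene_id, cl2$cluster_id), sort))
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("clustering rejects empty input", {
  expect_error(cluster_proteins(NULL), "no proteins")
  expect_error(
    cluster_proteins(toy_genes(c("AGLSK", NA), c("G1", "G2"))),
    "empty protein")
})

test_that("partition implements the presence-count rules", {
  m <- matrix(c(TRUE, TRUE, TRUE,
                TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE,
                FALSE, FALSE, TRUE),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("G", 1:3)))
  p <- partition(m)
  expect_equal(p$core, "c1")
  expect_equal(p$accessory, "c2")
  expect_setequal(p$unique, c("c3", "c4"))
  expect_equal(p$unique_by_genome$G1, "c3")
  expect_equal(p$unique_by_genome$G3, "c4")
  expect_equal(p$counts,
               c(pan = 4L, core = 1L, accessory = 1L, unique = 2L))

  all_core <- matrix(TRUE, 3, 4,
                     dimnames = list(paste0("c", 1:3), paste0("G", 1:4)))
  pc <- partition(all_core)
  expect_equal(length(pc$accessory), 0L)
  expect_equal(length(pc$unique), 0L)
  expect_equal(unname(pc$counts["pan"]), unname(pc$counts["core"]))

  bad <- m; bad[1, ] <- FALSE
  expect_error(partition(bad), "present in no genome")
})

test_that("partition conserves counts on random matrices", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    r <- sample(5:40, 1)
    m <- matrix(runif(r * n) < 0.5, r, n,
                dimnames = list(paste0("c", 1:r), paste0("G", 1:n)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (!nrow(m)) next
    p <- partition(m)
    expect_equal(unname(p$counts["core"] + p$counts["accessory"] +
                          p$counts["unique"]),
                 unname(p$counts["pan"]))
  }
})

test_that("accumulation curves are exact at stated endpoints", {
  # n identical genomes: pan = core = constant
  m <- matrix(TRUE, 7, 4,
              dimnames = list(paste0("c", 1:7), paste0("G", 1:4)))
  ac <- accumulation_curves(m, n_iterations = 5L, seed = 1L)
  expect_equal(ac$mean_pan, rep(7, 4))
  expect_equal(ac$mean_core, rep(7, 4))

  # 2 genomes sharing c clusters with u1, u2 unique
  m2 <- rbind(matrix(TRUE, 5, 2),                 # shared
              cbind(rep(TRUE, 3), rep(FALSE, 3)), # unique to G1
              cbind(rep(FALSE, 2), rep(TRUE, 2))) # unique to G2
  dimnames(m2) <- list(paste0("c", 1:10), c("G1", "G2"))
  ac2 <- accumulation_curves(m2, n_iterations = 8L, seed = 2L)
  expect_equal(ac2$mean_pan[2], 5 + 3 + 2)
  expect_equal(ac2$mean_core[2], 5)
})

test_that("exhaustive-ordering oracle matches the 3-genome toy example", {
  # core 2, accessory 1 in genomes {1,2}, unique 1 each
  m <- rbind(matrix(TRUE, 2, 3),
             c(TRUE, TRUE, FALSE),
             c(TRUE, FALSE, FALSE),
             c(FALSE, TRUE, FALSE),
             c(FALSE, FALSE, TRUE))
  dimnames(m) <- list(paste0("c", 1:6), paste0("G", 1:3))
  want <- oracle_accumulation_exact(m)
  # with all 3! = 6 orderings enumerable, a large MC run converges on it
  ac <- accumulation_curves(m, n_iterations = 2000L, seed = 3L)
  expect_equal(ac$mean_pan, want$mean_pan, tolerance = 0.05)
  expect_equal(ac$mean_core, want$mean_core, tolerance = 0.05)
  # final step is order-independent and exact in every iteration
  expect_true(all(ac$pan[, 3] == want$mean_pan[3]))
  expect_true(all(ac$core[, 3] == want$mean_core[3]))
})

test_that("COG assignment takes the best qualifying hit", {
  ht <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    subject = paste0("s", 1:5),
    e_value = c(1e-5, 1e-9, 0.01, 1e-7, 1e-7),
    cog_letters = c("L", "K", "J", "M", "N"),
    stringsAsFactors = FALSE)
  a <- assign_cog(ht)
  expect_equal(unname(a["g1"]), "K")      # smallest e-value wins
  expect_equal(unname(a["g2"]), "none")   # above cutoff
  expect_equal(unname(a["g3"]), "M")      # tie: first row in file order
  bad <- ht; bad$e_value <- as.character(bad$e_value); bad$e_value[2] <- "x"
  expect_error(assign_cog(bad), "malformed e-value at line 2")
})

test_that("COG crosstab counts letters once per letter", {
  set.seed(23)
  prots <- vapply(1:10, function(i) {
    paste(sample(c("A", "G", "L", "S", "K", "T", "V", "E"), 100,
                 replace = TRUE), collapse = "")
  }, character(1))
  cl <- cluster_proteins(toy_genes(prots, rep("G1", 10)))
  expect_equal(length(unique(cl$cluster_id)), 10L)
  m <- presence_absence_matrix(cl)
  p <- partition(m)                         # single genome: all unique
  asg <- setNames(rep("J", 10), cl$gene_id)
  ct <- cog_crosstab(p, cl, asg)
  expect_equal(unname(ct$counts["J", "unique"]), 10L)
  expect_equal(unname(ct$percentages["J", "unique"]), 100)
  # multi-letter assignment counts in both rows
  asg2 <- asg; asg2[] <- "KL"
  ct2 <- cog_crosstab(p, cl, asg2)
  expect_equal(unname(ct2$counts["K", "unique"]), 10L)
  expect_equal(unname(ct2$counts["L", "unique"]), 10L)
  expect_equal(unname(ct2$counts["J", "unique"]), 0L)
})

test_that("Roary presence/absence import reads the standard layout", {
  meta <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
            "No. sequences", "Avg sequences per isolate", "Genome Fragment",
            "Order within Fragment", "Accessory Fragment",
            "Accessory Order with Fragment", "QC", "Min group size nuc",
            "Max group size nuc", "Avg group size nuc")
  header <- paste(c(sprintf('"%s"', meta), '"strainA"', '"strainB"',
                    '"strainC"'), collapse = ",")
  row1 <- paste(c('"clusA"', rep('""', 13), '"a1"', '"b1"', '"c1"'),
                collapse = ",")
  row2 <- paste(c('"clusB"', rep('""', 13), '"a2"', '""', '"c2"'),
                collapse = ",")
  row3 <- paste(c('"clusC"', rep('""', 13), '""', '""', '"c3"'),
                collapse = ",")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, row1, row2, row3), path)
  m <- read_roary_presence_absence(path)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(colnames(m), c("strainA", "strainB", "strainC"))
  expect_equal(rownames(m), c("clusA", "clusB", "clusC"))
  p <- partition(m)
  expect_equal(p$core, "clusA")
  expect_equal(p$accessory, "clusB")
  expect_equal(p$unique, "clusC")
  # truncated file without genome columns
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(sprintf('"%s"', meta), collapse = ","),
               paste(rep('""', 14), collapse = ",")), path2)
  expect_error(read_roary_presence_absence(path2), "no genome columns")
})
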