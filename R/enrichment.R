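#' Pseudogene GO-term enrichment
#'
#' Pseudogenes carry frameshifts, so protein domains can sit in any reading
#' frame: sequences are six-frame translated before domain scanning. Domain
#' hits (from an hmmscan/interproscan-like tabular file) are filtered at a
#' strict e-value cutoff, mapped to GO terms, propagated up the GO DAG
#' (true-path rule), and biological-process terms are tested for
#' overrepresentation among the pseudogenes ("genes of interest") against the
#' combined CDS + pseudogene universe with a one-sided Fisher exact test,
#' optionally decorrelated bottom-up with the elim algorithm.
#'
#' @name enrichment
NULL

#' Six-frame translation
#'
#' Frames 1-3 are the forward strand at offsets 0, 1, 2; frames 4-6 the
#' reverse complement at offsets 0, 1, 2. The bacterial genetic code
#' (translation table 11) is used; internal stops are kept as `*` and
#' alternative start codons are translated as their table-11 amino acid, not
#' forced to M.
#'
#' @param seq DNA string (length >= 3).
#' @return character vector of 6 amino-acid strings.
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  code <- Biostrings::getGeneticCode("11")
  one <- function(s, off) {
    L <- nchar(s) - off
    L <- L - L %% 3L
    if (L < 3L) return("")
    x <- Biostrings::DNAString(substr(s, off + 1L, off + L))
    as.character(Biostrings::translate(x, genetic.code = code,
                                       if.fuzzy.codon = "X"))
  }
  rc <- revcomp(seq)
  c(one(seq, 0L), one(seq, 1L), one(seq, 2L),
    one(rc, 0L), one(rc, 1L), one(rc, 2L))
}

#' Filter domain hits at a strict e-value threshold
#'
#' Hits are kept iff `e_value < e_threshold` (strictly); duplicates of the
#' same (query, domain) pair — e.g. the same domain found in several frames —
#' collapse to one record (the smallest e-value).
#'
#' @param hits data.frame with columns query, domain, e_value.
#' @param e_threshold default 1e-10.
#' @return filtered, deduplicated data.frame.
#' @export
filter_hits <- function(hits, e_threshold = 1e-10) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(query = character(0), domain = character(0),
                      e_value = numeric(0)))
  }
  if (any(hits$e_value <= 0)) stop("non-positive e-value")
  hits <- hits[hits$e_value < e_threshold, , drop = FALSE]
  hits <- hits[order(hits$e_value), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("query", "domain")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# -- GO DAG -------------------------------------------------------------------

#' Construct a GO DAG from term and edge tables
#'
#' @param terms data.frame: id, name, namespace (`BP`/`MF`/`CC`).
#' @param edges data.frame: child, parent (is_a edges).
#' @return object of class `go_dag` with `terms`, `edges`, and a
#'   precomputed `parents` list. Acyclicity is verified.
#' @export
go_dag <- function(terms, edges) {
  parents <- split(edges$parent, edges$child)
  dag <- structure(list(terms = terms, edges = edges, parents = parents),
                   class = "go_dag")
  depth <- dag_depths(dag)    # errors on cycles
  dag$depth <- depth
  dag
}

# Longest-path depth from roots; detects cycles.
dag_depths <- function(dag) {
  ids <- dag$terms$id
  depth <- setNames(rep(NA_integer_, length(ids)), ids)
  visiting <- setNames(logical(length(ids)), ids)
  walk <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    if (visiting[[id]]) stop("cycle in GO DAG at ", id)
    visiting[[id]] <<- TRUE
    ps <- dag$parents[[id]]
    d <- if (is.null(ps)) 0L else 1L + max(vapply(ps, walk, integer(1)))
    visiting[[id]] <<- FALSE
    depth[[id]] <<- d
    d
  }
  for (id in ids) walk(id)
  depth
}

#' All ancestors (inclusive) of a set of terms
#' @param dag a `go_dag`.
#' @param ids term ids.
#' @return character vector of the ids and all their ancestors.
#' @export
go_ancestors <- function(dag, ids) {
  seen <- character(0)
  frontier <- ids
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
  }
  seen
}

#' Parse a (subset of an) OBO ontology file
#'
#' Reads `[Term]` stanzas, extracting id, name, namespace and is_a edges;
#' obsolete terms are dropped. Namespaces are abbreviated to BP/MF/CC.
#'
#' @param path OBO file.
#' @return a `go_dag`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  stanza <- cumsum(lines == "[Term]")
  inside <- stanza > 0 & !grepl("^\\[(?!Term)", lines, perl = TRUE)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  terms <- list(); edges <- list()
  for (s in split(lines[inside], stanza[inside])) {
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), s,
                                                value = TRUE))
      if (length(v)) v else NA_character_
    }
    if (any(s == "is_obsolete: true")) next
    id <- get1("id")[1]
    if (is.na(id)) next
    isa <- sub(" !.*$", "", get1("is_a"))
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = get1("name")[1],
      namespace = unname(ns_map[get1("namespace")[1]]),
      stringsAsFactors = FALSE)
    if (!all(is.na(isa))) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = isa[!is.na(isa)], stringsAsFactors = FALSE)
    }
  }
  go_dag(do.call(rbind, terms),
         if (length(edges)) do.call(rbind, edges) else
           data.frame(child = character(0), parent = character(0)))
}

#' Read a 3-column GO edge table (child, parent, namespace)
#' @param path TSV file with header.
#' @return a `go_dag` (term names set to ids).
#' @export
read_go_edges <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  ids <- unique(c(x$child, x$parent))
  ns <- setNames(rep("BP", length(ids)), ids)
  if (!is.null(x$namespace)) {
    ns[x$child] <- x$namespace
  }
  go_dag(data.frame(id = ids, name = ids, namespace = unname(ns[ids]),
                    stringsAsFactors = FALSE),
         x[, c("child", "parent")])
}

#' Read a pfam2go-style mapping
#'
#' Lines look like `Pfam:PF00001 7tm_1 > GO:receptor activity ; GO:0004930`;
#' comment lines start with `!`.
#'
#' @param path mapping file.
#' @return data.frame: domain, go_id.
#' @export
read_pfam2go <- function(path) {
  lines <- grep("^!", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  dom <- sub("^Pfam:(\\S+).*", "\\1", lines)
  go <- sub(".*; (GO:\\d+)\\s*$", "\\1", lines)
  data.frame(domain = dom, go_id = go, stringsAsFactors = FALSE)
}

#' Map filtered domain hits to propagated GO annotations
#'
#' Direct terms are unioned per gene, propagated to all ancestors (true-path
#' rule) and restricted to the requested namespace. GO ids absent from the
#' DAG raise a warning and are skipped.
#'
#' @param hits filtered data.frame (query, domain, ...).
#' @param domain2go data.frame: domain, go_id.
#' @param dag a `go_dag`.
#' @param namespace ontology to keep (default `"BP"`).
#' @return named list gene -> character vector of GO ids.
#' @export
annotate_go <- function(hits, domain2go, dag, namespace = "BP") {
  known <- dag$terms$id
  ns_of <- setNames(dag$terms$namespace, dag$terms$id)
  mg <- merge(hits[, c("query", "domain")], domain2go, by = "domain")
  bad <- setdiff(unique(mg$go_id), known)
  if (length(bad)) {
    warning("GO ids not in DAG, skipped: ", paste(bad, collapse = ", "))
    mg <- mg[!mg$go_id %in% bad, , drop = FALSE]
  }
  ann <- lapply(split(mg$go_id, mg$query), function(ids) {
    a <- go_ancestors(dag, unique(ids))
    a[ns_of[a] == namespace]
  })
  ann[lengths(ann) > 0L]
}

# one-sided hypergeometric tail: P(X >= k)
hyper_tail <- function(k, K, N, n) {
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' GO term overrepresentation test
#'
#' Classic: per term, a one-sided Fisher exact test (hypergeometric tail) of
#' the 2x2 table {interest, universe \ interest} x {annotated, not}. Elim:
#' terms are processed children-before-parents; whenever a term is
#' significant at `elim_alpha`, its annotated genes are removed from all its
#' ancestors' annotation lists before those are tested, decorrelating nested
#' terms. No multiple-testing correction is applied to the ranking (a
#' Benjamini-Hochberg column is emitted for information only).
#'
#' @param universe named list gene -> GO ids (annotations are re-propagated
#'   internally, so direct annotations are accepted).
#' @param interest character vector of genes of interest (must be a subset of
#'   the universe).
#' @param dag a `go_dag`.
#' @param algorithm `"classic"` or `"elim"` (ranking statistic).
#' @param elim_alpha significance level driving elim gene removal.
#' @param namespace ontology tested (default `"BP"`).
#' @return data.frame ranked by the chosen p-value: term, name, annotated,
#'   significant (interest genes annotated), expected, p_classic, p_elim,
#'   bh_fdr.
#' @export
go_enrichment <- function(universe, interest, dag,
                          algorithm = c("classic", "elim"),
                          elim_alpha = 0.01, namespace = "BP") {
  algorithm <- match.arg(algorithm)
  if (!length(interest)) stop("empty interest set")
  if (!all(interest %in% names(universe))) {
    stop("interest genes must be part of the universe")
  }
  ns_of <- setNames(dag$terms$namespace, dag$terms$id)
  prop <- lapply(universe, function(ids) {
    ids <- intersect(ids, dag$terms$id)
    a <- go_ancestors(dag, ids)
    a[ns_of[a] == namespace]
  })
  term_genes <- split(rep(names(prop), lengths(prop)), unlist(prop))
  term_genes <- lapply(term_genes, unique)
  if (!length(term_genes)) stop("no annotated terms in namespace")

  N <- length(universe)
  n <- length(interest)
  terms <- names(term_genes)

  classic <- vapply(terms, function(t) {
    g <- term_genes[[t]]
    hyper_tail(sum(g %in% interest), length(g), N, n)
  }, numeric(1))

  # elim: bottom-up, removing significant children's genes from ancestors
  ord <- order(-dag$depth[terms])
  removed <- lapply(terms, function(t) character(0))
  names(removed) <- terms
  p_elim <- setNames(numeric(length(terms)), terms)
  for (t in terms[ord]) {
    g <- setdiff(term_genes[[t]], removed[[t]])
    p <- hyper_tail(sum(g %in% interest), length(g), N, n)
    p_elim[t] <- p
    if (p < elim_alpha) {
      anc <- setdiff(go_ancestors(dag, t), t)
      anc <- intersect(anc, terms)
      for (a in anc) removed[[a]] <- union(removed[[a]], g)
    }
  }

  name_of <- setNames(dag$terms$name, dag$terms$id)
  res <- data.frame(
    term = terms,
    name = unname(name_of[terms]),
    annotated = lengths(term_genes),
    significant = vapply(term_genes, function(g) sum(g %in% interest),
                         integer(1)),
    expected = lengths(term_genes) * n / N,
    p_classic = classic,
    p_elim = unname(p_elim[terms]),
    stringsAsFactors = FALSE)
  key <- if (algorithm == "classic") res$p_classic else res$p_elim
  res$bh_fdr <- stats::p.adjust(key, method = "BH")
  res <- res[order(key, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a domain-hit TSV (columns: query, domain, e_value)
#' @param path TSV with header.
#' @return data.frame.
#' @export
read_domain_hits <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  ev <- suppressWarnings(as.numeric(x$e_value))
  if (anyNA(ev)) stop("malformed e-value at line ", which(is.na(ev))[1] + 1L)
  x$e_value <- ev
  x
}
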