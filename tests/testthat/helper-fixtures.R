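# In-code fixtures shared across the suite.  Everything is generated at
# test time; nothing binary ships with the package.

# writes OBO stanzas to a temp file and returns the path
write_obo_text <- function(...) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", ...), path)
  path
}

# chain root -> mid -> leaf plus a second root branch
toy_ontology <- function() {
  new_trait_ontology(
    tibble::tibble(
      term_id = c("T:1", "T:2", "T:3", "T:4"),
      name = c("root one", "middle", "leaf", "root two")),
    tibble::tibble(term_id = c("T:2", "T:3"),
                   parent_id = c("T:1", "T:2")))
}

# 10 terms x 12 genes over a 100-gene background, fixed layout
toy_annotation <- function(seed = 1, n_genes = 100, n_terms = 10,
                           genes_per_term = 12) {
  withr::with_seed(seed, {
    annotation_set(
      tibble::tibble(
        term_id = rep(sprintf("T%02d", seq_len(n_terms)),
                      each = genes_per_term),
        gene_id = sprintf("g%03d", unlist(lapply(seq_len(n_terms), function(i)
          sample(n_genes, genes_per_term))))),
      background = sprintf("g%03d", seq_len(n_genes)))
  })
}

# column-stochastic transition matrix of two disjoint triangles
two_triangles <- function() {
  A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  diag(A) <- 1
  sweep(A, 2, colSums(A), "/")
}

# exhaustive upper-tail hypergeometric oracle: enumerate all C(N, n) draws
enum_tail <- function(N, n, M, k) {
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= M)
  mean(overlap >= k)
}

# naive O(records x genes) window-link oracle
scan_links <- function(records, genes, ld_kb) {
  d <- ld_kb * 1000
  out <- list()
  for (i in seq_len(nrow(records))) for (j in seq_len(nrow(genes))) {
    if (records$chromosome[[i]] == genes$chromosome[[j]] &&
        records$position[[i]] >= max(genes$start[[j]] - d, 1) &&
        records$position[[i]] <= genes$end[[j]] + d) {
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = genes$gene_id[[j]], marker_name = records$marker_name[[i]])
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(gene_id = character(), marker_name = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), gene_id, marker_name)
}

toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(10000L, 15000L, 10000L),
    end = c(12000L, 18000L, 12000L),
    strand = c("+", "-", "+"))
}

toy_records <- function(pos, chrom = "chr1", p = 1e-8,
                        trait = "plant height", study = "study_A") {
  tibble::tibble(
    marker_name = sprintf("m%02d", seq_along(pos)),
    chromosome = rep_len(chrom, length(pos)),
    position = as.numeric(pos),
    p_value = rep_len(p, length(pos)),
    variant_class = "snp", maf = 0.2,
    trait_name = rep_len(trait, length(pos)),
    study_id = rep_len(study, length(pos)),
    genome_version = "SYNv1")
}

assoc_tsv <- function(df, path = withr::local_tempfile(
                        fileext = ".tsv", .local_envir = parent.frame())) {
  readr::write_tsv(df, path)
  path
}
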