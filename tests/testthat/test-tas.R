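toy_dict <- function(onto = toy_ontology()) {
  trait_dictionary(
    tibble::tibble(trait_label = c("Plant height", "grain weight"),
                   term_id = c("T:3", "T:4")),
    onto)
}

test_that("marker-gene links use closed windows clamped at 1", {
  genes <- toy_genes()[1, ]                       # gA chr1 [10000, 12000]
  expect_equal(assign_markers_to_genes(toy_records(1000), genes, 10)$gene_id,
               "gA")                              # window clamps to [1, 22000]
  expect_equal(nrow(assign_markers_to_genes(toy_records(22000), genes, 10)), 1)
  expect_equal(nrow(assign_markers_to_genes(toy_records(22001), genes, 10)), 0)
  expect_equal(nrow(assign_markers_to_genes(toy_records(15000, chrom = "chr2"),
                                            genes, 10)), 0)
  expect_error(assign_markers_to_genes(toy_records(1), genes, -5),
               class = "traitlink_param_error")
})

test_that("window assignment agrees with the exhaustive pair-scan oracle", {
  withr::with_seed(11, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:15),
      chromosome = sample(c("chr1", "chr2"), 15, replace = TRUE),
      start = sample.int(200000, 15), strand = "+") |>
      dplyr::mutate(end = start + sample(1000:5000, 15))
    rec <- toy_records(sample.int(250000, 40),
                       chrom = sample(c("chr1", "chr2"), 40, replace = TRUE))
    for (d in c(5, 10, 25)) {
      got <- assign_markers_to_genes(rec, genes, d) |>
        dplyr::select(gene_id, marker_name) |>
        dplyr::arrange(gene_id, marker_name)
      expect_equal(as.data.frame(got), as.data.frame(scan_links(rec, genes, d)))
    }
  })
  # one marker inside two overlapping gene windows yields two links
  genes <- toy_genes()[1:2, ]                     # gA, gB overlap on chr1
  links <- assign_markers_to_genes(toy_records(14000), genes, 10)
  expect_equal(sort(links$gene_id), c("gA", "gB"))
})

test_that("evidence rows multiply over terms and deduplicate over studies", {
  onto <- toy_ontology()
  dict <- trait_dictionary(
    tibble::tibble(trait_label = c("plant height", "plant height"),
                   term_id = c("T:3", "T:4")), onto)
  one_gene <- toy_genes()[1, ]
  tab <- build_gene_to_term_table(toy_records(11000), one_gene, dict, onto,
                                  ld_levels = 10)
  expect_equal(nrow(tab), 2)                      # 1 link x 2 terms
  expect_equal(nrow(distinct_gene_terms(tab)), 2)

  # two studies hitting the same (gene, term): 2 evidence rows, 1 pair
  rec <- dplyr::bind_rows(toy_records(11000, study = "s1"),
                          toy_records(11000, study = "s2"))
  tab2 <- build_gene_to_term_table(rec, one_gene, toy_dict(), onto,
                                   ld_levels = 10)
  expect_equal(nrow(tab2), 2)
  expect_equal(nrow(distinct_gene_terms(tab2)), 1)
})

test_that("the significance gate honours per-study overrides", {
  onto <- toy_ontology()
  rec <- dplyr::bind_rows(toy_records(11000, p = 1e-4, study = "lenient"),
                          toy_records(11000, p = 1e-4, study = "strict"))
  tab <- build_gene_to_term_table(rec, toy_genes(), toy_dict(), onto,
                                  ld_levels = 10,
                                  p_cutoff = c(lenient = 1e-3, strict = 1e-6))
  expect_equal(unique(tab$study_id), "lenient")
  # scalar gate drops both (default 1e-5)
  tab2 <- build_gene_to_term_table(rec, toy_genes(), toy_dict(), onto,
                                   ld_levels = 10)
  expect_equal(nrow(tab2), 0)
})

test_that("mixed genome versions are a hard error", {
  rec <- dplyr::bind_rows(toy_records(11000), toy_records(11000))
  rec$genome_version <- c("V3", "V4")
  expect_error(
    build_gene_to_term_table(rec, toy_genes(), toy_dict(), toy_ontology()),
    class = "traitlink_genome_error")
})

test_that("unique genes and pairs grow monotonically with the LD window", {
  for (seed in 1:4) {
    spec <- fixture_spec(seed = seed)
    genes <- generate_gene_models(spec)
    dict <- generate_trait_dictionary(spec, onto <- generate_ontology(spec))
    st <- generate_association_study(spec, genes, dict)
    counts <- tas_counts(build_gene_to_term_table(
      st$records, genes, dict, onto, ld_levels = c(10, 25)))
    expect_equal(counts$ld_level_kb, c(10, 25))
    expect_true(counts$n_genes[1] <= counts$n_genes[2])
    expect_true(counts$n_pairs[1] <= counts$n_pairs[2])
  }
})

test_that("deduplicated output is invariant to input row order", {
  spec <- fixture_spec(seed = 3)
  genes <- generate_gene_models(spec)
  onto <- generate_ontology(spec)
  dict <- generate_trait_dictionary(spec, onto)
  st <- generate_association_study(spec, genes, dict)
  shuffled <- withr::with_seed(99, st$records[sample.int(nrow(st$records)), ])
  a <- distinct_gene_terms(build_gene_to_term_table(st$records, genes, dict, onto))
  b <- distinct_gene_terms(build_gene_to_term_table(shuffled, genes, dict, onto))
  key <- function(x) dplyr::arrange(as.data.frame(x), ld_level_kb, gene_id, term_id)
  expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("trait queries resolve direct and descendant annotations", {
  onto <- toy_ontology()
  tab <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), term_id = c("T:3", "T:3", "T:2"),
    ld_level_kb = 10)
  expect_equal(query_genes_by_trait(tab, "T:3", onto), c("g1", "g2"))
  expect_equal(query_genes_by_trait(tab, "T:1", onto), character(0))
  expect_equal(query_genes_by_trait(tab, "T:1", onto, descendants = TRUE),
               c("g1", "g2", "g3"))
  expect_error(query_genes_by_trait(tab, "nope", onto),
               class = "traitlink_lookup_error")

  # diamond descendants: gene annotated via two paths appears once
  dia <- new_trait_ontology(
    tibble::tibble(term_id = c("R", "A", "B", "X"), name = c("r", "a", "b", "x")),
    tibble::tibble(term_id = c("A", "B", "X", "X"), parent_id = c("R", "R", "A", "B")))
  tab2 <- tibble::tibble(gene_id = c("g1", "g1"), term_id = c("X", "A"),
                         ld_level_kb = 10)
  expect_equal(query_genes_by_trait(tab2, "R", dia, descendants = TRUE), "g1")
})

test_that("gene-to-term tables round-trip through their TSV layout", {
  onto <- toy_ontology()
  tab <- build_gene_to_term_table(toy_records(11000), toy_genes(), toy_dict(),
                                  onto, ld_levels = c(10, 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_term_table(tab, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr[1:6], c("gene_id", "term_id", "ld_level_kb", "study_id",
                           "marker_name", "p_value"))
  back <- read_gene_term_table(path)
  expect_equal(as.data.frame(back)[, 1:6], as.data.frame(tab)[, 1:6])
})

test_that("unseen labels fall back to similarity suggestions above threshold", {
  onto <- toy_ontology()
  dict <- toy_dict(onto)
  freq <- term_frequency(c(`T:1` = 40, `T:2` = 10, `T:3` = 4, `T:4` = 20),
                         total = 100)

  hit <- map_trait_to_terms("plant  Height ", dict)   # normalization
  expect_equal(hit$term_id, "T:3")
  expect_equal(hit$provenance, "curated")

  # brute-force oracle: score every candidate term by hand
  label <- "leaf trait"
  known <- freq$term_id[freq$count > 0]
  pool <- onto$terms
  q_tokens <- strsplit(label, " ")[[1]]
  cl_p <- pool$term_id[vapply(strsplit(tolower(pool$name), " "),
                              function(tk) any(tk %in% q_tokens), logical(1))]
  scores <- vapply(pool$term_id, function(t) {
    cl_r <- intersect(c(t, term_ancestors(onto, t)), known)
    if (length(cl_r) == 0) return(0)
    semantic_similarity(cl_p, cl_r, freq)
  }, numeric(1))
  best <- names(which.max(scores))

  got <- map_trait_to_terms(label, dict, onto, freq, threshold = 0.4)
  if (max(scores) >= 0.4) {
    expect_equal(got$term_id, best)
    expect_equal(got$provenance, "similarity-suggested")
  } else {
    expect_equal(nrow(got), 0)
  }

  # an impossible threshold yields an empty (valid) result
  none <- map_trait_to_terms(label, dict, onto, freq, threshold = 1.01)
  expect_equal(nrow(none), 0)
})
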