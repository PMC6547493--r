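test_that("ontology generator hits the requested shape exactly", {
  spec <- fixture_spec(seed = 1, roots = 9, depth = 3, branching = 2)
  onto <- generate_ontology(spec)
  expect_equal(nrow(onto$terms), 9 + 18 + 36)
  expect_equal(sum(onto$terms$is_root), 9)
  expect_equal(max(onto$terms$level), 3)
  expect_equal(unname(table(onto$terms$level)), c(9L, 18L, 36L),
               ignore_attr = TRUE)
})

test_that("generators are byte-reproducible from (spec, seed)", {
  spec <- fixture_spec(seed = 12)
  f1 <- withr::local_tempfile(fileext = ".obo")
  f2 <- withr::local_tempfile(fileext = ".obo")
  write_obo(generate_ontology(spec), f1)
  write_obo(generate_ontology(spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_identical(generate_expression(spec)$expr,
                   generate_expression(spec)$expr)
  expect_identical(generate_gene_models(spec), generate_gene_models(spec))
  expect_false(identical(
    generate_expression(fixture_spec(seed = 12))$expr,
    generate_expression(fixture_spec(seed = 13))$expr))
})

test_that("generated OBO round-trips through the parser with zero loss", {
  spec <- fixture_spec(seed = 4, depth = 4)
  onto <- generate_ontology(spec)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(onto, path)
  back <- read_obo(path)
  ord <- function(o) list(
    terms = dplyr::arrange(as.data.frame(o$terms), term_id),
    parents = dplyr::arrange(as.data.frame(o$parents), term_id, parent_id))
  expect_equal(ord(back), ord(onto), ignore_attr = TRUE)
})

test_that("some generated terms carry a second parent (DAG, not tree)", {
  spec <- fixture_spec(seed = 5, roots = 6, depth = 5,
                       extra_parent_prob = 0.2)
  onto <- generate_ontology(spec)
  multi <- table(onto$parents$term_id)
  expect_true(any(multi >= 2))
  # second parents never change a term's level
  lv <- setNames(onto$terms$level, onto$terms$term_id)
  expect_true(all(lv[onto$parents$term_id] == lv[onto$parents$parent_id] + 1))
})

test_that("association truth tables are sound and complete for the pipeline", {
  for (seed in c(2, 8)) {
    spec <- fixture_spec(seed = seed)
    onto <- generate_ontology(spec)
    genes <- generate_gene_models(spec)
    dict <- generate_trait_dictionary(spec, onto)
    st <- generate_association_study(spec, genes, dict)
    expect_equal(nrow(st$causal_genes), sum(spec$causal_genes_per_trait))

    got <- distinct_gene_terms(build_gene_to_term_table(
      st$records, genes, dict, onto, ld_levels = spec$ld_levels,
      p_cutoff = spec$p_cutoff))
    key <- function(x) dplyr::arrange(as.data.frame(x)[
      c("ld_level_kb", "gene_id", "term_id")], ld_level_kb, gene_id, term_id)
    expect_equal(key(got), key(st$truth), ignore_attr = TRUE)
  }
})

test_that("zero causal genes give an empty truth table", {
  spec <- fixture_spec(seed = 3, causal_genes_per_trait = 0)
  genes <- generate_gene_models(spec)
  dict <- generate_trait_dictionary(spec, generate_ontology(spec))
  st <- generate_association_study(spec, genes, dict)
  expect_equal(nrow(st$truth), 0)
})

test_that("planted expression reaches the designed correlation structure", {
  # near-noiseless limit: within-module correlations approach 1
  tight <- generate_expression(fixture_spec(seed = 9, modules = 2,
                                            genes_per_module = 8,
                                            within_cor = 0.999))
  C <- stats::cor(t(tight$expr))
  within <- C[1:8, 1:8][upper.tri(C[1:8, 1:8])]
  expect_true(all(within > 0.99))

  # across modules the mean correlation sits within sampling error of 0
  ex <- generate_expression(fixture_spec(seed = 10))
  C2 <- stats::cor(t(ex$expr))
  labels <- ex$labels$module
  between <- C2[labels == "t01", labels == "t02"]
  expect_lt(abs(mean(between)), 3 / sqrt(ncol(ex$expr)))
})

test_that("make_fixtures writes every dialect its reader consumes", {
  dir <- withr::local_tempdir()
  make_fixtures(fixture_spec(seed = 21, depth = 3), dir)
  onto <- read_obo(file.path(dir, "ontology.obo"))
  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  rec <- read_association_table(file.path(dir, "associations.tsv"))
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_gt(nrow(onto$terms), 0)
  expect_equal(nrow(genes), 60)
  expect_equal(nrow(rejected_rows(rec)), 0)
  expect_equal(dim(expr), c(100, 40))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$command, "make-fixtures")
})
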