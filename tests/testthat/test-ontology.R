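test_that("read_obo loads terms, drops obsolete stanzas, keeps DAG parents", {
  path <- write_obo_text(
    "", "[Term]", "id: T:1", "name: root",
    "", "[Term]", "id: T:2", "name: child a", "is_a: T:1 ! root",
    "", "[Term]", "id: T:3", "name: child b", "is_a: T:1",
    "", "[Term]", "id: T:4", "name: dead", "is_a: T:1", "is_obsolete: true",
    "", "[Typedef]", "id: part_of")
  onto <- read_obo(path)
  expect_equal(nrow(onto$terms), 3)
  expect_equal(sum(onto$terms$is_root), 1)
  expect_false("T:4" %in% onto$terms$term_id)

  # a term may have two parents: DAG, not tree
  p2 <- write_obo_text(
    "", "[Term]", "id: T:1", "name: r1",
    "", "[Term]", "id: T:2", "name: r2",
    "", "[Term]", "id: T:3", "name: both", "is_a: T:1", "is_a: T:2")
  onto2 <- read_obo(p2)
  expect_equal(sort(onto2$parents$parent_id[onto2$parents$term_id == "T:3"]),
               c("T:1", "T:2"))
})

test_that("structural defects are rejected at load", {
  cyc <- write_obo_text(
    "", "[Term]", "id: A", "name: a", "is_a: B",
    "", "[Term]", "id: B", "name: b", "is_a: A")
  expect_error(read_obo(cyc), class = "traitlink_structure_error")
  expect_error(read_obo(cyc), "cycle")

  dangling <- write_obo_text(
    "", "[Term]", "id: A", "name: a", "is_a: NOPE")
  expect_error(read_obo(dangling), class = "traitlink_structure_error")
})

test_that("term levels follow the shortest parent path to a root", {
  onto <- toy_ontology()
  expect_equal(term_level(onto, "T:1"), 1)
  expect_equal(term_level(onto, "T:2"), 2)
  expect_equal(term_level(onto, "T:3"), 3)
  expect_error(term_level(onto, "T:99"), class = "traitlink_lookup_error")

  # multi-parent term with parents on levels 1 and 3 sits on level 2,
  # matching enumeration of all its root paths (lengths 1 and 3)
  multi <- new_trait_ontology(
    tibble::tibble(term_id = c("R", "A", "B", "X"),
                   name = c("root", "a", "b", "x")),
    tibble::tibble(term_id = c("A", "B", "X", "X"),
                   parent_id = c("R", "A", "R", "B")))
  paths_to_root <- c(1, 3)  # X -> R and X -> B -> A -> R
  expect_equal(term_level(multi, "X"), 1 + min(paths_to_root))
})

test_that("level assignment is stable under stanza reordering", {
  stanzas <- list(
    c("[Term]", "id: T:1", "name: root"),
    c("[Term]", "id: T:2", "name: mid", "is_a: T:1"),
    c("[Term]", "id: T:3", "name: leaf", "is_a: T:2"))
  lv_for <- function(ord) {
    path <- do.call(write_obo_text, as.list(unlist(lapply(stanzas[ord], c, ""))))
    onto <- read_obo(path)
    term_level(onto, c("T:1", "T:2", "T:3"))
  }
  expect_equal(lv_for(c(3, 1, 2)), c(1, 2, 3))
  expect_equal(lv_for(c(2, 3, 1)), c(1, 2, 3))
})

test_that("ancestor and descendant closures list each term once", {
  onto <- toy_ontology()
  expect_equal(term_ancestors(onto, "T:1"), character(0))
  expect_equal(term_ancestors(onto, "T:3"), c("T:1", "T:2"))
  expect_equal(term_descendants(onto, "T:1"), c("T:2", "T:3"))

  # diamond: X under both A and B, both under R
  dia <- new_trait_ontology(
    tibble::tibble(term_id = c("R", "A", "B", "X"), name = c("r", "a", "b", "x")),
    tibble::tibble(term_id = c("A", "B", "X", "X"),
                   parent_id = c("R", "R", "A", "B")))
  # BFS oracle over explicit edges
  bfs_up <- function(start, edges) {
    seen <- character()
    frontier <- start
    while (length(frontier)) {
      nxt <- setdiff(edges$parent_id[edges$term_id %in% frontier],
                     c(seen, start))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    sort(seen)
  }
  expect_equal(term_ancestors(dia, "X"), bfs_up("X", dia$parents))
  expect_equal(anyDuplicated(term_ancestors(dia, "X")), 0L)
})

test_that("level table and OBO writers round-trip the structure", {
  onto <- toy_ontology()
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_level_table(onto, tf)
  expect_equal(names(tab), c("term_id", "Level1", "Level2", "Level3"))
  expect_equal(tab$Level3[tab$term_id == "T:3"], "leaf")
  expect_true(is.na(tab$Level2[tab$term_id == "T:1"]))

  of <- withr::local_tempfile(fileext = ".obo")
  write_obo(onto, of)
  back <- read_obo(of)
  expect_equal(back$terms, onto$terms[order(onto$terms$term_id), ],
               ignore_attr = TRUE)
  expect_equal(dplyr::arrange(back$parents, term_id),
               dplyr::arrange(onto$parents, term_id))
})
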