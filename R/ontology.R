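#' Read a trait/function ontology from an OBO file
#'
#' Parses the OBO flat-file dialect used by the Plant Trait Ontology and the
#' Gene Ontology: `[Term]` stanzas carrying `id`, `name`, `is_a` and
#' `is_obsolete` tags.  Obsolete terms are dropped; `is_a` edges become
#' parent links.  Other relationship types (`part_of` etc.) and OBO 1.4
#' cross-products are ignored: the hierarchy here is pure parent layering.
#'
#' The loaded structure is validated: the parent graph must be acyclic,
#' every `is_a` target must exist, and every non-root term must reach a
#' root.  Term levels (1 = root) are assigned as one plus the length of the
#' shortest parent path to any root, so a term with parents on several
#' layers sits on the shallowest layer consistent with its parents.
#'
#' @param path Path to an OBO file.
#' @return A `trait_ontology` object: a list with
#'   * `terms`: tibble with columns `term_id`, `name`, `level`, `is_root`,
#'     `category` (the name of the level-1 root the term falls under;
#'     the first root in `term_id` order when several apply);
#'   * `parents`: tibble of `is_a` edges with columns `term_id`,
#'     `parent_id`.
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: TO:0000001", "name: plant trait", "",
#'   "[Term]", "id: TO:0000002", "name: plant height",
#'   "is_a: TO:0000001 ! plant trait"), obo)
#' onto <- read_obo(obo)
#' term_level(onto, "TO:0000002")
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("OBO file not found: ", path), class = "traitlink_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)

  # split into stanzas at [Term] / other headers
  hdr <- grepl("^\\[.*\\]$", lines)
  stanza_id <- cumsum(hdr)
  in_term <- stanza_id %in% stanza_id[hdr & lines == "[Term]"]

  terms <- list()
  parents_from <- character()
  parents_to <- character()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    cur
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (hdr[[i]]) {
      fin <- flush(cur)
      if (!is.null(fin)) terms[[fin$id]] <- fin
      cur <- if (ln == "[Term]") list(parents = character()) else NULL
      next
    }
    if (is.null(cur) || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("^is_a:", "", ln))
      tgt <- trimws(sub("!.*$", "", tgt))       # strip trailing comment
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  fin <- flush(cur)
  if (!is.null(fin)) terms[[fin$id]] <- fin

  if (length(terms) == 0L) {
    abort("no [Term] stanzas found", class = "traitlink_structure_error")
  }
  term_tbl <- tibble(
    term_id = vapply(terms, function(t) t$id, character(1)),
    name    = vapply(terms, function(t) t$name %||% t$id, character(1))
  )
  parent_tbl <- purrr::map_dfr(terms, function(t) {
    if (length(t$parents) == 0L) return(NULL)
    tibble(term_id = t$id, parent_id = unique(t$parents))
  })
  # edges pointing at obsolete (dropped) parents are pruned silently; edges
  # pointing at terms never defined are structural errors
  new_trait_ontology(term_tbl, parent_tbl)
}

#' Construct an ontology from term and edge tables
#'
#' Lower-level constructor behind [read_obo()] and the synthetic generator.
#' Validates uniqueness, referential integrity and acyclicity, and computes
#' levels and root categories.
#'
#' @param terms Tibble with columns `term_id`, `name`.
#' @param parents Tibble with columns `term_id`, `parent_id` (may be empty).
#' @return A `trait_ontology` object; see [read_obo()].
#' @export
new_trait_ontology <- function(terms, parents) {
  terms <- as_tibble(terms)
  if (anyDuplicated(terms$term_id)) {
    abort(paste0("duplicate term ids: ",
                 paste(head(unique(terms$term_id[duplicated(terms$term_id)]), 5),
                       collapse = ", ")),
          class = "traitlink_structure_error")
  }
  if (is.null(parents) || nrow(parents) == 0L) {
    parents <- tibble(term_id = character(), parent_id = character())
  }
  parents <- distinct(as_tibble(parents), .data$term_id, .data$parent_id)
  bad <- setdiff(parents$parent_id, terms$term_id)
  if (length(bad) > 0L) {
    abort(paste0("is_a target not defined in ontology: ", bad[[1]]),
          class = "traitlink_structure_error")
  }

  lv <- compute_levels(terms$term_id, parents)   # errors on cycles
  terms$level <- lv[terms$term_id]
  terms$is_root <- !(terms$term_id %in% parents$term_id)

  # root category: name of the first (by id order) level-1 ancestor
  roots <- sort(terms$term_id[terms$is_root])
  root_name <- setNames(terms$name, terms$term_id)
  cat_of <- setNames(rep(NA_character_, nrow(terms)), terms$term_id)
  cat_of[roots] <- root_name[roots]
  pmap <- split(parents$parent_id, parents$term_id)
  for (id in terms$term_id[order(terms$level)]) {
    if (!is.na(cat_of[[id]])) next
    pc <- sort(pmap[[id]])
    cats <- cat_of[pc]
    cat_of[[id]] <- cats[!is.na(cats)][1]
  }
  terms$category <- unname(cat_of[terms$term_id])

  structure(
    list(terms = terms[, c("term_id", "name", "level", "is_root", "category")],
         parents = parents),
    class = "trait_ontology"
  )
}

# Shortest-path-to-root levels via Kahn's algorithm; detects cycles and
# names one participating term.
compute_levels <- function(ids, parents) {
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  np <- integer(n)                               # number of unresolved parents
  tab <- table(parents$term_id)
  np[idx[names(tab)]] <- as.integer(tab)
  children <- split(parents$term_id, parents$parent_id)
  level <- setNames(rep(NA_integer_, n), ids)
  queue <- ids[np == 0L]
  level[queue] <- 1L
  remaining <- np
  while (length(queue) > 0L) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (ch in children[[cur]] %||% character()) {
      lv <- level[[ch]]
      cand <- level[[cur]] + 1L
      level[[ch]] <- if (is.na(lv)) cand else min(lv, cand)
      remaining[[idx[[ch]]]] <- remaining[[idx[[ch]]]] - 1L
      if (remaining[[idx[[ch]]]] == 0L) queue <- c(queue, ch)
    }
  }
  if (anyNA(level)) {
    member <- ids[is.na(level)][[1]]
    abort(paste0("cycle detected in ontology involving term ", member),
          class = "traitlink_structure_error")
  }
  level
}

#' @export
print.trait_ontology <- function(x, ...) {
  cat(sprintf(
    "<trait_ontology> %d terms, %d roots, %d is_a edges, depth %d\n",
    nrow(x$terms), sum(x$terms$is_root), nrow(x$parents), max(x$terms$level)))
  invisible(x)
}

#' @export
tidy.trait_ontology <- function(x, ...) x$terms

#' Hierarchical level of a term
#'
#' Levels count layers from the top: roots are level 1 and every other term
#' sits one below its shallowest parent (shortest parent path to any root).
#'
#' @param ontology A `trait_ontology`.
#' @param term_id Term accession(s).
#' @return Integer vector of levels.
#' @export
term_level <- function(ontology, term_id) {
  check_terms_exist(ontology, term_id)
  lv <- setNames(ontology$terms$level, ontology$terms$term_id)
  unname(lv[term_id])
}

#' Ancestors or descendants of a term
#'
#' `term_ancestors()` returns the transitive closure over parent links,
#' excluding the term itself; `term_descendants()` the closure over child
#' links.  Each related term is listed once even when the DAG offers several
#' paths to it.
#'
#' @inheritParams term_level
#' @param term_id A single term accession.
#' @return Character vector of term accessions (sorted).
#' @export
term_ancestors <- function(ontology, term_id) {
  check_terms_exist(ontology, term_id)
  closure(term_id, split(ontology$parents$parent_id, ontology$parents$term_id))
}

#' @rdname term_ancestors
#' @export
term_descendants <- function(ontology, term_id) {
  check_terms_exist(ontology, term_id)
  closure(term_id, split(ontology$parents$term_id, ontology$parents$parent_id))
}

closure <- function(start, adj) {
  seen <- character()
  frontier <- start
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, start))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

check_terms_exist <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "trait_ontology"))
  missing <- setdiff(term_id, ontology$terms$term_id)
  if (length(missing) > 0L) {
    abort(paste0("unknown term: ", paste(head(missing, 5), collapse = ", ")),
          class = "traitlink_lookup_error")
  }
  invisible(TRUE)
}

#' Write the term-level table
#'
#' Emits one row per term with columns `Level1`, `Level2`, ... holding the
#' shortest parent chain from the term's root down to the term itself
#' (names, not accessions, beyond the id column).  Mirrors the layered
#' trait-relationship tables distributed with plant trait ontologies.
#'
#' @inheritParams term_level
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_level_table <- function(ontology, path) {
  depth <- max(ontology$terms$level)
  pmap <- split(ontology$parents$parent_id, ontology$parents$term_id)
  lv <- setNames(ontology$terms$level, ontology$terms$term_id)
  nm <- setNames(ontology$terms$name, ontology$terms$term_id)
  chain <- function(id) {
    # walk up choosing, deterministically, the lexicographically first
    # parent on a shortest path
    path_ids <- id
    cur <- id
    while (lv[[cur]] > 1L) {
      ps <- sort(pmap[[cur]])
      cur <- ps[lv[ps] == lv[[cur]] - 1L][[1]]
      path_ids <- c(cur, path_ids)
    }
    out <- rep(NA_character_, depth)
    out[seq_along(path_ids)] <- nm[path_ids]
    out
  }
  rows <- t(vapply(ontology$terms$term_id, chain, character(depth)))
  colnames(rows) <- paste0("Level", seq_len(depth))
  out <- dplyr::bind_cols(tibble(term_id = ontology$terms$term_id),
                          as_tibble(rows))
  readr::write_tsv(out, path)
  invisible(out)
}

#' Write an ontology back to OBO text
#'
#' Stanzas are emitted in `term_id` order so output bytes are a pure
#' function of the ontology content.
#'
#' @inheritParams term_level
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  pmap <- split(ontology$parents$parent_id, ontology$parents$term_id)
  nm <- setNames(ontology$terms$name, ontology$terms$term_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in sort(ontology$terms$term_id)) {
    writeLines(c("", "[Term]", paste0("id: ", id), paste0("name: ", nm[[id]])),
               con)
    for (p in sort(pmap[[id]] %||% character())) {
      writeLines(paste0("is_a: ", p, " ! ", nm[[p]]), con)
    }
  }
  invisible(path)
}
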