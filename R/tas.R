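#' Assign association markers to genes by LD flanking windows
#'
#' A marker is linked to a gene when both lie on the same chromosome and
#' the marker position falls inside the gene body extended by the LD
#' distance on each side: `[start - d, end + d]`, closed on both sides and
#' clamped at coordinate 1.  One marker may link to several genes (all
#' genes whose windows cover it are kept); each (gene, marker-record) link
#' is emitted once.
#'
#' @param records Association record tibble (see
#'   [read_association_table()]).
#' @param genes Gene-model tibble (`gene_id`, `chromosome`, `start`,
#'   `end`).
#' @param ld_kb LD flanking distance in kilobases (> 0).
#' @return Tibble of links: all record columns plus `gene_id`,
#'   `ld_level_kb`.
#' @export
assign_markers_to_genes <- function(records, genes, ld_kb) {
  if (!is.numeric(ld_kb) || length(ld_kb) != 1L || ld_kb <= 0) {
    abort("ld_kb must be a single positive number",
          class = "traitlink_param_error")
  }
  d <- ld_kb * 1000
  g <- genes %>%
    mutate(.win_lo = pmax(.data$start - d, 1), .win_hi = .data$end + d) %>%
    select(all_of(c("gene_id", "chromosome", ".win_lo", ".win_hi")))
  out <- inner_join(as_tibble(records), g, by = "chromosome",
                    relationship = "many-to-many") %>%
    filter(.data$position >= .data$.win_lo,
           .data$position <= .data$.win_hi) %>%
    select(-all_of(c(".win_lo", ".win_hi"))) %>%
    distinct() %>%
    mutate(ld_level_kb = ld_kb)
  out
}

#' Build a gene-to-term evidence table from association records
#'
#' The core curation step: records are gated on significance, markers are
#' assigned to genes within each LD window, trait labels are resolved to
#' ontology terms through the dictionary, and one evidence row is emitted
#' per (gene link x term).  Records from different studies hitting the
#' same (gene, term) stay as separate evidence rows; the deduplicated
#' relationship view is available via [distinct_gene_terms()].
#'
#' @param records Association records.
#' @param genes Gene models.
#' @param dict A [trait_dictionary()].
#' @param ontology `trait_ontology` used to validate resolved terms (and
#'   to power similarity suggestions when `freq` is given).
#' @param ld_levels LD distances in kb, e.g. `c(10, 25)` (maize-style) or
#'   `c(25, 50)` (rice-style).
#' @param p_cutoff Significance gate: a single threshold, or a named
#'   vector keyed by `study_id` to honour per-study cutoffs (unnamed
#'   default applies to unlisted studies via the `""` name or the first
#'   unnamed element).  Default `1e-5`.
#' @param freq,threshold Passed to [map_trait_to_terms()] for labels
#'   absent from the dictionary.
#' @return A `gene_term_table`: tibble with columns `gene_id`, `term_id`,
#'   `ld_level_kb`, `study_id`, `marker_name`, `p_value`, `trait_name`,
#'   `provenance`.  Attribute `unmapped_traits` lists labels that resolved
#'   to no term.
#' @export
build_gene_to_term_table <- function(records, genes, dict, ontology,
                                     ld_levels = c(10, 25), p_cutoff = 1e-5,
                                     freq = NULL, threshold = 0.4) {
  if (length(ld_levels) == 0L || any(ld_levels <= 0)) {
    abort("ld_levels must be positive LD distances in kb",
          class = "traitlink_param_error")
  }
  gv_rec <- unique(records$genome_version)
  gv_rec <- gv_rec[!is.na(gv_rec) & nzchar(gv_rec)]
  if (length(gv_rec) > 1L) {
    abort(paste0("association records mix genome versions: ",
                 paste(gv_rec, collapse = ", "), " (no lift-over performed)"),
          class = "traitlink_genome_error")
  }

  gate <- resolve_gate(records$study_id, p_cutoff)
  sig <- records[records$p_value <= gate, ]

  labels <- unique(sig$trait_name)
  term_map <- purrr::map(setNames(labels, labels), map_trait_to_terms,
                         dict = dict, ontology = ontology, freq = freq,
                         threshold = threshold)
  unmapped <- labels[vapply(term_map, nrow, integer(1)) == 0L]

  evidence <- purrr::map_dfr(ld_levels, function(d) {
    links <- assign_markers_to_genes(sig, genes, d)
    if (nrow(links) == 0L) return(NULL)
    purrr::map_dfr(seq_len(nrow(links)), function(i) {
      tm <- term_map[[links$trait_name[[i]]]]
      if (nrow(tm) == 0L) return(NULL)
      tibble(gene_id = links$gene_id[[i]], term_id = tm$term_id,
             ld_level_kb = d, study_id = links$study_id[[i]],
             marker_name = links$marker_name[[i]],
             p_value = links$p_value[[i]],
             trait_name = links$trait_name[[i]],
             provenance = tm$provenance)
    })
  })
  if (nrow(evidence) > 0L) {
    check_terms_exist(ontology, unique(evidence$term_id))
    evidence <- distinct(evidence)
  } else {
    evidence <- tibble(gene_id = character(), term_id = character(),
                       ld_level_kb = numeric(), study_id = character(),
                       marker_name = character(), p_value = numeric(),
                       trait_name = character(), provenance = character())
  }
  structure(evidence,
            unmapped_traits = unmapped,
            p_cutoff = p_cutoff,
            ld_levels = ld_levels,
            class = c("gene_term_table", class(evidence)))
}

resolve_gate <- function(study_id, p_cutoff) {
  if (is.null(names(p_cutoff))) {
    if (length(p_cutoff) != 1L) {
      abort("p_cutoff must be scalar or named by study",
            class = "traitlink_param_error")
    }
    return(rep(p_cutoff, length(study_id)))
  }
  default <- if ("" %in% names(p_cutoff)) p_cutoff[[""]] else 1e-5
  out <- unname(p_cutoff[study_id])
  ifelse(is.na(out), default, out)
}

#' Deduplicated gene-to-term relationships
#'
#' Collapses an evidence table to unique (gene, term) pairs per LD level —
#' the "relationship" counting unit used when sizing curated datasets.
#'
#' @param table A `gene_term_table` (or any tibble with `gene_id`,
#'   `term_id`, `ld_level_kb`).
#' @return Tibble with columns `gene_id`, `term_id`, `ld_level_kb`, one
#'   row per unique triple.
#' @export
distinct_gene_terms <- function(table) {
  distinct(as_tibble(table), .data$ld_level_kb, .data$gene_id, .data$term_id)
}

#' Summary counts per LD level
#'
#' Reports, for each LD level, the number of distinct genes and of
#' distinct (gene, term) relationships — the quantities that grow
#' monotonically with the LD window.
#'
#' @inheritParams distinct_gene_terms
#' @return Tibble with columns `ld_level_kb`, `n_genes`, `n_pairs`.
#' @export
tas_counts <- function(table) {
  distinct_gene_terms(table) %>%
    group_by(.data$ld_level_kb) %>%
    summarise(n_genes = dplyr::n_distinct(.data$gene_id),
              n_pairs = n(), .groups = "drop") %>%
    arrange(.data$ld_level_kb)
}

#' Extract candidate genes for a trait term
#'
#' @param table A `gene_term_table`.
#' @param term_id A single ontology accession.
#' @param ontology `trait_ontology` (needed to resolve descendants and to
#'   validate the accession).
#' @param descendants Also include genes annotated to any descendant term.
#' @param ld_level Restrict to one LD level (default: all).
#' @return Sorted character vector of gene ids (each once).
#' @export
query_genes_by_trait <- function(table, term_id, ontology,
                                 descendants = FALSE, ld_level = NULL) {
  check_terms_exist(ontology, term_id)
  terms <- term_id
  if (descendants) terms <- c(terms, term_descendants(ontology, term_id))
  tab <- as_tibble(table)
  if (!is.null(ld_level)) tab <- tab[tab$ld_level_kb %in% ld_level, ]
  sort(unique(tab$gene_id[tab$term_id %in% terms]))
}

#' Read/write gene-to-term tables
#'
#' TSV layout mirroring deposited gene-to-trait-term datasets: columns
#' `gene_id`, `term_id`, `ld_level_kb`, `study_id`, `marker_name`,
#' `p_value` (plus `trait_name`, `provenance` when present).
#'
#' @param table A `gene_term_table` tibble.
#' @param path TSV path.
#' @return `write_gene_term_table()`: `path`, invisibly;
#'   `read_gene_term_table()`: the tibble.
#' @export
write_gene_term_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_gene_term_table
#' @export
read_gene_term_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", term_id = "c", ld_level_kb = "d", study_id = "c",
    marker_name = "c", p_value = "d", .default = "c"), progress = FALSE)
  structure(out, class = c("gene_term_table", class(out)))
}
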