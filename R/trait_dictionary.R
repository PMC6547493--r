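#' Trait dictionary: normalized trait labels to ontology terms
#'
#' Curated mapping from free-text trait labels (as printed in association
#' studies) to trait-ontology accessions.  Labels are normalized (lower
#' case, collapsed whitespace) so lookups tolerate case and spacing
#' variation.  Every target accession must exist in the ontology when one
#' is supplied.
#'
#' @param entries Tibble with columns `trait_label`, `term_id` and
#'   optionally `provenance` (defaults to `"curated"`).
#' @param ontology Optional `trait_ontology` used to validate accessions.
#' @return A `trait_dictionary` tibble with normalized labels.
#' @export
trait_dictionary <- function(entries, ontology = NULL) {
  entries <- as_tibble(entries)
  if (!all(c("trait_label", "term_id") %in% names(entries))) {
    abort("dictionary needs columns trait_label, term_id",
          class = "traitlink_param_error")
  }
  if (!"provenance" %in% names(entries)) entries$provenance <- "curated"
  entries$trait_label <- normalize_label(entries$trait_label)
  if (!is.null(ontology)) check_terms_exist(ontology, unique(entries$term_id))
  entries <- distinct(entries, .data$trait_label, .data$term_id,
                      .keep_all = TRUE)
  structure(entries, class = c("trait_dictionary", class(entries)))
}

normalize_label <- function(x) stringr::str_squish(tolower(x))

#' Resolve a trait label to ontology terms
#'
#' An exact hit on the normalized label returns the curated term set.  For
#' unseen labels, when an ontology and frequency table are supplied, the
#' label is matched by name-token overlap: the query profile is the set of
#' ontology terms whose names share a token with the label, each candidate
#' term's profile is itself plus its ancestors, and the candidate
#' maximizing [semantic_similarity()] is suggested if its score reaches
#' `threshold` (flagged `"similarity-suggested"`).  Otherwise the result is
#' empty — a valid outcome, not an error.
#'
#' Profiles are restricted to terms with a defined (count > 0) frequency
#' entry, since IC is undefined elsewhere.
#'
#' @param trait_name Free-text trait label.
#' @param dict A [trait_dictionary()].
#' @param ontology,freq Optional `trait_ontology` and [term_frequency()]
#'   enabling similarity suggestions.
#' @param threshold Minimum similarity for a suggestion (default 0.4).
#' @return Tibble with columns `term_id`, `provenance` (zero rows when the
#'   label resolves to nothing).
#' @export
map_trait_to_terms <- function(trait_name, dict, ontology = NULL,
                               freq = NULL, threshold = 0.4) {
  if (!nzchar(trimws(trait_name))) {
    abort("trait_name must be non-empty", class = "traitlink_param_error")
  }
  key <- normalize_label(trait_name)
  hit <- dict[dict$trait_label == key, ]
  if (nrow(hit) > 0L) {
    return(tibble(term_id = hit$term_id, provenance = hit$provenance))
  }
  empty <- tibble(term_id = character(), provenance = character())
  if (is.null(ontology) || is.null(freq)) return(empty)

  known <- freq$term_id[freq$count > 0]
  pool <- ontology$terms[ontology$terms$term_id %in% known, ]
  if (nrow(pool) == 0L) return(empty)
  q_tokens <- unlist(strsplit(key, " ", fixed = TRUE))
  name_tokens <- strsplit(normalize_label(pool$name), " ", fixed = TRUE)
  in_query <- vapply(name_tokens, function(tk) any(tk %in% q_tokens),
                     logical(1))
  cl_p <- pool$term_id[in_query]
  if (length(cl_p) == 0L) return(empty)

  score <- vapply(pool$term_id, function(t) {
    cl_r <- intersect(c(t, term_ancestors(ontology, t)), known)
    if (length(cl_r) == 0L) return(0)
    semantic_similarity(cl_p, cl_r, freq)
  }, numeric(1))
  best <- pool$term_id[order(-score, pool$term_id)][[1]]
  if (score[[which(pool$term_id == best)]] >= threshold) {
    tibble(term_id = best, provenance = "similarity-suggested")
  } else {
    empty
  }
}
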