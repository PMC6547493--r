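#' Term frequency table
#'
#' Counts how often each ontology term annotates an entity (a phenotype
#' description or a gene — the counting basis is the caller's choice) and
#' stores the total used to form the annotation probability
#' P(X = t) = count(t) / total.
#'
#' @param counts Either a tibble with columns `term_id`, `count`, or a
#'   named numeric vector of per-term counts.
#' @param total Denominator for P(X = t); defaults to the sum of counts.
#' @return A `term_frequency` tibble with columns `term_id`, `count` and
#'   attribute `total`.
#' @examples
#' freq <- term_frequency(c(a = 1, b = 2, c = 1), total = 10)
#' information_content(freq, "b")
#' @export
term_frequency <- function(counts, total = NULL) {
  if (is.numeric(counts) && !is.null(names(counts))) {
    counts <- tibble(term_id = names(counts), count = as.numeric(counts))
  }
  counts <- as_tibble(counts)[, c("term_id", "count")]
  if (any(counts$count < 0)) {
    abort("term counts must be non-negative", class = "traitlink_param_error")
  }
  if (anyDuplicated(counts$term_id)) {
    abort("duplicate term ids in frequency table",
          class = "traitlink_param_error")
  }
  total <- total %||% sum(counts$count)
  if (total < max(counts$count)) {
    abort("total must be at least the largest per-term count",
          class = "traitlink_param_error")
  }
  structure(counts, total = total, class = c("term_frequency", class(counts)))
}

#' Count term frequencies from an annotation table
#'
#' @param annotations Tibble with columns `term_id`, `gene_id` (or any
#'   entity column); each row is one annotation.
#' @return A [term_frequency()] table with total = number of annotation
#'   rows.
#' @export
term_frequency_from_annotations <- function(annotations) {
  counts <- dplyr::count(as_tibble(annotations), .data$term_id, name = "count")
  term_frequency(counts)
}

#' Information content of ontology terms
#'
#' IC(t) = -ln P(X = t), in nats: the rarer a term, the more informative an
#' annotation with it.  IC is 0 exactly when every entity carries the term
#' (P = 1), and undefined for a term never observed.
#'
#' @param freq A [term_frequency()] table.
#' @param term_id Term accession(s).
#' @return Numeric vector of IC values (nats).
#' @export
information_content <- function(freq, term_id) {
  stopifnot(inherits(freq, "term_frequency"))
  cnt <- setNames(freq$count, freq$term_id)[term_id]
  if (anyNA(cnt) || any(cnt == 0)) {
    offender <- term_id[is.na(cnt) | cnt == 0][[1]]
    abort(paste0("information content undefined for unobserved term: ",
                 offender, " (smooth or exclude it first)"),
          class = "traitlink_ic_error")
  }
  unname(-log(cnt / attr(freq, "total")))
}

#' Phenotype profile under the entity-quality model
#'
#' A phenotype is described as an entity (organism, species, trait term
#' set) plus quality tags (how the trait varies).  Only the trait term set
#' enters similarity computations; the rest is carried as metadata.
#'
#' @param terms Non-empty character vector of term accessions, the class
#'   set Cl(.) of the phenotype.
#' @param organism,species,quality Optional free-text descriptors.
#' @return A `phenotype_profile` object.
#' @export
phenotype_profile <- function(terms, organism = NA_character_,
                              species = NA_character_,
                              quality = character()) {
  terms <- unique(as.character(terms))
  if (length(terms) == 0L) {
    abort("a phenotype profile needs a non-empty term set",
          class = "traitlink_param_error")
  }
  structure(list(terms = terms, organism = organism, species = species,
                 quality = quality),
            class = "phenotype_profile")
}

#' Information-content semantic similarity of two phenotype profiles
#'
#' sim(P, R) = sum of IC over the shared terms Cl(P) n Cl(R) divided by the
#' sum of IC over all terms Cl(P) u Cl(R).  Ranges over \[0, 1\]: identical
#' class sets score 1, disjoint sets score 0, and shared rare (high-IC)
#' terms pull the score up more than shared common ones.  Symmetric in its
#' arguments.
#'
#' @param p,r [phenotype_profile()] objects, or plain character vectors of
#'   term accessions.
#' @param freq A [term_frequency()] table defining IC; every term of both
#'   profiles must have a defined (count > 0) entry.
#' @return A single number in \[0, 1\].
#' @examples
#' freq <- term_frequency(c(a = 1, b = 2, c = 1), total = exp(1)^0 + 10)
#' semantic_similarity(c("a", "b"), c("b", "c"), freq)
#' @export
semantic_similarity <- function(p, r, freq) {
  cl_p <- if (inherits(p, "phenotype_profile")) p$terms else unique(as.character(p))
  cl_r <- if (inherits(r, "phenotype_profile")) r$terms else unique(as.character(r))
  if (length(cl_p) == 0L || length(cl_r) == 0L) {
    abort("both class sets must be non-empty", class = "traitlink_param_error")
  }
  uni <- union(cl_p, cl_r)
  ic <- setNames(information_content(freq, uni), uni)
  denom <- sum(ic)
  if (denom == 0) {
    abort("similarity undefined: every term in the union has IC 0 (P = 1)",
          class = "traitlink_ic_error")
  }
  inter <- intersect(cl_p, cl_r)
  if (length(inter) == 0L) return(0)
  sum(ic[inter]) / denom
}
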