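#' Hypergeometric probability mass
#'
#' Probability of drawing exactly `k` annotated genes when `n` background
#' genes carry the term, `M` query genes are drawn from a background of
#' `N`:
#' `C(M, k) * C(N - M, n - k) / C(N, n)`, evaluated through log-binomials
#' so genome-scale backgrounds (N in the tens of thousands) do not
#' overflow.  Configurations outside the support return 0, not an error.
#'
#' @param N Background size.
#' @param n Background genes annotated to the term.
#' @param M Query genes present in the background.
#' @param k Query genes annotated to the term (vectorized).
#' @return Probability vector, same length as `k`.
#' @examples
#' hypergeom_pmf(10, 3, 4, 2)  # 0.3
#' @export
hypergeom_pmf <- function(N, n, M, k) {
  stopifnot(N >= 0, n >= 0, n <= N, M >= 0, M <= N)
  out <- numeric(length(k))
  ok <- k >= max(0, n + M - N) & k <= min(M, n) & k == floor(k)
  kk <- k[ok]
  out[ok] <- exp(lchoose(M, kk) + lchoose(N - M, n - kk) - lchoose(N, n))
  out
}

#' Upper-tail enrichment p-value
#'
#' P(X >= k) for the hypergeometric draw above, computed as the complement
#' of the lower sum: `p = 1 - sum_{i=0}^{k-1} pmf(i)`.  `k = 0` gives
#' exactly 1.  For numerical robustness deep in the tail the sum is taken
#' over the smaller side of the support.
#'
#' @inheritParams hypergeom_pmf
#' @param k Observed overlap (vectorized).
#' @return p-value vector in (0, 1].
#' @examples
#' enrichment_pvalue(10, 3, 4, 2)  # 1/3
#' @export
enrichment_pvalue <- function(N, n, M, k) {
  vapply(k, function(k1) {
    if (k1 <= max(0, n + M - N)) return(1)
    hi <- min(M, n)
    if (k1 > hi) return(0)
    upper <- sum(hypergeom_pmf(N, n, M, k1:hi))
    lower <- 1 - sum(hypergeom_pmf(N, n, M, 0:(k1 - 1)))
    # the two routes agree to ~1e-15; prefer the direct upper sum, which
    # cannot go negative by cancellation
    min(max(upper, 0), 1, na.rm = TRUE) -> p
    if (p == 0) p <- max(lower, 0)
    p
  }, numeric(1))
}

#' Bundle an annotation source for enrichment
#'
#' An annotation source is a term -> gene-set mapping over a stated
#' background universe of N genes.  By default the background is the full
#' set of genes the source annotates (the convention of agriGO-style
#' tools); a narrower user background (e.g. expressed genes) may be
#' supplied and the mapping is intersected with it.  Terms left with no
#' genes are dropped.
#'
#' @param annotations Tibble with columns `term_id`, `gene_id` (e.g. a
#'   [distinct_gene_terms()] view, or a parsed GO/pathway export).
#' @param background Optional character vector of background gene ids.
#' @param source Label for the source (`"TO"`, `"GO"`, `"PC"`,
#'   `"module"`, ...).
#' @return An `annotation_set` object with elements `map` (named list of
#'   gene-id vectors), `background`, `source`.
#' @export
annotation_set <- function(annotations, background = NULL, source = "TO") {
  ann <- distinct(as_tibble(annotations), .data$term_id, .data$gene_id)
  if (is.null(background)) {
    background <- sort(unique(ann$gene_id))
  } else {
    background <- sort(unique(as.character(background)))
    ann <- ann[ann$gene_id %in% background, ]
  }
  map <- split(ann$gene_id, ann$term_id)
  map <- map[lengths(map) > 0L]
  structure(list(map = map, background = background, source = source),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> source %s: %d terms over %d background genes\n",
              x$source, length(x$map), length(x$background)))
  invisible(x)
}

#' Hypergeometric enrichment of a gene list
#'
#' Tests every term of the annotation source for over-representation in
#' the query list.  Duplicate query genes are collapsed; `M` counts only
#' query genes present in the source's background.  One result row is
#' produced per term with at least one background gene; rows are ordered
#' by ascending p-value, ties broken by accession.  Benjamini-Hochberg
#' q-values are reported alongside but the `enriched` flag follows the raw
#' p-value against `alpha` unless `flag_on = "q"`.
#'
#' @param genes Character vector of query gene ids.
#' @param ann An [annotation_set()].
#' @param alpha Significance level for the `enriched` flag (default 0.05).
#' @param flag_on Flag on raw `"p"` (default) or BH-adjusted `"q"` values.
#' @return An `enrichment_result` tibble with columns `term_id`, `k`, `M`,
#'   `n`, `N`, `p_value`, `q_value`, `enriched`.
#' @export
enrich <- function(genes, ann, alpha = 0.05, flag_on = c("p", "q")) {
  flag_on <- match.arg(flag_on)
  stopifnot(inherits(ann, "annotation_set"))
  if (length(genes) == 0L) {
    abort("query gene list is empty", class = "traitlink_param_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "traitlink_param_error")
  }
  query <- unique(as.character(genes))
  inside <- query[query %in% ann$background]
  if (length(inside) == 0L) {
    abort(paste0("no query gene found in the annotation background; first ",
                 "offenders: ", paste(head(query, 10), collapse = ", ")),
          class = "traitlink_background_error")
  }
  N <- length(ann$background)
  M <- length(inside)
  res <- tibble(
    term_id = names(ann$map),
    k = unname(vapply(ann$map, function(g) sum(inside %in% g), integer(1))),
    M = M,
    n = unname(lengths(ann$map)),
    N = N)
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    enrichment_pvalue(N, res$n[[i]], M, res$k[[i]])
  }, numeric(1))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- if (flag_on == "p") res$p_value < alpha else res$q_value < alpha
  res <- arrange(res, .data$p_value, .data$term_id)
  structure(res,
            source = ann$source, alpha = alpha, flag_on = flag_on,
            query_size = length(query),
            class = c("enrichment_result", class(res)))
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(source = attr(x, "source"),
         n_terms = nrow(x),
         n_enriched = sum(x$enriched),
         query_size = attr(x, "query_size"),
         background = if (nrow(x) > 0) x$N[[1]] else NA_integer_,
         alpha = attr(x, "alpha"))
}

#' Align enrichment results from several annotation sources
#'
#' Stacks per-source results into one table keyed by (source, term) so TO,
#' GO, pathway and co-expression-module views of the same query can be
#' read side by side.  P-values are never combined across sources.
#'
#' @param ... Named `enrichment_result` objects, or a single named list of
#'   them.  Names override each result's own source label.
#' @return Tibble with a `source` column followed by the result columns;
#'   attribute `per_source` holds [glance()] rows per source, and
#'   attribute `empty_sources` names any source contributing zero rows.
#' @export
cross_compare <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) &&
      !inherits(dots[[1]], "enrichment_result")) {
    dots <- dots[[1]]
  }
  if (length(dots) < 2L) {
    abort("cross_compare needs at least two result sets",
          class = "traitlink_param_error")
  }
  nms <- names(dots) %||% rep("", length(dots))
  nms <- ifelse(nzchar(nms), nms,
                vapply(dots, function(r) attr(r, "source") %||% "?",
                       character(1)))
  stacked <- purrr::map2_dfr(dots, nms, function(r, nm) {
    mutate(as_tibble(r), source = nm, .before = 1)
  })
  if (anyDuplicated(stacked[, c("source", "term_id")])) {
    abort("duplicated (source, term) pair in cross comparison",
          class = "traitlink_integrity_error")
  }
  empty <- nms[vapply(dots, nrow, integer(1)) == 0L]
  if (length(empty) > 0L) {
    warn(paste0("source(s) with no tested terms: ",
                paste(empty, collapse = ", ")))
  }
  per_source <- purrr::map2_dfr(dots, nms, function(r, nm) {
    mutate(glance(r), source = nm)
  })
  structure(stacked, per_source = per_source, empty_sources = empty)
}

#' Plot an enrichment result
#'
#' Bar chart of -log10 p-values for the top terms, coloured by the
#' enriched flag.
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_value),
    y = stats::reorder(.data$term_id, -.data$p_value),
    fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL,
                  title = paste0(attr(object, "source"), " enrichment")) +
    ggplot2::theme_minimal()
}
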