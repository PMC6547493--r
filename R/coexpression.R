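#' Pearson product-moment correlation of two expression profiles
#'
#' Thin, validating wrapper around [stats::cor()]: requires equal-length
#' vectors of at least 3 samples and refuses constant vectors, for which
#' the correlation is undefined.
#'
#' @param x,y Numeric vectors of per-sample expression values.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3",
          class = "traitlink_param_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "traitlink_constant_error")
  }
  stats::cor(x, y)
}

#' Fisher z-transform of a correlation
#'
#' Z = arctanh(r) = 1/2 ln((1 + r) / (1 - r)).  Variance-stabilizes
#' Pearson correlations before thresholding.  Values with |r| >= 1 are
#' clipped to 1 - 1e-12 in magnitude (with a warning) so perfectly
#' correlated pairs stay finite.
#'
#' @param r Correlation(s) in \[-1, 1\].
#' @return Numeric vector of z-scores; an odd function of `r`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    warn("clipping |r| >= 1 to 1 - 1e-12 before Fisher transform")
    r <- sign(r) * pmin(abs(r), 1 - 1e-12)
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows and samples in columns, with a header row of
#' sample ids and the first column holding gene ids.
#'
#' @param path TSV path.
#' @return Numeric matrix, rownames = gene ids.
#' @export
read_expression_matrix <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  ct <- do.call(readr::cols,
                c(setNames(list("c"), hdr[[1]]), list(.default = "d")))
  df <- readr::read_tsv(path, col_types = ct, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("duplicate gene or sample ids in expression matrix",
          class = "traitlink_structure_error")
  }
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric matrix (genes x samples).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- dplyr::bind_cols(tibble(gene_id = rownames(expr)),
                         as_tibble(expr))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Build a co-expression network from an expression matrix
#'
#' Computes all pairwise Pearson correlations across samples, attaches
#' their Fisher z-scores, keeps edges passing the edge rule, and forms the
#' column-stochastic transition matrix used by Markov clustering
#' (absolute-correlation edge weights, self-loops of weight 1 added before
#' column normalization).
#'
#' Two edge rules are available: a minimum absolute correlation
#' (`min_abs_r`, default 0.7) or each gene's `top_k` strongest partners
#' (union over genes).  Genes with missing values or constant expression
#' cannot enter the correlation and are dropped with a report.
#'
#' @param expr Numeric matrix, genes x samples (>= 3 samples).
#' @param min_abs_r Minimum |r| for an edge (ignored when `top_k` given).
#' @param top_k Alternative rule: keep each gene's k strongest partners.
#' @return A `coexpression_network`: list with `genes`, `edges` (tibble
#'   `gene_a`, `gene_b`, `r`, `z`), `transition` (column-stochastic
#'   matrix), `modules` (`NULL` until [mcl_cluster()]), `dropped`
#'   (report tibble), `params`.
#' @export
build_coexpression_network <- function(expr, min_abs_r = 0.7, top_k = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 3L) {
    abort("at least 3 samples are required for correlations",
          class = "traitlink_param_error")
  }
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))

  has_na <- apply(expr, 1, anyNA)
  constant <- !has_na & apply(expr, 1, function(x) sd(x) == 0)
  dropped <- tibble(
    gene_id = rownames(expr)[has_na | constant],
    reason = c(rep("missing values", sum(has_na)),
               rep("constant expression", sum(constant))))
  if (nrow(dropped) > 0L) {
    inform(sprintf("build_coexpression_network: dropped %d gene(s) (missing or constant)",
                   nrow(dropped)))
  }
  expr <- expr[!(has_na | constant), , drop = FALSE]
  genes <- rownames(expr)

  C <- stats::cor(t(expr))
  diag(C) <- 0
  if (!is.null(top_k)) {
    keep <- matrix(FALSE, nrow(C), ncol(C))
    for (i in seq_len(nrow(C))) {
      ord <- order(abs(C[i, ]), decreasing = TRUE)[seq_len(min(top_k, ncol(C) - 1))]
      keep[i, ord] <- TRUE
    }
    keep <- keep | t(keep)
  } else {
    keep <- abs(C) >= min_abs_r
  }
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    abort("edge rule leaves an empty network",
          class = "traitlink_empty_network_error")
  }
  r <- C[idx]
  edges <- tibble(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                  r = r, z = fisher_z(r))

  A <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  A[idx] <- abs(r)
  A <- A + t(A)
  diag(A) <- 1                                  # self-loops before normalizing
  M <- sweep(A, 2, colSums(A), "/")

  structure(list(genes = genes, edges = edges, transition = M,
                 modules = NULL, dropped = dropped,
                 params = list(min_abs_r = if (is.null(top_k)) min_abs_r else NA,
                               top_k = top_k)),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d genes, %d edges%s\n",
              length(x$genes), nrow(x$edges),
              if (is.null(x$modules)) "" else
                sprintf(", %d modules", dplyr::n_distinct(x$modules$module_id))))
  invisible(x)
}

#' @export
tidy.coexpression_network <- function(x, ...) {
  if (is.null(x$modules)) x$edges else x$modules
}

#' Map a gene set onto co-expression modules
#'
#' Counts how many query genes fall in each module and tests each module
#' for over-representation with the hypergeometric engine (modules acting
#' as annotation terms over the network's gene universe).  Query genes
#' absent from the network are reported in an `unassigned` attribute, not
#' silently lost.
#'
#' @param genes Character vector of query gene ids.
#' @param net A clustered `coexpression_network` (run [mcl_cluster()]
#'   first).
#' @return Tibble `module_id`, `module_size`, `k`, `p_value` sorted by p;
#'   attribute `unassigned` holds query genes outside the network.
#' @export
module_overlap <- function(genes, net) {
  if (is.null(net$modules)) {
    abort("network has no module assignment; run mcl_cluster() first",
          class = "traitlink_param_error")
  }
  genes <- unique(as.character(genes))
  unassigned <- setdiff(genes, net$genes)
  inside <- intersect(genes, net$genes)
  ann <- annotation_set(
    tibble(term_id = net$modules$module_id, gene_id = net$modules$gene_id),
    background = net$genes, source = "module")
  if (length(inside) == 0L) {
    out <- tibble(module_id = names(ann$map),
                  module_size = lengths(ann$map),
                  k = 0L, p_value = 1)
  } else {
    res <- enrich(inside, ann)
    out <- tibble(module_id = res$term_id, module_size = res$n,
                  k = res$k, p_value = res$p_value)
  }
  structure(arrange(out, .data$p_value, .data$module_id),
            unassigned = unassigned)
}
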