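#' Estimate enrichment false-positive rates by random gene sets
#'
#' Repeatedly draws gene sets uniformly without replacement from the
#' annotation background, runs the hypergeometric enrichment on each draw
#' and records how often terms come out significant at `alpha`.  Since the
#' draws carry no signal, any significant term is a false positive; the
#' per-size mean is the empirical false-positive rate.
#'
#' Two estimators are available, because "rate of significant terms" can
#' be read per term or per draw:
#' * `"per_term"` (default): per replicate, the fraction of tested terms
#'   with p < alpha; the summary is its mean over replicates.
#' * `"any_hit"`: the share of replicates with at least one significant
#'   term.
#'
#' The run is bit-reproducible: one master seed drives the whole size
#' grid, with per-size substreams derived deterministically from it.
#'
#' @param ann An [annotation_set()].
#' @param sizes Gene-set sizes to draw (default the classic grid 20, 40,
#'   60, 80, 100, 200, 500, 1000, truncated to the background size).
#' @param replicates Draws per size (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Master RNG seed (mandatory).
#' @param estimator `"per_term"` or `"any_hit"`.
#' @return An `fpr_summary` tibble: `size`, `mean_fpr`, `se`,
#'   `replicates`, `estimator`, `source`.
#' @export
simulate_fpr <- function(ann, sizes = c(20, 40, 60, 80, 100, 200, 500, 1000),
                         replicates = 1000, alpha = 0.05, seed,
                         estimator = c("per_term", "any_hit")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(ann, "annotation_set"))
  if (missing(seed)) {
    abort("a seed is mandatory for FPR simulation",
          class = "traitlink_param_error")
  }
  if (any(sizes < 1) || any(sizes != floor(sizes))) {
    abort("sizes must be positive integers", class = "traitlink_param_error")
  }
  if (any(sizes > length(ann$background))) {
    abort(sprintf("requested set size exceeds the background (%d genes)",
                  length(ann$background)),
          class = "traitlink_param_error")
  }
  if (replicates < 1) {
    abort("replicates must be >= 1", class = "traitlink_param_error")
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, length(sizes))

  res <- purrr::map2_dfr(sizes, substreams, function(sz, ss) {
    set.seed(ss)
    stat <- vapply(seq_len(replicates), function(rep) {
      draw <- sample(ann$background, sz)
      r <- enrich(draw, ann, alpha = max(alpha, .Machine$double.eps))
      if (estimator == "per_term") {
        mean(r$p_value < alpha)
      } else {
        as.numeric(any(r$p_value < alpha))
      }
    }, numeric(1))
    tibble(size = sz, mean_fpr = mean(stat),
           se = stats::sd(stat) / sqrt(replicates),
           replicates = replicates)
  })
  res$estimator <- estimator
  res$source <- ann$source
  structure(res, alpha = alpha, seed = seed,
            class = c("fpr_summary", class(res)))
}

#' Pair false-positive-rate summaries from two or more sources
#'
#' Aligns `fpr_summary` tables on their common size grid and reports the
#' difference in mean FPR per size together with a descriptive
#' two-proportion z statistic `(m1 - m2) / sqrt(se1^2 + se2^2)`.
#'
#' @param ... Two or more [simulate_fpr()] summaries (optionally named),
#'   or one named list of them.
#' @return Tibble with one row per (size, source pair): means, standard
#'   errors, `diff` and `z`.
#' @export
compare_fpr <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) &&
      !inherits(dots[[1]], "fpr_summary")) {
    dots <- dots[[1]]
  }
  if (length(dots) < 2L) {
    abort("compare_fpr needs at least two summaries",
          class = "traitlink_param_error")
  }
  nms <- names(dots) %||% rep("", length(dots))
  nms <- ifelse(nzchar(nms),
                nms, vapply(dots, function(s) s$source[[1]], character(1)))
  grids <- purrr::map(dots, "size")
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    abort("FPR summaries must share the same size grid",
          class = "traitlink_param_error")
  }
  pairs <- utils::combn(length(dots), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(ij) {
    a <- dots[[ij[1]]]; b <- dots[[ij[2]]]
    tibble(size = a$size,
           source_a = nms[[ij[1]]], source_b = nms[[ij[2]]],
           fpr_a = a$mean_fpr, se_a = a$se,
           fpr_b = b$mean_fpr, se_b = b$se,
           diff = a$mean_fpr - b$mean_fpr,
           z = ifelse(a$se^2 + b$se^2 > 0,
                      (a$mean_fpr - b$mean_fpr) / sqrt(a$se^2 + b$se^2), 0))
  })
}

#' Plot false-positive-rate curves
#'
#' @param object One `fpr_summary` (or bind several with
#'   `dplyr::bind_rows()` first; curves are coloured by `source`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fpr_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$size, .data$mean_fpr,
                                       colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_fpr - .data$se, ymax = .data$mean_fpr + .data$se)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genes drawn", y = "false-positive rate") +
    ggplot2::theme_minimal()
}
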