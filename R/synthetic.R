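#' Specification of a synthetic fixture set
#'
#' One object collecting every knob of the synthetic generators: ontology
#' shape, toy genome shape, association-study design and expression-matrix
#' design.  Every generator is a pure function of (spec, seed): the same
#' spec yields byte-identical fixtures.
#'
#' Defaults emulate the curated-corpus setting at desk scale: an ontology
#' with 9 root trait groups and 6 levels; a 3-chromosome toy genome; 3
#' traits studied by 2 association studies each, with 5 planted causal
#' genes in total (2 + 2 + 1); causal markers at a point-mass p of 1e-8
#' against uniform(0, 1) null markers, gated at 1e-5; LD window levels 10
#' and 25 kb; and an expression matrix of 4 modules x 25 genes over 40
#' samples with within-module correlation 0.8.
#'
#' @param seed Integer seed (mandatory).
#' @param roots,depth,branching,extra_parent_prob Ontology shape: number
#'   of root trait groups, number of levels, children per term, and the
#'   probability that a non-root term receives a second parent (drawn from
#'   the same upper level, so term levels are unambiguous).
#' @param chromosomes,chrom_length,n_genes,gene_length Toy genome shape
#'   (bp).
#' @param traits,studies_per_trait,markers_per_study,causal_genes_per_trait
#'   Study design; `causal_genes_per_trait` may be a vector of length
#'   `traits`.
#' @param causal_p,null_p Effect-marker p-value distribution: a point mass
#'   (`causal_p`) by default, or Beta(a, 1) draws when
#'   `null_p = "uniform"` is kept and `causal_beta_a` is set; null markers
#'   are uniform(0, 1).
#' @param causal_beta_a If non-`NULL`, causal p-values are drawn from
#'   Beta(`causal_beta_a`, 1) instead of the point mass (power-style
#'   experiments).
#' @param p_cutoff Significance gate used when tabulating ground truth.
#' @param ld_levels LD window sizes (kb) the truth table is computed for.
#' @param modules,genes_per_module,samples,within_cor Expression design;
#'   `within_cor` is the expected pairwise correlation inside a module.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed,
                         roots = 9, depth = 6, branching = 2,
                         extra_parent_prob = 0.1,
                         chromosomes = 3, chrom_length = 1e6,
                         n_genes = 60, gene_length = c(2000, 5000),
                         traits = 3, studies_per_trait = 2,
                         markers_per_study = 40,
                         causal_genes_per_trait = c(2, 2, 1),
                         causal_p = 1e-8, causal_beta_a = NULL,
                         p_cutoff = 1e-5, ld_levels = c(10, 25),
                         modules = 4, genes_per_module = 25,
                         samples = 40, within_cor = 0.8) {
  if (missing(seed)) {
    abort("fixture_spec requires a seed", class = "traitlink_param_error")
  }
  if (within_cor <= 0 || within_cor >= 1) {
    abort("within_cor must lie in (0, 1)", class = "traitlink_param_error")
  }
  if (depth > 7) {
    abort("ontology depth above 7 is not part of the emulated layout",
          class = "traitlink_param_error")
  }
  causal_genes_per_trait <- rep_len(causal_genes_per_trait, traits)
  spec <- as.list(environment())
  structure(spec, class = "fixture_spec")
}

trait_group_names <- c(
  "plant height", "yield", "grain morphology", "flowering time",
  "stress response", "root architecture", "leaf morphology",
  "biochemical content", "disease resistance")

with_seed_offset <- function(spec, offset, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((spec$seed + offset) %% (.Machine$integer.max - 1L))
  force(code)
}

#' Generate a synthetic trait ontology
#'
#' Builds a rooted DAG with the requested number of root trait groups,
#' depth and branching factor; a fraction of non-root terms receives a
#' second parent from the same upper level, so the structure is a genuine
#' DAG (not a tree) while every term keeps an unambiguous level.
#'
#' @param spec A [fixture_spec()].
#' @return A `trait_ontology` (pass to [write_obo()] for the file form).
#' @export
generate_ontology <- function(spec) {
  with_seed_offset(spec, 11L, {
    ids <- character()
    names_ <- character()
    level <- integer()
    edges_from <- character()
    edges_to <- character()
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("SYN:%07d", counter)
    }
    roots <- replicate(spec$roots, new_id())
    ids <- roots
    names_ <- paste0(rep_len(trait_group_names, spec$roots),
                     ifelse(seq_len(spec$roots) > length(trait_group_names),
                            paste0(" ", seq_len(spec$roots)), ""))
    level <- rep(1L, spec$roots)
    group_of <- setNames(names_, roots)         # root trait group per term
    prev <- roots
    if (spec$depth > 1) for (lv in 2:spec$depth) {
      cur <- character()
      for (p in prev) {
        for (b in seq_len(spec$branching)) {
          id <- new_id()
          cur <- c(cur, id)
          ids <- c(ids, id)
          group_of[[id]] <- group_of[[p]]
          names_ <- c(names_,
                      sprintf("%s trait %s", group_of[[id]],
                              substr(id, 5, 11)))
          level <- c(level, lv)
          edges_from <- c(edges_from, id)
          edges_to <- c(edges_to, p)
        }
      }
      # second parents: same upper level, different from the first parent
      if (length(prev) > 1) for (id in cur) {
        if (stats::runif(1) < spec$extra_parent_prob) {
          first <- edges_to[edges_from == id][[1]]
          extra <- sample(setdiff(prev, first), 1)
          edges_from <- c(edges_from, id)
          edges_to <- c(edges_to, extra)
        }
      }
      prev <- cur
    }
    new_trait_ontology(
      tibble(term_id = ids, name = names_),
      tibble(term_id = edges_from, parent_id = edges_to))
  })
}

#' Generate toy gene models
#'
#' Places genes uniformly over the configured chromosomes with lengths
#' drawn from the configured range.
#'
#' @param spec A [fixture_spec()].
#' @return Gene-model tibble (`gene_id`, `chromosome`, `start`, `end`,
#'   `strand`).
#' @export
generate_gene_models <- function(spec) {
  with_seed_offset(spec, 23L, {
    chrom <- sample(paste0("chr", seq_len(spec$chromosomes)), spec$n_genes,
                    replace = TRUE)
    len <- sample(spec$gene_length[1]:spec$gene_length[2], spec$n_genes,
                  replace = TRUE)
    start <- vapply(len, function(l) {
      sample.int(spec$chrom_length - l, 1)
    }, integer(1))
    validate_gene_models(tibble(
      gene_id = sprintf("GENE%04d", seq_len(spec$n_genes)),
      chromosome = chrom, start = start, end = start + len - 1L,
      strand = sample(c("+", "-"), spec$n_genes, replace = TRUE)))
  })
}

#' Generate a trait dictionary over a synthetic ontology
#'
#' Picks one deepest-level term per trait and uses its name as the curated
#' trait label.
#'
#' @param spec A [fixture_spec()].
#' @param ontology The matching [generate_ontology()] output.
#' @return A [trait_dictionary()].
#' @export
generate_trait_dictionary <- function(spec, ontology) {
  with_seed_offset(spec, 31L, {
    leaves <- ontology$terms[ontology$terms$level == max(ontology$terms$level), ]
    pick <- leaves[sample.int(nrow(leaves), spec$traits), ]
    trait_dictionary(tibble(trait_label = pick$name, term_id = pick$term_id),
                     ontology)
  })
}

#' Generate association studies with planted causal genes
#'
#' For each trait, `studies_per_trait` studies are simulated.  Each study
#' carries `markers_per_study` null markers placed uniformly over the
#' genome with p-values uniform(0, 1), plus one effect marker inside each
#' of the trait's causal genes whose p-value follows the effect
#' distribution (point mass `causal_p` by default).  The same causal
#' marker positions recur across a trait's studies, exercising
#' evidence-level deduplication downstream.
#'
#' The returned truth table lists every (gene, term) pair recoverable at
#' each LD level, computed by an exhaustive marker x gene window scan over
#' all emitted markers that pass the significance gate — so incidental
#' recoveries (an effect marker inside the window of a neighbouring
#' non-causal gene) are part of the truth, as they are of the pipeline
#' output.
#'
#' @param spec A [fixture_spec()].
#' @param genes Gene models from [generate_gene_models()].
#' @param dict Dictionary from [generate_trait_dictionary()].
#' @return List with `records` (association tibble), `truth` (tibble
#'   `ld_level_kb`, `gene_id`, `term_id`), `causal_genes` (tibble
#'   `trait_label`, `gene_id`, `term_id`).
#' @export
generate_association_study <- function(spec, genes, dict) {
  with_seed_offset(spec, 47L, {
    stopifnot(nrow(dict) >= spec$traits)
    traits <- dict$trait_label[seq_len(spec$traits)]
    term_of <- setNames(dict$term_id, dict$trait_label)

    # causal genes are planted far enough apart (two maximal LD windows)
    # that no gene can fall inside the windows of two different causal
    # markers: each planted signal stays attributable to its own trait
    D <- max(spec$ld_levels) * 1000
    need <- sum(spec$causal_genes_per_trait)
    order_ids <- sample(genes$gene_id)
    causal_ids <- character()
    for (id in order_ids) {
      if (length(causal_ids) == need) break
      g <- genes[genes$gene_id == id, ]
      others <- genes[genes$gene_id %in% causal_ids &
                        genes$chromosome == g$chromosome, ]
      gap_ok <- nrow(others) == 0 ||
        all(pmax(g$start, others$start) - pmin(g$end, others$end) > 2 * D)
      if (gap_ok) causal_ids <- c(causal_ids, id)
    }
    if (length(causal_ids) < need) {
      abort("genome too dense to plant well-separated causal genes",
            class = "traitlink_param_error")
    }
    split_idx <- rep(seq_len(spec$traits), spec$causal_genes_per_trait)
    causal <- tibble(trait_label = traits[split_idx], gene_id = causal_ids,
                     term_id = unname(term_of[traits[split_idx]]))

    draw_causal_p <- function(n) {
      if (is.null(spec$causal_beta_a)) rep(spec$causal_p, n)
      else stats::rbeta(n, spec$causal_beta_a, 1)
    }

    gidx <- setNames(seq_len(nrow(genes)), genes$gene_id)
    records <- purrr::map_dfr(seq_len(spec$traits), function(ti) {
      tr <- traits[[ti]]
      cg <- causal$gene_id[causal$trait_label == tr]
      purrr::map_dfr(seq_len(spec$studies_per_trait), function(si) {
        study <- sprintf("study_%02d_%s", si, gsub("[^a-z0-9]+", "_", tr))
        null_chr <- sample(paste0("chr", seq_len(spec$chromosomes)),
                           spec$markers_per_study, replace = TRUE)
        null_pos <- sample.int(spec$chrom_length, spec$markers_per_study,
                               replace = TRUE)
        nulls <- tibble(
          marker_name = sprintf("%s_m%03d", study, seq_len(spec$markers_per_study)),
          chromosome = null_chr, position = as.numeric(null_pos),
          p_value = stats::runif(spec$markers_per_study))
        g <- genes[gidx[cg], ]
        hits <- tibble(
          marker_name = sprintf("%s_causal_%s", study, cg),
          chromosome = g$chromosome,
          position = as.numeric(floor((g$start + g$end) / 2)),
          p_value = draw_causal_p(length(cg)))
        bind_rows(nulls, hits) %>%
          mutate(variant_class = "snp", maf = round(stats::runif(n(), 0.05, 0.5), 3),
                 trait_name = tr, study_id = study,
                 pop_type = "natural", pop_size = "200",
                 marker_set = as.character(spec$markers_per_study),
                 model = "MLM", genome_version = "SYNv1")
      })
    })

    sig <- records[records$p_value <= spec$p_cutoff, ]
    truth <- purrr::map_dfr(spec$ld_levels, function(d) {
      # independent exhaustive pair scan, kept deliberately naive
      rows <- list()
      for (i in seq_len(nrow(sig))) for (j in seq_len(nrow(genes))) {
        if (sig$chromosome[[i]] == genes$chromosome[[j]] &&
            sig$position[[i]] >= max(genes$start[[j]] - d * 1000, 1) &&
            sig$position[[i]] <= genes$end[[j]] + d * 1000) {
          rows[[length(rows) + 1L]] <-
            tibble(ld_level_kb = d, gene_id = genes$gene_id[[j]],
                   term_id = unname(term_of[sig$trait_name[[i]]]))
        }
      }
      if (length(rows) == 0L) return(NULL)
      distinct(bind_rows(rows))
    })

    list(records = records, truth = truth, causal_genes = causal)
  })
}

#' Generate an expression matrix with planted co-expression modules
#'
#' Each module draws a latent standard-normal sample profile; member genes
#' are `sqrt(w) * latent + sqrt(1 - w) * noise` with unit-variance
#' Gaussian noise, so the expected correlation between two genes of the
#' same module is exactly `w = within_cor` and 0 across modules.
#'
#' @param spec A [fixture_spec()].
#' @return List with `expr` (matrix, genes x samples) and `labels`
#'   (tibble `gene_id`, `module`).
#' @export
generate_expression <- function(spec) {
  with_seed_offset(spec, 61L, {
    n_genes <- spec$modules * spec$genes_per_module
    w <- spec$within_cor
    latent <- matrix(stats::rnorm(spec$modules * spec$samples),
                     spec$modules, spec$samples)
    module <- rep(seq_len(spec$modules), each = spec$genes_per_module)
    noise <- matrix(stats::rnorm(n_genes * spec$samples), n_genes,
                    spec$samples)
    expr <- sqrt(w) * latent[module, , drop = FALSE] + sqrt(1 - w) * noise
    rownames(expr) <- sprintf("XG%04d", seq_len(n_genes))
    colnames(expr) <- sprintf("sample_%02d", seq_len(spec$samples))
    list(expr = expr,
         labels = tibble(gene_id = rownames(expr),
                         module = sprintf("t%02d", module)))
  })
}

#' Write a complete fixture set to a directory
#'
#' Emits every synthetic input in the dialect its reader consumes:
#' `ontology.obo`, `genes.gff3`, `associations.tsv` (curated-summary
#' layout), `trait_dict.tsv`, `expression.tsv`, plus ground truth
#' (`truth.tsv`, `causal_genes.tsv`, `module_labels.tsv`) and a
#' `provenance.json` record.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  onto <- generate_ontology(spec)
  genes <- generate_gene_models(spec)
  dict <- generate_trait_dictionary(spec, onto)
  study <- generate_association_study(spec, genes, dict)
  ex <- generate_expression(spec)

  write_obo(onto, file.path(dir, "ontology.obo"))
  write_gene_models(genes, file.path(dir, "genes.gff3"))
  sch <- default_association_schema()
  rec <- study$records
  out <- rec[, names(sch)[names(sch) %in% names(rec)]]
  names(out) <- unname(sch[names(out)])
  readr::write_tsv(out, file.path(dir, "associations.tsv"))
  readr::write_tsv(as_tibble(dict), file.path(dir, "trait_dict.tsv"))
  write_expression_matrix(ex$expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(study$causal_genes, file.path(dir, "causal_genes.tsv"))
  readr::write_tsv(ex$labels, file.path(dir, "module_labels.tsv"))
  write_provenance(file.path(dir, "provenance.json"),
                   command = "make-fixtures",
                   params = unclass(spec))
  invisible(dir)
}
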