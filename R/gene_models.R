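#' Read gene models from a GFF3 file
#'
#' Extracts gene features (1-based inclusive coordinates, per the GFF3
#' convention) into a tidy table.  Non-gene features are ignored.
#'
#' @param path GFF3 file.
#' @param feature_type Feature type(s) to keep; default `"gene"`.
#' @return Tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Name")))
  gff <- gff[gff$type %in% feature_type, , drop = FALSE]
  if (nrow(gff) == 0L) {
    abort(paste0("no '", paste(feature_type, collapse = "/"),
                 "' features in ", path),
          class = "traitlink_io_error")
  }
  ids <- ifelse(is.na(gff$ID) | !nzchar(gff$ID),
                ifelse(is.na(gff$Name), paste0("feature_", seq_len(nrow(gff))),
                       gff$Name),
                gff$ID)
  out <- tibble(
    gene_id = sub("^gene:", "", ids),
    chromosome = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = ifelse(as.character(gff$strand) %in% c("+", "-"),
                    as.character(gff$strand), "unknown"))
  validate_gene_models(out)
}

validate_gene_models <- function(genes) {
  genes <- as_tibble(genes)
  if (any(genes$start > genes$end)) {
    abort("gene model with start > end", class = "traitlink_structure_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene ids in gene models",
          class = "traitlink_structure_error")
  }
  genes
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (`gene_id`, `chromosome`, `start`, `end`,
#'   `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttraitlink\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chromosome, genes$start, genes$end,
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}
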