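#' Default column schema for association summary tables
#'
#' Maps canonical field names to the column headers used in curated
#' marker-trait summary spreadsheets (`Marker_name`, `chr_ref`,
#' `Marker_location`, `Pvalue`, `indel/snp`, `MAF`, population and
#' reference metadata).  Pass a modified copy to
#' [read_association_table()] to ingest tables with other headers.
#'
#' @return Named character vector: canonical field -> source header.
#' @export
default_association_schema <- function() {
  c(marker_name    = "Marker_name",
    chromosome     = "chr_ref",
    position       = "Marker_location",
    p_value        = "Pvalue",
    variant_class  = "indel/snp",
    maf            = "MAF",
    trait_name     = "Trait_name",
    study_id       = "Ref_name",
    pop_type       = "Pop_type",
    pop_size       = "Pop_size",
    marker_set     = "Marker_set",
    model          = "Model",
    genome_version = "genome_version")
}

assoc_mandatory <- c("marker_name", "chromosome", "position", "p_value",
                     "trait_name", "study_id")

#' Read an association-mapping summary table
#'
#' Ingests one TSV of marker-trait association results (one row per
#' significant marker reported by a study).  Rows whose position, p-value
#' or MAF cannot be parsed or fall outside their valid ranges are rejected
#' with a per-row report, never silently dropped: the returned tibble
#' carries the rejects in its `rejections` attribute (see
#' [rejected_rows()]).
#'
#' @param path TSV file with a header row.
#' @param schema Named character vector mapping canonical fields to source
#'   headers; see [default_association_schema()].  Optional columns absent
#'   from the file are filled with `NA`.
#' @return Tibble of association records with canonical columns
#'   `marker_name`, `chromosome`, `position` (1-based bp), `p_value`,
#'   `variant_class`, `maf`, `trait_name`, `study_id` and metadata columns.
#' @export
read_association_table <- function(path, schema = default_association_schema()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(unname(schema[assoc_mandatory]), names(raw))
  if (length(missing) > 0L) {
    abort(paste0("association table is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")),
          class = "traitlink_schema_error")
  }
  present <- schema[schema %in% names(raw)]
  out <- raw[, unname(present)]
  names(out) <- names(present)
  for (f in setdiff(names(schema), names(out))) out[[f]] <- NA_character_

  out$.row <- seq_len(nrow(out))
  pos <- suppressWarnings(as.numeric(out$position))
  pv <- suppressWarnings(as.numeric(out$p_value))
  maf <- suppressWarnings(as.numeric(out$maf))

  reason <- rep(NA_character_, nrow(out))
  flag <- function(cond, msg) ifelse(is.na(reason) & cond, msg, reason)
  reason <- flag(is.na(pos) | pos < 1 | pos != floor(pos),
                 "unparseable or invalid position")
  reason <- flag(is.na(pv) | pv <= 0 | pv > 1, "unparseable or invalid p-value")
  reason <- flag(!is.na(out$maf) & (is.na(maf) | maf < 0 | maf > 0.5),
                 "MAF outside [0, 0.5]")
  reason <- flag(is.na(out$trait_name) | !nzchar(trimws(out$trait_name)),
                 "empty trait name")
  reason <- flag(is.na(out$study_id) | !nzchar(trimws(out$study_id)),
                 "empty study id")

  rejections <- tibble(row = out$.row[!is.na(reason)],
                       marker_name = out$marker_name[!is.na(reason)],
                       reason = reason[!is.na(reason)])
  keep <- is.na(reason)
  res <- out[keep, ]
  res$position <- pos[keep]
  res$p_value <- pv[keep]
  res$maf <- maf[keep]
  res$.row <- NULL
  if (nrow(rejections) > 0L) {
    inform(sprintf("read_association_table: rejected %d of %d row(s); see rejected_rows()",
                   nrow(rejections), nrow(out)))
  }
  attr(res, "rejections") <- rejections
  res
}

#' Per-row rejection report of the last read
#'
#' @param x A tibble returned by [read_association_table()].
#' @return Tibble with columns `row`, `marker_name`, `reason`.
#' @export
rejected_rows <- function(x) {
  attr(x, "rejections") %||%
    tibble(row = integer(), marker_name = character(), reason = character())
}

#' Keep the most significant fraction of association records
#'
#' Retains the `ceiling(fraction * n)` records with the smallest p-values,
#' within each study (`per_study = TRUE`, the usual reading of "top 10%
#' from each association mapping study") or over the pooled table.  All
#' records tied with the cutoff p-value are retained, so the result may
#' exceed the nominal count — a record is never dropped while an equally
#' significant one is kept.
#'
#' @param records Association record tibble with `p_value` (and `study_id`
#'   when `per_study`).
#' @param fraction Fraction in (0, 1] to keep.
#' @param per_study Apply the cut within each study separately.
#' @return Filtered tibble.
#' @export
top_fraction_filter <- function(records, fraction = 0.1, per_study = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort("fraction must be a single number in (0, 1]",
          class = "traitlink_param_error")
  }
  if (anyNA(records$p_value)) {
    abort("all records must carry a p-value", class = "traitlink_param_error")
  }
  cut_one <- function(df) {
    cutoff <- sort(df$p_value)[ceiling(fraction * nrow(df))]
    df[df$p_value <= cutoff, ]
  }
  if (per_study) {
    records %>%
      group_by(.data$study_id) %>%
      dplyr::group_modify(function(df, key) cut_one(df)) %>%
      ungroup() %>%
      dplyr::relocate(all_of(names(records)))
  } else {
    cut_one(records)
  }
}
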