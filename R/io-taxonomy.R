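#' Read a genome taxonomy table
#'
#' Loads a tab-separated taxonomy file (GTDB-metadata style) mapping genome
#' accessions to phyla. Column names are configurable to accommodate
#' different metadata dialects.
#'
#' @param path TSV file with a header line.
#' @param genome_col name of the genome-id column (default `"genome_id"`).
#' @param phylum_col name of the phylum column (default `"phylum"`).
#' @param lineage_col optional name of a free-text lineage column.
#' @return data.frame with columns `genome_id`, `phylum` and, when present,
#'   `lineage`.
#' @export
read_taxonomy <- function(path, genome_col = "genome_id",
                          phylum_col = "phylum", lineage_col = NULL) {
  if (!file.exists(path)) {
    rqc_abort(sprintf("taxonomy file not found: %s", path), "rqc_io_error")
  }
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  need <- c(genome_col, phylum_col, lineage_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    rqc_abort(sprintf("%s: missing required column(s): %s",
                      path, paste(missing_cols, collapse = ", ")),
              "rqc_schema_error")
  }
  out <- data.frame(genome_id = as.character(tab[[genome_col]]),
                    phylum = as.character(tab[[phylum_col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(lineage_col)) out$lineage <- as.character(tab[[lineage_col]])
  if (anyDuplicated(out$genome_id)) {
    dup <- unique(out$genome_id[duplicated(out$genome_id)])
    rqc_abort(sprintf("%s: duplicate genome id(s): %s",
                      path, paste(dup, collapse = ", ")),
              "rqc_duplicate_error")
  }
  if (any(!nzchar(out$phylum) | is.na(out$phylum))) {
    rqc_abort(sprintf("%s: empty phylum value(s)", path), "rqc_schema_error")
  }
  out
}

#' Write a taxonomy table as TSV
#'
#' @param taxonomy data.frame with `genome_id` and `phylum` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
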