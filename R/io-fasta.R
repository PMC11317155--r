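#' Read an amino-acid FASTA file into protein records
#'
#' Parses a protein FASTA file with strict validation: sequences are
#' uppercased, a single terminal `*` stop character is stripped, and any
#' other character outside the 20 canonical amino acids plus `X` raises a
#' format error naming the offending line. Ambiguity codes such as B, J or Z
#' are rejected rather than coerced because downstream motif rules require
#' exact residue identity.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param genome_id genome identifier attached to every record.
#' @return a `data.frame` with columns `protein_id`, `genome_id`,
#'   `sequence`, `description`, one row per FASTA entry, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, genome_id) {
  if (!file.exists(path)) {
    rqc_abort(sprintf("FASTA file not found: %s", path), "rqc_io_error")
  }
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    rqc_abort(sprintf("%s: no FASTA header found", path), "rqc_format_error")
  }
  if (headers[1] != 1L && any(nzchar(trimws(lines[seq_len(headers[1] - 1L)])))) {
    rqc_abort(sprintf("%s: sequence data before first header (line 1)", path),
              "rqc_format_error")
  }

  ids <- character(length(headers))
  descs <- character(length(headers))
  seqs <- character(length(headers))
  bounds <- c(headers, length(lines) + 1L)
  valid <- paste0("[", paste(AA20, collapse = ""), "X]*")

  for (k in seq_along(headers)) {
    h <- sub("^>", "", lines[headers[k]])
    id <- sub("\\s.*$", "", h)
    if (!nzchar(id)) {
      rqc_abort(sprintf("%s: malformed header at line %d", path, headers[k]),
                "rqc_format_error")
    }
    ids[k] <- id
    descs[k] <- trimws(sub("^\\S+", "", h))

    body_lines <- seq(headers[k] + 1L, bounds[k + 1L] - 1L)
    body_lines <- body_lines[body_lines <= length(lines)]
    if (bounds[k + 1L] - 1L < headers[k] + 1L) body_lines <- integer(0)
    seq_parts <- character(0)
    for (ln in body_lines) {
      piece <- toupper(gsub("\\s", "", lines[ln]))
      if (!nzchar(piece)) next
      # '*' is allowed only as the final character of the final line
      stars <- gregexpr("\\*", piece)[[1]]
      if (stars[1] != -1L) {
        is_last_line <- all(!nzchar(gsub("\\s", "", lines[body_lines[body_lines > ln]])))
        if (length(stars) > 1L || stars != nchar(piece) || !is_last_line) {
          rqc_abort(sprintf("%s: internal stop '*' at line %d", path, ln),
                    "rqc_format_error")
        }
        piece <- sub("\\*$", "", piece)
      }
      if (!grepl(paste0("^", valid, "$"), piece)) {
        bad <- setdiff(unique(strsplit(piece, "")[[1]]), c(AA20, "X"))
        rqc_abort(sprintf("%s: invalid residue character(s) %s at line %d",
                          path, paste(bad, collapse = ","), ln),
                  "rqc_format_error")
      }
      seq_parts <- c(seq_parts, piece)
    }
    seqs[k] <- paste(seq_parts, collapse = "")
    if (!nzchar(seqs[k])) {
      rqc_abort(sprintf("%s: empty sequence for '%s' (header line %d)",
                        path, id, headers[k]),
                "rqc_format_error")
    }
  }

  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rqc_abort(sprintf("%s: duplicate protein id(s): %s",
                      path, paste(dup, collapse = ", ")),
              "rqc_duplicate_error")
  }

  data.frame(protein_id = ids, genome_id = genome_id, sequence = seqs,
             description = descs, stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records data.frame with columns `protein_id`, `sequence` and
#'   optionally `description`.
#' @param path output file path.
#' @param width line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  for (k in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[k])) paste(records$protein_id[k], desc[k])
           else records$protein_id[k]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[k]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
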