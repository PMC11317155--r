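#' Construct a validated multiple sequence alignment object
#'
#' @param row_ids character vector of row identifiers.
#' @param rows character vector of aligned sequences (gap character `-`).
#' @param reference_row_id id of the row whose ungapped coordinates define
#'   reference residue numbering (e.g. B. subtilis numbering such as Arg2).
#' @return an object of class `rqc_msa` with elements `row_ids`, `rows`,
#'   `reference_row_id`.
#' @export
new_msa <- function(row_ids, rows, reference_row_id) {
  if (length(row_ids) != length(rows) || length(rows) == 0L) {
    rqc_abort("MSA needs matching, non-empty row_ids and rows",
              "rqc_alignment_error")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    rqc_abort(sprintf("ragged alignment: row lengths %s",
                      paste(unique(widths), collapse = ", ")),
              "rqc_alignment_error")
  }
  if (!reference_row_id %in% row_ids) {
    rqc_abort(sprintf("reference row '%s' absent from alignment",
                      reference_row_id),
              "rqc_missing_reference_error")
  }
  ref <- rows[match(reference_row_id, row_ids)]
  if (!grepl("[^-]", ref)) {
    rqc_abort("reference row is all gaps", "rqc_missing_reference_error")
  }
  structure(list(row_ids = row_ids, rows = rows,
                 reference_row_id = reference_row_id),
            class = "rqc_msa")
}

#' Read a seed multiple sequence alignment
#'
#' Accepts aligned FASTA or Stockholm format (detected from the
#' `# STOCKHOLM` magic line). `.` gap characters are normalized to `-` and
#' sequences are uppercased, so a Stockholm file and its aligned-FASTA
#' equivalent load to identical objects.
#'
#' @inheritParams new_msa
#' @param path path to the alignment file.
#' @return an `rqc_msa` object.
#' @export
read_msa <- function(path, reference_row_id) {
  if (!file.exists(path)) {
    rqc_abort(sprintf("alignment file not found: %s", path), "rqc_io_error")
  }
  lines <- readLines(path)
  if (length(lines) > 0L && grepl("^# STOCKHOLM", lines[1])) {
    seqs <- list()
    order_ids <- character(0)
    for (ln in lines[-1]) {
      if (grepl("^//", ln) || grepl("^#", ln) || !nzchar(trimws(ln))) next
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) != 2L) {
        rqc_abort(sprintf("%s: malformed Stockholm sequence line: %s",
                          path, ln),
                  "rqc_format_error")
      }
      id <- parts[1]
      if (!id %in% order_ids) {
        order_ids <- c(order_ids, id)
        seqs[[id]] <- ""
      }
      seqs[[id]] <- paste0(seqs[[id]], parts[2])
    }
    ids <- order_ids
    rows <- unlist(seqs[ids], use.names = FALSE)
  } else {
    headers <- grep("^>", lines)
    if (length(headers) == 0L) {
      rqc_abort(sprintf("%s: neither Stockholm nor FASTA", path),
                "rqc_format_error")
    }
    ids <- sub("\\s.*$", "", sub("^>", "", lines[headers]))
    bounds <- c(headers, length(lines) + 1L)
    rows <- vapply(seq_along(headers), function(k) {
      body <- lines[seq(headers[k] + 1L, bounds[k + 1L] - 1L)]
      if (bounds[k + 1L] - 1L < headers[k] + 1L) body <- character(0)
      paste(gsub("\\s", "", body), collapse = "")
    }, character(1))
  }
  rows <- toupper(gsub(".", "-", rows, fixed = TRUE))
  new_msa(ids, rows, reference_row_id)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa an `rqc_msa` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(msa$row_ids)) {
    writeLines(c(paste0(">", msa$row_ids[k]), msa$rows[k]), con)
  }
  invisible(path)
}

#' @export
print.rqc_msa <- function(x, ...) {
  cat(sprintf("<rqc_msa> %d rows x %d columns, reference '%s'\n",
              length(x$rows), nchar(x$rows[1]), x$reference_row_id))
  invisible(x)
}
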