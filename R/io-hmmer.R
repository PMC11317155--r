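#' Parse the gathering cutoff (GA) line from a HMMER3 ASCII profile
#'
#' Pfam profiles carry a curated gathering cutoff: a pair of bit-score
#' thresholds (sequence-level, domain-level) above which hits are trusted
#' family members. Only the GA line is read; the rest of the profile text is
#' ignored.
#'
#' @param path HMMER3 ASCII profile file.
#' @return numeric vector `c(sequence_ga, domain_ga)` in bits.
#' @export
parse_ga_cutoff <- function(path) {
  if (!file.exists(path)) {
    rqc_abort(sprintf("profile file not found: %s", path), "rqc_io_error")
  }
  lines <- readLines(path)
  ga <- grep("^GA\\s", lines, value = TRUE)
  if (length(ga) == 0L) {
    rqc_abort(sprintf("%s: no GA line; supply a cutoff via the rule config",
                      path),
              "rqc_missing_cutoff_error")
  }
  nums <- regmatches(ga[1], gregexpr("-?[0-9]+\\.?[0-9]*", ga[1]))[[1]]
  if (length(nums) < 2L) {
    rqc_abort(sprintf("%s: malformed GA line: %s", path, ga[1]),
              "rqc_format_error")
  }
  c(sequence_ga = as.numeric(nums[1]), domain_ga = as.numeric(nums[2]))
}

# Column layout of the 23-column hmmsearch --domtblout standard; fields past
# 23 belong to the free-text target description.
DOMTBL_COLS <- c("target_name", "target_accession", "tlen",
                 "query_name", "query_accession", "qlen",
                 "full_evalue", "full_score", "full_bias",
                 "dom_num", "dom_total", "c_evalue", "i_evalue",
                 "dom_score", "dom_bias",
                 "hmm_from", "hmm_to", "ali_from", "ali_to",
                 "env_from", "env_to", "acc", "description")

#' Parse a HMMER3 domtblout file
#'
#' Adapter for externally produced search scores. One row is returned per
#' domain line, keyed on the fixed 23-column layout; extra whitespace-split
#' tokens at the end are folded back into the description. Comment lines
#' beginning with `#` are skipped; any other malformed line is an error, not
#' silently dropped. In hmmsearch output the *target* is the protein
#' sequence and the *query* is the profile. Coordinates are 1-based
#' inclusive.
#'
#' @param path domtblout-format file.
#' @return data.frame with one row per domain line (columns:
#'   `target_name`, `query_name`, `qlen`, `full_score`, `dom_score`,
#'   `hmm_from`, `hmm_to`, `ali_from`, `ali_to`, and the remaining standard
#'   fields).
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) {
    rqc_abort(sprintf("domtblout file not found: %s", path), "rqc_io_error")
  }
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(DOMTBL_COLS)),
                                  DOMTBL_COLS), stringsAsFactors = FALSE)
    return(out)
  }
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    toks <- strsplit(trimws(lines[keep[k]]), "\\s+")[[1]]
    if (length(toks) < 23L) {
      rqc_abort(sprintf("%s: expected >= 23 columns, got %d at line %d",
                        path, length(toks), keep[k]),
                "rqc_format_error")
    }
    toks <- c(toks[1:22], paste(toks[23:length(toks)], collapse = " "))
    rows[[k]] <- toks
  }
  mat <- do.call(rbind, rows)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- DOMTBL_COLS
  num_cols <- c("tlen", "qlen", "full_evalue", "full_score", "full_bias",
                "dom_num", "dom_total", "c_evalue", "i_evalue",
                "dom_score", "dom_bias", "hmm_from", "hmm_to",
                "ali_from", "ali_to", "env_from", "env_to", "acc")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      bad <- keep[which(is.na(v))[1]]
      rqc_abort(sprintf("%s: non-numeric value in column '%s' at line %d",
                        path, cc, bad),
                "rqc_format_error")
    }
    out[[cc]] <- v
  }
  int_cols <- c("tlen", "qlen", "dom_num", "dom_total", "hmm_from", "hmm_to",
                "ali_from", "ali_to", "env_from", "env_to")
  for (cc in int_cols) out[[cc]] <- as.integer(out[[cc]])
  out
}

#' Write rows in domtblout format
#'
#' Inverse of [parse_domtblout()], used to emit synthetic external-search
#' fixtures and for round-trip testing.
#'
#' @param rows data.frame with the columns produced by [parse_domtblout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(rows, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# domtblout written by rqcensus", con)
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    writeLines(paste(r$target_name, r$target_accession, r$tlen,
                     r$query_name, r$query_accession, r$qlen,
                     format(r$full_evalue), r$full_score, r$full_bias,
                     r$dom_num, r$dom_total,
                     format(r$c_evalue), format(r$i_evalue),
                     r$dom_score, r$dom_bias,
                     r$hmm_from, r$hmm_to, r$ali_from, r$ali_to,
                     r$env_from, r$env_to, r$acc,
                     ifelse(nzchar(r$description), r$description, "-")),
               con)
  }
  invisible(path)
}

#' Convert domtblout rows to profile hits
#'
#' Builds one hit per (protein, profile) pair from external search rows: the
#' full-sequence score is shared across a pair's domain rows and the
#' best-scoring domain supplies the aligned span. The profile-column to
#' query-position map is reconstructed from the domain's hmm/ali coordinate
#' pairs assuming a collinear (indel-free) correspondence, which is the only
#' mapping the tabular format supports; motif checks on external hits
#' therefore carry that approximation.
#'
#' @param rows data.frame from [parse_domtblout()].
#' @return named list: for each target protein id, a list of `rqc_hit`
#'   objects (one per profile), each with `bit_score` (full-sequence),
#'   `dom_score` (best domain), `query_span` and `column_map`.
#' @export
domtblout_hits <- function(rows) {
  hits <- list()
  if (nrow(rows) == 0L) return(hits)
  key <- paste(rows$target_name, rows$query_name, sep = "\r")
  for (grp in split(seq_len(nrow(rows)), key)) {
    sub <- rows[grp, , drop = FALSE]
    best <- sub[which.max(sub$dom_score), , drop = FALSE]
    span_len <- min(best$hmm_to - best$hmm_from, best$ali_to - best$ali_from)
    cols <- best$hmm_from + 0:span_len
    poss <- best$ali_from + 0:span_len
    hit <- structure(list(
      query_id = best$target_name,
      profile_name = best$query_name,
      family = NA_character_,
      bit_score = best$full_score[1],
      dom_score = best$dom_score[1],
      query_span = c(best$ali_from, best$ali_to),
      column_map = setNames(as.integer(poss), as.integer(cols)),
      coverage = length(cols) / best$qlen[1]),
      class = "rqc_hit")
    tid <- best$target_name
    hits[[tid]] <- c(hits[[tid]], list(hit))
  }
  hits
}
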