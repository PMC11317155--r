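#' Score a protein sequence against a profile
#'
#' Computes the best local profile-to-sequence alignment score in bits via
#' an affine-gap dynamic program over the profile's match-column log-odds.
#' A run of `k` skipped interior columns or residues costs
#' `gap_open + (k - 1) * gap_extend`; flanking columns and residues are
#' free; the empty alignment scores 0, so the returned bit score is never
#' negative. `X` residues score 0 bits in every column. The traceback is
#' deterministic (ties prefer extending an alignment over starting a new
#' one, and match steps over gaps), so the column map is reproducible.
#'
#' @param profile an `rqc_profile`.
#' @param record either a one-row data.frame with `protein_id` and
#'   `sequence` columns or a plain character sequence.
#' @param gap_open gap-open cost in bits (default 4).
#' @param gap_extend gap-extension cost in bits (default 0.25).
#' @return an `rqc_hit`: list with `query_id`, `profile_name`, `family`,
#'   `bit_score`, `query_span` (1-based inclusive), `column_map` (named
#'   integer vector, profile column -> query position, strictly increasing
#'   in both) and `coverage` (matched columns / profile length).
#' @export
score_sequence <- function(profile, record, gap_open = 4, gap_extend = 0.25) {
  stopifnot(inherits(profile, "rqc_profile"))
  if (gap_open < 0 || gap_extend < 0) {
    rqc_abort("gap penalties must be >= 0", "rqc_range_error")
  }
  if (is.character(record)) {
    query_id <- "query"
    sequence <- record
  } else {
    query_id <- record$protein_id[1]
    sequence <- record$sequence[1]
  }
  idx <- seq_to_idx(sequence)
  res <- psm_align_local(profile$scores, idx, gap_open, gap_extend)
  cm <- setNames(res$positions, res$columns)
  span <- if (length(cm) > 0L) c(min(res$positions), max(res$positions))
          else c(NA_integer_, NA_integer_)
  structure(list(query_id = query_id,
                 profile_name = profile$name,
                 family = profile$family,
                 bit_score = res$score,
                 dom_score = res$score,
                 query_span = span,
                 column_map = cm,
                 coverage = length(cm) / profile_length(profile)),
            class = "rqc_hit")
}

#' @export
print.rqc_hit <- function(x, ...) {
  cat(sprintf("<rqc_hit> %s vs %s: %.2f bits, %d columns matched\n",
              x$query_id, x$profile_name, x$bit_score, length(x$column_map)))
  invisible(x)
}

#' Score every protein against every profile
#'
#' @param records proteome data.frame (see [read_fasta()]).
#' @param profiles named list of `rqc_profile` objects.
#' @param gap_open,gap_extend see [score_sequence()].
#' @param min_bits hits below this bit score are dropped to keep the hit
#'   set small (default 0: keep only positive-scoring hits).
#' @return named list: `hits[[protein_id]]` is a list of `rqc_hit`.
#' @export
score_proteins <- function(records, profiles, gap_open = 4,
                           gap_extend = 0.25, min_bits = 0) {
  hits <- vector("list", nrow(records))
  names(hits) <- records$protein_id
  for (k in seq_len(nrow(records))) {
    hk <- list()
    for (p in profiles) {
      h <- score_sequence(p, records[k, ], gap_open, gap_extend)
      if (h$bit_score > min_bits) hk <- c(hk, list(h))
    }
    hits[[k]] <- hk
  }
  hits
}

#' Best bit score for a family among one query's hits
#'
#' Implements the max-over-subgroup-profiles gate: several subgroup
#' profiles may represent one family and a query qualifies on its best one.
#' Ties are broken deterministically toward the lexicographically smallest
#' profile name.
#'
#' @param hits list of `rqc_hit` for a single query.
#' @param family family tag to select.
#' @param profiles optional named profile list used to resolve the family
#'   of hits that lack a family tag (external-score adapters).
#' @param score_field `"full_sequence"` (default) or `"best_domain"`.
#' @return list with `best_bit` (0 when no hit of the family) and
#'   `best_hit` (`NULL` when none).
#' @export
max_family_score <- function(hits, family, profiles = NULL,
                             score_field = "full_sequence") {
  if (length(hits) > 0L) {
    qids <- unique(vapply(hits, function(h) h$query_id, character(1)))
    if (length(qids) > 1L) {
      rqc_abort(sprintf("hits from multiple queries: %s",
                        paste(qids, collapse = ", ")),
                "rqc_mixed_query_error")
    }
  }
  fams <- vapply(hits, function(h) {
    if (!is.na(h$family)) return(h$family)
    if (!is.null(profiles) && h$profile_name %in% names(profiles)) {
      return(profiles[[h$profile_name]]$family)
    }
    NA_character_
  }, character(1))
  sel <- which(!is.na(fams) & fams == family)
  if (length(sel) == 0L) return(list(best_bit = 0, best_hit = NULL))
  score_of <- function(h) {
    if (score_field == "best_domain") h$dom_score else h$bit_score
  }
  bits <- vapply(hits[sel], score_of, numeric(1))
  nms <- vapply(hits[sel], function(h) h$profile_name, character(1))
  ord <- order(-bits, nms)
  list(best_bit = bits[ord[1]], best_hit = hits[sel][[ord[1]]])
}

#' Locate reference-numbered residues in a query via a hit
#'
#' Composes the profile's reference map (profile column -> reference
#' residue number) with the hit's column map (profile column -> query
#' position) to find where reference-numbered positions such as Arg2 or
#' K14 fall in a query sequence.
#'
#' @param hit an `rqc_hit` against `profile`.
#' @param profile the `rqc_profile` the hit was scored with.
#' @param ref_positions integer vector of reference residue numbers.
#' @return named integer vector, one element per requested position; `NA`
#'   where the corresponding profile column is not matched in this hit.
#' @export
map_reference_positions <- function(hit, profile, ref_positions) {
  out <- setNames(rep(NA_integer_, length(ref_positions)),
                  as.character(ref_positions))
  for (k in seq_along(ref_positions)) {
    col <- which(profile$ref_map == ref_positions[k])
    if (length(col) == 0L) {
      rqc_abort(sprintf("reference position %d absent from profile '%s'",
                        ref_positions[k], profile$name),
                "rqc_unknown_position_error")
    }
    hit_cols <- as.integer(names(hit$column_map))
    m <- match(col, hit_cols)
    if (!is.na(m)) out[k] <- hit$column_map[[m]]
  }
  out
}
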