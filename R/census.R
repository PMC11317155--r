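# Per-genome and per-phylum aggregation of classification labels.
# Family column order is fixed everywhere: YlmH, RqcH, RqcP, Hsp15, SmpB.

# the 32 presence/absence patterns over the five families, as "10010" keys
all_patterns <- function() {
  grid <- expand.grid(rep(list(c(1L, 0L)), 5))[, 5:1]
  apply(grid, 1, paste, collapse = "")
}

#' Summarize one genome's classifications
#'
#' @param classifications data.frame rows ([classify_proteome()]) for a
#'   single genome.
#' @param taxonomy taxonomy data.frame ([read_taxonomy()]).
#' @return one-row data.frame: `genome_id`, `phylum`, per-family counts
#'   (`count_YlmH`, ...) and presence flags (`YlmH`, ...), with
#'   `presence == (count >= 1)`.
#' @export
summarize_genome <- function(classifications, taxonomy) {
  gid <- unique(classifications$genome_id)
  if (length(gid) != 1L) {
    rqc_abort("classifications must belong to exactly one genome",
              "rqc_consistency_error")
  }
  m <- match(gid, taxonomy$genome_id)
  if (is.na(m)) {
    rqc_abort(sprintf("genome '%s' missing from taxonomy", gid),
              "rqc_unknown_genome_error")
  }
  out <- data.frame(genome_id = gid, phylum = taxonomy$phylum[m],
                    stringsAsFactors = FALSE)
  for (f in RQC_FAMILIES) {
    out[[paste0("count_", f)]] <- sum(classifications$label == f)
  }
  for (f in RQC_FAMILIES) {
    out[[f]] <- out[[paste0("count_", f)]] >= 1L
  }
  out
}

#' Summarize all genomes
#'
#' Every genome in `taxonomy` gets a row; genomes with classifications but
#' absent from the taxonomy abort in strict mode (silent drops would
#' corrupt incidence denominators) or are dropped with a warning otherwise.
#'
#' @param classifications data.frame from [classify_proteome()].
#' @param taxonomy taxonomy data.frame.
#' @param strict abort on genomes missing from the taxonomy (default TRUE).
#' @return data.frame of genome summaries, one row per classified genome,
#'   ordered by `genome_id`.
#' @export
summarize_genomes <- function(classifications, taxonomy, strict = TRUE) {
  gids <- unique(classifications$genome_id)
  unknown <- setdiff(gids, taxonomy$genome_id)
  if (length(unknown) > 0L) {
    if (strict) {
      rqc_abort(sprintf("genome(s) missing from taxonomy: %s",
                        paste(unknown, collapse = ", ")),
                "rqc_unknown_genome_error")
    }
    warning(sprintf("dropping %d genome(s) missing from taxonomy",
                    length(unknown)))
    classifications <- classifications[
      classifications$genome_id %in% taxonomy$genome_id, , drop = FALSE]
    gids <- setdiff(gids, unknown)
  }
  rows <- lapply(sort(gids), function(g) {
    summarize_genome(classifications[classifications$genome_id == g, ,
                                     drop = FALSE],
                     taxonomy)
  })
  do.call(rbind, rows)
}

#' Co-distribution pattern counts
#'
#' Partitions genomes over the 32 presence/absence patterns of the five
#' families (pattern key: 0/1 flags in the order YlmH, RqcH, RqcP, Hsp15,
#' SmpB). Each genome falls in exactly one pattern, so the counts sum to
#' the number of genomes.
#'
#' @param genome_summaries data.frame from [summarize_genomes()].
#' @return named integer vector over all 32 patterns.
#' @export
co_distribution <- function(genome_summaries) {
  counts <- setNames(integer(32L), all_patterns())
  if (nrow(genome_summaries) > 0L) {
    mat <- as.matrix(genome_summaries[, RQC_FAMILIES, drop = FALSE])
    keys <- apply(mat, 1, function(r) paste(as.integer(r), collapse = ""))
    t <- table(keys)
    counts[names(t)] <- as.integer(t)
  }
  counts
}

#' Summarize one phylum
#'
#' Computes per-family incidence percentages (`100 * genomes-with-family /
#' n_genomes`, unrounded, plus a display value rounded half-up to integer)
#' and percentages for the named co-distribution categories reported in
#' comparative censuses: YlmH+RqcH without RqcP; YlmH+RqcP+RqcH;
#' RqcH+RqcP without YlmH; RqcH without RqcP and YlmH.
#'
#' @param genome_summaries data.frame from [summarize_genomes()].
#' @param phylum phylum name to summarize.
#' @return list of class `rqc_phylum_summary`: `phylum`, `n_genomes`,
#'   `incidence_pct`, `incidence_display`, `category_counts` (32
#'   patterns), `named_category_pct`.
#' @export
summarize_phylum <- function(genome_summaries, phylum) {
  g <- genome_summaries[genome_summaries$phylum == phylum, , drop = FALSE]
  if (nrow(g) == 0L) {
    rqc_abort(sprintf("no genomes in phylum '%s'", phylum),
              "rqc_empty_group_error")
  }
  n <- nrow(g)
  inc <- vapply(RQC_FAMILIES, function(f) 100 * sum(g[[f]]) / n, numeric(1))
  named <- c(
    ylmh_rqch_not_rqcp = 100 * sum(g$YlmH & g$RqcH & !g$RqcP) / n,
    ylmh_rqcp_rqch     = 100 * sum(g$YlmH & g$RqcP & g$RqcH) / n,
    rqch_rqcp_not_ylmh = 100 * sum(g$RqcH & g$RqcP & !g$YlmH) / n,
    rqch_not_rqcp_not_ylmh = 100 * sum(g$RqcH & !g$RqcP & !g$YlmH) / n)
  structure(list(phylum = phylum, n_genomes = n,
                 incidence_pct = inc,
                 incidence_display = round_half_up(inc),
                 category_counts = co_distribution(g),
                 named_category_pct = named),
            class = "rqc_phylum_summary")
}

#' Summarize every phylum as a table
#'
#' @param genome_summaries data.frame from [summarize_genomes()].
#' @return data.frame with one row per phylum: `phylum`, `n_genomes`,
#'   unrounded incidence columns `pct_<family>`, display columns
#'   `disp_<family>` (rounded half-up), and the named category
#'   percentages.
#' @export
summarize_phyla <- function(genome_summaries) {
  rows <- lapply(sort(unique(genome_summaries$phylum)), function(p) {
    s <- summarize_phylum(genome_summaries, p)
    row <- data.frame(phylum = s$phylum, n_genomes = s$n_genomes,
                      stringsAsFactors = FALSE)
    for (f in RQC_FAMILIES) row[[paste0("pct_", f)]] <- s$incidence_pct[[f]]
    for (f in RQC_FAMILIES) row[[paste0("disp_", f)]] <- s$incidence_display[[f]]
    for (nm in names(s$named_category_pct)) {
      row[[paste0("pct_", nm)]] <- s$named_category_pct[[nm]]
    }
    row
  })
  do.call(rbind, rows)
}

#' @export
print.rqc_phylum_summary <- function(x, ...) {
  cat(sprintf("<rqc_phylum_summary> %s: %d genomes\n", x$phylum, x$n_genomes))
  cat("  incidence (%):",
      paste(sprintf("%s %.1f", RQC_FAMILIES, x$incidence_pct),
            collapse = " | "), "\n")
  invisible(x)
}

#' Write census outputs
#'
#' Writes three files into `dir`: `presence_matrix.tsv` (per-genome counts
#' and 0/1 presence flags, family columns in the fixed order YlmH, RqcH,
#' RqcP, Hsp15, SmpB), `phylum_summary.tsv` ([summarize_phyla()] table)
#' and `presence_annotation.txt` (one line per genome — genome id then
#' five 0/1 fields, no header — for tree-annotation tools).
#'
#' @param genome_summaries data.frame from [summarize_genomes()].
#' @param phylum_summaries data.frame from [summarize_phyla()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_census <- function(genome_summaries, phylum_summaries, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    rqc_abort(sprintf("cannot create output directory: %s", dir),
              "rqc_io_error")
  }
  pm <- file.path(dir, "presence_matrix.tsv")
  ps <- file.path(dir, "phylum_summary.tsv")
  an <- file.path(dir, "presence_annotation.txt")
  gm <- genome_summaries
  for (f in RQC_FAMILIES) gm[[f]] <- as.integer(gm[[f]])
  write.table(gm, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(phylum_summaries, ps, sep = "\t", quote = FALSE,
              row.names = FALSE)
  flags <- as.matrix(genome_summaries[, RQC_FAMILIES, drop = FALSE]) * 1L
  ann <- cbind(genome_summaries$genome_id, flags)
  write.table(ann, an, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(presence_matrix = pm, phylum_summary = ps, annotation = an))
}

#' Read a presence matrix back
#'
#' Inverse of the `presence_matrix.tsv` output of [write_census()];
#' restores the logical presence flags.
#'
#' @param path path to a presence matrix TSV.
#' @return genome-summary data.frame.
#' @export
read_presence_matrix <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (f in RQC_FAMILIES) tab[[f]] <- as.logical(tab[[f]])
  tab
}
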