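#' Build a position-specific log-odds profile from a seed alignment
#'
#' Alignment columns in which the reference row carries a residue become
#' match columns, one per reference residue, so profile column `k` maps to
#' reference residue number `k` (the numbering used by motif rules such as
#' Arg2 or the K14-R15-R16 triad). The per-column score for residue `a` is
#'
#'   `log2( ((count_a + m * bg_a) / (n + m)) / bg_a )`
#'
#' in bits, where counts are taken over non-gap characters in the column,
#' `X` contributes background-distributed fractional counts, `n` is the
#' number of non-gap characters and `m` is the pseudocount mass. This
#' satisfies the identity `sum_a 2^score_a * bg_a = 1` per column.
#'
#' @param msa an `rqc_msa` seed alignment.
#' @param pseudocount_mass total pseudocount mass `m > 0` (default 1).
#' @param background probability vector over the 20 amino acids in
#'   alphabetical one-letter order; default uniform.
#' @param name profile name (e.g. `"RqcP"`, `"PF13275"`).
#' @param family family tag: one of `"YlmH"`, `"RqcH"`, `"RqcP"`,
#'   `"Hsp15"`, `"SmpB"`, `"exclusion"`.
#' @return an `rqc_profile`: list with `name`, `family`, `scores` (20 x C
#'   matrix, bits), `background`, `ref_map` (profile column -> reference
#'   residue number), `ga_cutoff` (`NULL` until attached).
#' @export
build_profile <- function(msa, pseudocount_mass = 1,
                          background = rep(1 / 20, 20),
                          name = "profile", family = "exclusion") {
  stopifnot(inherits(msa, "rqc_msa"))
  if (!is.numeric(pseudocount_mass) || pseudocount_mass <= 0) {
    rqc_abort("pseudocount_mass must be > 0", "rqc_range_error")
  }
  if (length(background) != 20L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    rqc_abort("background must be 20 strictly positive values summing to 1",
              "rqc_range_error")
  }
  ref <- msa$rows[match(msa$reference_row_id, msa$row_ids)]
  ref_chars <- strsplit(ref, "")[[1]]
  match_cols <- which(ref_chars != "-")
  if (length(match_cols) == 0L) {
    rqc_abort("reference row is all gaps", "rqc_missing_reference_error")
  }
  row_mat <- do.call(rbind, strsplit(msa$rows, ""))

  scores <- matrix(NA_real_, nrow = 20L, ncol = length(match_cols),
                   dimnames = list(AA20, NULL))
  for (k in seq_along(match_cols)) {
    col <- row_mat[, match_cols[k]]
    col <- col[col != "-"]
    counts <- setNames(numeric(20L), AA20)
    std <- col[col != "X"]
    if (length(std) > 0L) {
      t <- table(factor(std, levels = AA20))
      counts <- counts + as.numeric(t)
    }
    n_x <- sum(col == "X")
    if (n_x > 0L) counts <- counts + n_x * background
    n <- length(col)
    p <- (counts + pseudocount_mass * background) / (n + pseudocount_mass)
    scores[, k] <- log2(p / background)
  }

  structure(list(name = name, family = family, scores = scores,
                 background = background,
                 ref_map = seq_along(match_cols),
                 ga_cutoff = NULL),
            class = "rqc_profile")
}

#' Attach a gathering cutoff to a profile
#'
#' @param profile an `rqc_profile`.
#' @param sequence_ga sequence-level GA threshold in bits.
#' @param domain_ga domain-level GA threshold in bits (defaults to
#'   `sequence_ga`).
#' @return the profile with `ga_cutoff` set.
#' @export
set_ga_cutoff <- function(profile, sequence_ga, domain_ga = sequence_ga) {
  stopifnot(inherits(profile, "rqc_profile"))
  profile$ga_cutoff <- c(sequence_ga = as.numeric(sequence_ga),
                         domain_ga = as.numeric(domain_ga))
  profile
}

#' Number of match columns in a profile
#' @param profile an `rqc_profile`.
#' @return integer column count.
#' @export
profile_length <- function(profile) ncol(profile$scores)

#' @export
print.rqc_profile <- function(x, ...) {
  cat(sprintf("<rqc_profile> '%s' (family %s), %d columns%s\n",
              x$name, x$family, profile_length(x),
              if (is.null(x$ga_cutoff)) ""
              else sprintf(", GA %.2f/%.2f", x$ga_cutoff[1], x$ga_cutoff[2])))
  invisible(x)
}

#' Serialize a profile to the project TSV format
#'
#' Header metadata lines start with `#` (`name`, `family`, `background`,
#' `ga_cutoff`); then one row per profile column with the column index, the
#' reference residue number and 20 score fields.
#'
#' @param profile an `rqc_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#name\t%s", profile$name),
               sprintf("#family\t%s", profile$family),
               sprintf("#background\t%s",
                       paste(format(profile$background, digits = 17),
                             collapse = ","))), con)
  if (!is.null(profile$ga_cutoff)) {
    writeLines(sprintf("#ga_cutoff\t%s",
                       paste(format(profile$ga_cutoff, digits = 17),
                             collapse = ",")), con)
  }
  writeLines(paste(c("column", "ref_pos", AA20), collapse = "\t"), con)
  for (k in seq_len(profile_length(profile))) {
    writeLines(paste(c(k, profile$ref_map[k],
                       format(profile$scores[, k], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a profile from the project TSV format
#'
#' @param path file written by [write_profile_tsv()].
#' @return an `rqc_profile`.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[meta_idx]), "\t")
  kv <- setNames(vapply(meta, `[`, character(1), 2),
                 vapply(meta, `[`, character(1), 1))
  body <- read.delim(text = lines[-meta_idx], sep = "\t",
                     stringsAsFactors = FALSE)
  scores <- t(as.matrix(body[, AA20]))
  dimnames(scores) <- list(AA20, NULL)
  prof <- structure(list(
    name = kv[["name"]], family = kv[["family"]], scores = scores,
    background = as.numeric(strsplit(kv[["background"]], ",")[[1]]),
    ref_map = as.integer(body$ref_pos), ga_cutoff = NULL),
    class = "rqc_profile")
  if ("ga_cutoff" %in% names(kv)) {
    ga <- as.numeric(strsplit(kv[["ga_cutoff"]], ",")[[1]])
    prof <- set_ga_cutoff(prof, ga[1], ga[2])
  }
  prof
}
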