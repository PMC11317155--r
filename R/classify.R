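# Classification rule cascade.
#
# Threshold strictness follows the curation wording exactly: "exceeding"
# gates (100 / 80 / 40 bits) are strict (>), the gathering-cutoff and
# S4_2 >= 45 exclusions are inclusive (>=), and the <= 110 residue
# C-terminal distance rule is inclusive.

hit_score <- function(hit, score_field) {
  if (identical(score_field, "best_domain")) hit$dom_score else hit$bit_score
}

evidence_record <- function(rule, passed, ...) {
  list(rule = rule, passed = passed, values = list(...))
}

evidence_string <- function(evidence) {
  paste(vapply(evidence, function(e) {
    vals <- e$values
    v <- if (length(vals) == 0L) "" else
      paste0("(", paste(sprintf("%s=%s", names(vals),
                                vapply(vals, function(x)
                                  paste(format(x, digits = 6), collapse = "/"),
                                  character(1))),
                        collapse = ","), ")")
    sprintf("%s[%s]%s", e$rule, if (isTRUE(e$passed)) "pass" else "fail", v)
  }, character(1)), collapse = ";")
}

lookup_profile <- function(profiles, name) {
  if (!name %in% names(profiles)) {
    rqc_abort(sprintf("profile '%s' absent from registry", name),
              "rqc_consistency_error")
  }
  profiles[[name]]
}

# residue of `sequence` at each mapped query position; NA stays NA
residues_at <- function(sequence, positions) {
  out <- rep(NA_character_, length(positions))
  ok <- which(!is.na(positions))
  if (length(ok) > 0L) {
    out[ok] <- substring(sequence, positions[ok], positions[ok])
  }
  out
}

check_motif <- function(hit, profile, sequence, motif) {
  pos <- vapply(motif, function(m) m$position, integer(1))
  qpos <- map_reference_positions(hit, profile, pos)
  res <- residues_at(sequence, qpos)
  ok <- vapply(seq_along(motif), function(k) {
    !is.na(res[k]) &&
      res[k] %in% strsplit(motif[[k]]$allowed, "")[[1]]
  }, logical(1))
  list(passed = all(ok), qpos = qpos, residues = res)
}

#' SmpB gate: bit score at or above the gathering cutoff
#'
#' A protein is called SmpB when its score for the SmpB domain profile
#' (PF01668 by default) is equal to or greater than the profile's
#' sequence-level gathering cutoff (overridable via `config$smpb_ga`).
#'
#' @param hits list of `rqc_hit` for one query.
#' @param config an `rqc_rule_config`.
#' @param profiles named list of profiles.
#' @return list with `passed` (logical) and `evidence`.
#' @export
classify_smpb <- function(hits, config, profiles) {
  sel <- Filter(function(h) h$profile_name == config$smpb_profile, hits)
  if (length(sel) == 0L) {
    return(list(passed = FALSE,
                evidence = list(evidence_record("smpb_ga_gate", FALSE,
                                                bit = 0, ga = NA))))
  }
  bits <- vapply(sel, hit_score, numeric(1), score_field = config$score_field)
  bit <- max(bits)
  ga <- config$smpb_ga
  if (is.null(ga)) {
    prof <- if (config$smpb_profile %in% names(profiles))
      profiles[[config$smpb_profile]] else NULL
    if (!is.null(prof) && !is.null(prof$ga_cutoff)) {
      ga <- unname(prof$ga_cutoff[["sequence_ga"]])
    }
  }
  if (is.null(ga)) {
    rqc_abort(sprintf("no gathering cutoff for SmpB profile '%s' and no smpb_ga override",
                      config$smpb_profile),
              "rqc_missing_cutoff_error")
  }
  passed <- bit >= ga
  list(passed = passed,
       evidence = list(evidence_record("smpb_ga_gate", passed,
                                       bit = bit, ga = ga)))
}

#' YlmH rule: subgroup gate plus N-terminal-region coverage
#'
#' True when the best YlmH-subgroup bit score strictly exceeds
#' `ylmh_min_bits` and the best hit aligns at least
#' `ylmh_ntd_min_coverage` of the profile columns whose reference numbers
#' fall in `ylmh_ntd_ref_span` (the N-terminal + central region in
#' reference numbering); proteins carrying only the C-terminal S4 domain
#' fail the coverage requirement.
#'
#' @inheritParams classify_smpb
#' @param record one-row proteome data.frame for the query.
#' @return list with `passed` and `evidence`.
#' @export
classify_ylmh <- function(hits, record, config, profiles) {
  mfs <- max_family_score(hits, "YlmH", profiles, config$score_field)
  ev <- list(evidence_record("ylmh_bit_gate",
                             mfs$best_bit > config$ylmh_min_bits,
                             bit = mfs$best_bit,
                             threshold = config$ylmh_min_bits))
  if (mfs$best_bit <= config$ylmh_min_bits) {
    return(list(passed = FALSE, evidence = ev))
  }
  prof <- lookup_profile(profiles, mfs$best_hit$profile_name)
  span <- config$ylmh_ntd_ref_span
  ntd_cols <- which(prof$ref_map >= span[1] & prof$ref_map <= span[2])
  cov <- if (length(ntd_cols) == 0L) 0 else
    sum(ntd_cols %in% as.integer(names(mfs$best_hit$column_map))) /
      length(ntd_cols)
  passed <- cov >= config$ylmh_ntd_min_coverage
  ev <- c(ev, list(evidence_record("ylmh_ntd_coverage", passed,
                                   coverage = cov,
                                   min_coverage = config$ylmh_ntd_min_coverage)))
  list(passed = passed, evidence = ev)
}

#' RqcH rule: subgroup gate plus conserved dyad motif
#'
#' True when the best RqcH-subgroup bit score strictly exceeds
#' `rqch_min_bits` and every configured motif position (the conserved
#' Asp-Arg or similar dyad) aligns to a query residue within its allowed
#' set; a position gapped out of the alignment fails. With an empty
#' `rqch_motif` the motif check is vacuous (the positions are
#' dataset-specific and must be supplied for real runs).
#'
#' @inheritParams classify_ylmh
#' @return list with `passed` and `evidence`.
#' @export
classify_rqch <- function(hits, record, config, profiles) {
  mfs <- max_family_score(hits, "RqcH", profiles, config$score_field)
  ev <- list(evidence_record("rqch_bit_gate",
                             mfs$best_bit > config$rqch_min_bits,
                             bit = mfs$best_bit,
                             threshold = config$rqch_min_bits))
  if (mfs$best_bit <= config$rqch_min_bits) {
    return(list(passed = FALSE, evidence = ev))
  }
  if (length(config$rqch_motif) == 0L) {
    ev <- c(ev, list(evidence_record("rqch_motif", TRUE, note = "no_motif_configured")))
    return(list(passed = TRUE, evidence = ev))
  }
  prof <- lookup_profile(profiles, mfs$best_hit$profile_name)
  chk <- check_motif(mfs$best_hit, prof, record$sequence[1],
                     config$rqch_motif)
  ev <- c(ev, list(evidence_record("rqch_motif", chk$passed,
                                   residues = chk$residues)))
  list(passed = chk$passed, evidence = ev)
}

#' RqcP / Hsp15 discrimination cascade
#'
#' Evaluation order: (1) gate — the best RqcP-or-Hsp15 profile bit score
#' must strictly exceed `rqcp_hsp15_min_bits`; (2) exclusions — a bit
#' score equal to or greater than the gathering cutoff for any configured
#' exclusion domain (uS4, TyrS, RluB, YqxC families of S4-domain
#' proteins), or an S4_2 (PF13275) score `>= s4_2_exclusion_bits`, or a
#' YlmH call, removes the protein; (3) anchors — the residues aligned to
#' reference positions 2 and 4 must be Arg and Asp; (4) discrimination —
#' proteins carrying the K14-R15-R16 triad whose Arg2-equivalent lies
#' within `c_term_max_distance` residues of the C-terminus
#' (`length - position(Arg2) <= 110`, inclusive) are RqcP; the remaining
#' anchored proteins are Hsp15.
#'
#' @inheritParams classify_ylmh
#' @param is_ylmh was this protein classified as YlmH? (YlmH homologues
#'   are excluded from the RqcP/Hsp15 branch.)
#' @return list with `label` in `c("RqcP", "Hsp15", "none")` and
#'   `evidence`.
#' @export
classify_rqcp_hsp15 <- function(hits, record, config, profiles, is_ylmh) {
  cand <- list(max_family_score(hits, "RqcP", profiles, config$score_field),
               max_family_score(hits, "Hsp15", profiles, config$score_field))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "best_bit"))]]
  ev <- list(evidence_record("rqcp_hsp15_bit_gate",
                             best$best_bit > config$rqcp_hsp15_min_bits,
                             bit = best$best_bit,
                             threshold = config$rqcp_hsp15_min_bits))
  if (best$best_bit <= config$rqcp_hsp15_min_bits) {
    return(list(label = "none", evidence = ev))
  }

  # (2) exclusion cascade
  for (nm in config$exclusion_profiles_ga) {
    sel <- Filter(function(h) h$profile_name == nm, hits)
    if (length(sel) == 0L) next
    bit <- max(vapply(sel, hit_score, numeric(1),
                      score_field = config$score_field))
    prof <- if (nm %in% names(profiles)) profiles[[nm]] else NULL
    if (is.null(prof) || is.null(prof$ga_cutoff)) {
      rqc_abort(sprintf("exclusion profile '%s' lacks a gathering cutoff", nm),
                "rqc_missing_cutoff_error")
    }
    ga <- unname(prof$ga_cutoff[["sequence_ga"]])
    if (bit >= ga) {
      ev <- c(ev, list(evidence_record("exclusion_ga", FALSE,
                                       profile = nm, bit = bit, ga = ga)))
      return(list(label = "none", evidence = ev))
    }
  }
  s4_2 <- Filter(function(h) h$profile_name == config$s4_2_profile, hits)
  if (length(s4_2) > 0L) {
    bit <- max(vapply(s4_2, hit_score, numeric(1),
                      score_field = config$score_field))
    if (bit >= config$s4_2_exclusion_bits) {
      ev <- c(ev, list(evidence_record("exclusion_s4_2", FALSE,
                                       bit = bit,
                                       threshold = config$s4_2_exclusion_bits)))
      return(list(label = "none", evidence = ev))
    }
  }
  if (isTRUE(is_ylmh)) {
    ev <- c(ev, list(evidence_record("exclusion_ylmh", FALSE)))
    return(list(label = "none", evidence = ev))
  }

  # (3) anchor residues (Arg2, Asp4 in reference numbering)
  prof <- lookup_profile(profiles, best$best_hit$profile_name)
  anchors <- check_motif(best$best_hit, prof, record$sequence[1],
                         config$rqcp_anchor_positions)
  ev <- c(ev, list(evidence_record("anchor_residues", anchors$passed,
                                   residues = anchors$residues)))
  if (!anchors$passed) {
    return(list(label = "none", evidence = ev))
  }

  # (4) K14-R15-R16 plus C-terminal distance from the Arg2-equivalent
  krr <- check_motif(best$best_hit, prof, record$sequence[1],
                     config$rqcp_krr_motif)
  arg2_qpos <- anchors$qpos[1]
  distance <- nchar(record$sequence[1]) - arg2_qpos
  within <- !is.na(distance) && distance <= config$c_term_max_distance
  is_rqcp <- krr$passed && within
  ev <- c(ev, list(evidence_record("krr_motif", krr$passed,
                                   residues = krr$residues)),
          list(evidence_record("c_term_distance", within,
                               distance = distance,
                               max_distance = config$c_term_max_distance)))
  list(label = if (is_rqcp) "RqcP" else "Hsp15", evidence = ev)
}

#' Classify a single protein
#'
#' Evaluates the family rules in fixed order SmpB, YlmH, RqcH,
#' RqcP/Hsp15; the YlmH outcome feeds the RqcP/Hsp15 exclusion. A protein
#' carries at most one label, resolved by the precedence
#' SmpB > YlmH > RqcH > RqcP > Hsp15. The full rule-evaluation trace is
#' retained as evidence.
#'
#' @param hits list of `rqc_hit` for this protein (may be empty).
#' @param record one-row proteome data.frame.
#' @param config an `rqc_rule_config`.
#' @param profiles named list of profiles.
#' @return an `rqc_classification`: list with `protein_id`, `genome_id`,
#'   `label`, `family_bits` (named numeric, best bit per family) and
#'   `evidence`.
#' @export
classify_protein <- function(hits, record, config, profiles) {
  smpb <- classify_smpb(hits, config, profiles)
  ylmh <- classify_ylmh(hits, record, config, profiles)
  rqch <- classify_rqch(hits, record, config, profiles)
  rqcp <- classify_rqcp_hsp15(hits, record, config, profiles,
                              is_ylmh = ylmh$passed)
  label <- if (smpb$passed) "SmpB"
           else if (ylmh$passed) "YlmH"
           else if (rqch$passed) "RqcH"
           else if (rqcp$label != "none") rqcp$label
           else "unclassified"
  fbits <- vapply(RQC_FAMILIES, function(f) {
    max_family_score(hits, f, profiles, config$score_field)$best_bit
  }, numeric(1))
  structure(list(protein_id = record$protein_id[1],
                 genome_id = record$genome_id[1],
                 label = label,
                 family_bits = fbits,
                 evidence = c(smpb$evidence, ylmh$evidence,
                              rqch$evidence, rqcp$evidence)),
            class = "rqc_classification")
}

#' Classify every protein of a proteome
#'
#' @param records proteome data.frame (one or more genomes).
#' @param hits named list of per-protein hit lists, as produced by
#'   [score_proteins()] or [domtblout_hits()]; proteins without an entry
#'   are treated as hit-free.
#' @param config an `rqc_rule_config`.
#' @param profiles named list of profiles.
#' @return data.frame with one row per protein: `protein_id`, `genome_id`,
#'   `label`, best bit score per family (`ylmh_bits` ... `smpb_bits`) and
#'   an `evidence` trace string. Deterministic; the row order follows
#'   `records` and the labels are independent of input order.
#' @export
classify_proteome <- function(records, hits, config, profiles) {
  config <- validate_config(config)
  orphans <- setdiff(names(hits)[vapply(hits, length, integer(1)) > 0L],
                     records$protein_id)
  if (length(orphans) > 0L) {
    rqc_abort(sprintf("hits reference unknown protein id(s): %s",
                      paste(utils::head(orphans, 5), collapse = ", ")),
              "rqc_consistency_error")
  }
  n <- nrow(records)
  out <- data.frame(protein_id = records$protein_id,
                    genome_id = records$genome_id,
                    label = character(n),
                    ylmh_bits = numeric(n), rqch_bits = numeric(n),
                    rqcp_bits = numeric(n), hsp15_bits = numeric(n),
                    smpb_bits = numeric(n),
                    evidence = character(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    h <- hits[[records$protein_id[k]]]
    if (is.null(h)) h <- list()
    cl <- classify_protein(h, records[k, ], config, profiles)
    out$label[k] <- cl$label
    out$ylmh_bits[k] <- cl$family_bits[["YlmH"]]
    out$rqch_bits[k] <- cl$family_bits[["RqcH"]]
    out$rqcp_bits[k] <- cl$family_bits[["RqcP"]]
    out$hsp15_bits[k] <- cl$family_bits[["Hsp15"]]
    out$smpb_bits[k] <- cl$family_bits[["SmpB"]]
    out$evidence[k] <- evidence_string(cl$evidence)
  }
  out
}

#' Write classifications as TSV
#'
#' @param classifications data.frame from [classify_proteome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(classifications, path) {
  write.table(classifications, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
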