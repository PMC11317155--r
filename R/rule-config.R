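#' Default classification rule configuration
#'
#' All thresholds, motif positions, allowed-residue sets and exclusion
#' lists of the curation procedure, each overridable. Defaults:
#'
#' * `ylmh_min_bits = 100`, `rqch_min_bits = 80`,
#'   `rqcp_hsp15_min_bits = 40` — family bit-score gates, applied as strict
#'   inequalities ("exceeding").
#' * `s4_2_exclusion_bits = 45` — inclusive (>=) exclusion threshold for
#'   the S4_2 domain profile (`s4_2_profile = "PF13275"`).
#' * `exclusion_profiles_ga` — profiles excluded at a bit score equal to or
#'   greater than their gathering cutoff: Ribosomal_S4 (PF00163, uS4),
#'   tRNA-synt_1b (PF00579, TyrS/TyrZ), PseudoU_synth_2 (PF00849,
#'   RluB/YhcT/YlyB/YtzG), FtsJ (PF01728, YqxC).
#' * `c_term_max_distance = 110` — inclusive maximum distance in residues
#'   from the Arg2-equivalent to the C-terminus for the RqcP call.
#' * `rqcp_anchor_positions` — reference positions that must carry specific
#'   residues (Arg2, Asp4 in B. subtilis numbering).
#' * `rqcp_krr_motif` — the K14-R15-R16 triad that, together with the
#'   distance rule, separates RqcP from Hsp15.
#' * `rqch_motif` — positions/allowed-set pairs for the conserved Asp-Arg
#'   (or similar) RqcH motif; positions are dataset-specific and must be
#'   supplied (allowed sets default to D/E and R/K when omitted).
#' * `ylmh_ntd_ref_span = c(1, 166)`, `ylmh_ntd_min_coverage = 0.5` — the
#'   YlmH call requires at least half of the profile columns mapping to
#'   the reference N-terminal + central region to be aligned.
#' * `smpb_profile = "PF01668"` gated at its gathering cutoff (override via
#'   `smpb_ga`).
#' * `score_field` — which external score is gated (`"full_sequence"` or
#'   `"best_domain"`); the internal aligner produces a single score used
#'   for both.
#' * `extra_profiles` — additionally loadable profiles (PF00472, PF03462)
#'   that fire no default rule.
#' * `search_evalue_cutoff = 1e-10` — recorded for external-search
#'   adapters; not used by the internal scorer.
#' * `gap_open = 4`, `gap_extend = 0.25`, `pseudocount_mass = 1` —
#'   internal scorer parameters, in bits / bits / counts.
#'
#' @return a named list of class `rqc_rule_config`.
#' @export
default_rule_config <- function() {
  structure(list(
    ylmh_min_bits = 100,
    rqch_min_bits = 80,
    rqcp_hsp15_min_bits = 40,
    s4_2_exclusion_bits = 45,
    c_term_max_distance = 110L,
    score_field = "full_sequence",
    smpb_profile = "PF01668",
    smpb_ga = NULL,
    s4_2_profile = "PF13275",
    exclusion_profiles_ga = c("PF00163", "PF00579", "PF00849", "PF01728"),
    extra_profiles = c("PF00472", "PF03462"),
    rqcp_anchor_positions = list(list(position = 2L, allowed = "R"),
                                 list(position = 4L, allowed = "D")),
    rqcp_krr_motif = list(list(position = 14L, allowed = "K"),
                          list(position = 15L, allowed = "R"),
                          list(position = 16L, allowed = "R")),
    rqch_motif = list(),
    ylmh_ntd_ref_span = c(1L, 166L),
    ylmh_ntd_min_coverage = 0.5,
    search_evalue_cutoff = 1e-10,
    gap_open = 4,
    gap_extend = 0.25,
    pseudocount_mass = 1
  ), class = "rqc_rule_config")
}

# normalize a motif entry from YAML/list form to list(position=, allowed=)
normalize_motif <- function(entries, default_sets = NULL, what = "motif") {
  if (length(entries) == 0L) return(list())
  out <- vector("list", length(entries))
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (is.null(e$position)) {
      rqc_abort(sprintf("%s entry %d lacks a 'position' field", what, k),
                "rqc_config_error")
    }
    pos <- as.integer(e$position)
    allowed <- e$allowed
    if (is.null(allowed) && !is.null(default_sets)) {
      allowed <- default_sets[[min(k, length(default_sets))]]
    }
    if (is.null(allowed)) {
      rqc_abort(sprintf("%s entry %d lacks an 'allowed' residue set", what, k),
                "rqc_config_error")
    }
    allowed <- toupper(paste(unlist(strsplit(allowed, "")), collapse = ""))
    chars <- strsplit(allowed, "")[[1]]
    if (length(chars) == 0L || !all(chars %in% AA20)) {
      rqc_abort(sprintf("%s entry %d: allowed set '%s' is not a non-empty subset of the 20 amino acids",
                        what, k, allowed),
                "rqc_range_error")
    }
    if (is.na(pos) || pos < 1L) {
      rqc_abort(sprintf("%s entry %d: position must be a positive integer",
                        what, k),
                "rqc_range_error")
    }
    out[[k]] <- list(position = pos, allowed = allowed)
  }
  out
}

#' Validate and normalize a rule configuration
#'
#' Accepts a YAML file path or a named list of overrides; fills every
#' default, rejects unknown keys (typo protection) and range-checks values.
#'
#' @param config `NULL` (all defaults), a path to a YAML file whose keys
#'   mirror [default_rule_config()], or a named list of overrides.
#' @return a normalized `rqc_rule_config`.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_rule_config()
  if (is.null(config)) {
    overrides <- list()
  } else if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      rqc_abort(sprintf("config file not found: %s", config), "rqc_io_error")
    }
    overrides <- yaml::read_yaml(config)
    if (is.null(overrides)) overrides <- list()
  } else if (is.list(config)) {
    overrides <- unclass(config)
  } else {
    rqc_abort("config must be NULL, a file path or a named list",
              "rqc_config_error")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    rqc_abort(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")),
              "rqc_config_error")
  }
  cfg <- defaults
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]

  for (nm in c("ylmh_min_bits", "rqch_min_bits", "rqcp_hsp15_min_bits",
               "s4_2_exclusion_bits")) {
    if (!is.numeric(cfg[[nm]]) || !is.finite(cfg[[nm]])) {
      rqc_abort(sprintf("%s must be a finite number", nm), "rqc_range_error")
    }
  }
  if (!is.numeric(cfg$c_term_max_distance) ||
      cfg$c_term_max_distance < 1 ||
      cfg$c_term_max_distance != as.integer(cfg$c_term_max_distance)) {
    rqc_abort("c_term_max_distance must be a positive integer",
              "rqc_range_error")
  }
  cfg$c_term_max_distance <- as.integer(cfg$c_term_max_distance)
  if (!cfg$score_field %in% c("full_sequence", "best_domain")) {
    rqc_abort("score_field must be 'full_sequence' or 'best_domain'",
              "rqc_config_error")
  }
  if (!is.numeric(cfg$ylmh_ntd_min_coverage) ||
      cfg$ylmh_ntd_min_coverage <= 0 || cfg$ylmh_ntd_min_coverage > 1) {
    rqc_abort("ylmh_ntd_min_coverage must lie in (0, 1]", "rqc_range_error")
  }
  span <- as.integer(unlist(cfg$ylmh_ntd_ref_span))
  if (length(span) != 2L || any(span < 1L) || span[1] > span[2]) {
    rqc_abort("ylmh_ntd_ref_span must be an increasing pair of positive integers",
              "rqc_range_error")
  }
  cfg$ylmh_ntd_ref_span <- span
  if (any(c(cfg$gap_open, cfg$gap_extend) < 0)) {
    rqc_abort("gap penalties must be >= 0", "rqc_range_error")
  }
  if (cfg$pseudocount_mass <= 0) {
    rqc_abort("pseudocount_mass must be > 0", "rqc_range_error")
  }
  cfg$rqcp_anchor_positions <- normalize_motif(cfg$rqcp_anchor_positions,
                                               what = "rqcp_anchor_positions")
  cfg$rqcp_krr_motif <- normalize_motif(cfg$rqcp_krr_motif,
                                        what = "rqcp_krr_motif")
  cfg$rqch_motif <- normalize_motif(cfg$rqch_motif,
                                    default_sets = list("DE", "RK"),
                                    what = "rqch_motif")
  class(cfg) <- "rqc_rule_config"
  cfg
}

#' @export
print.rqc_rule_config <- function(x, ...) {
  cat("<rqc_rule_config>\n")
  cat(sprintf("  gates (bits, strict >): YlmH %g | RqcH %g | RqcP/Hsp15 %g\n",
              x$ylmh_min_bits, x$rqch_min_bits, x$rqcp_hsp15_min_bits))
  cat(sprintf("  exclusions: %s at >= GA; %s at >= %g bits\n",
              paste(x$exclusion_profiles_ga, collapse = ","),
              x$s4_2_profile, x$s4_2_exclusion_bits))
  cat(sprintf("  RqcP distance rule: <= %d residues from Arg2-equivalent\n",
              x$c_term_max_distance))
  invisible(x)
}
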