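# Synthetic proteomes, seed alignments and taxonomy tables with planted
# truth labels, so every pipeline stage is testable offline.
#
# Family consensus sequences are generated, never copied from real
# proteins. Motif layouts mirror the rule set: RqcP-like members carry
# Arg2/Asp4 anchors plus the K14-R15-R16 triad within a short protein
# (C-terminal distance <= 110); Hsp15-like members carry the anchors but a
# non-basic 14-16 stretch; RqcH-like members carry an Asp-Arg dyad at the
# generator's configured positions (97-98); YlmH-like members span an
# N-terminal region (reference 1-166) plus a C-terminal S4-like region.
# Decoy proteins mimic the excluded families: each embeds a short
# RqcP-window so it passes the 40-bit RqcP/Hsp15 gate, plus its own
# exclusion domain, and therefore fails exactly one rule.

SYN_FAMILY_LENGTHS <- c(YlmH = 300L, RqcH = 350L, RqcP = 86L, Hsp15 = 130L,
                        SmpB = 150L,
                        PF00163 = 60L, PF00579 = 60L, PF00849 = 60L,
                        PF01728 = 60L, PF13275 = 60L, random = 200L)

# generator-side motif coordinates (reference numbering)
SYN_RQCH_MOTIF_POS <- c(97L, 98L)
SYN_YLMH_CTD_START <- 180L

# Synthetic gathering cutoff attached to the Pfam-like domain profiles.
# A curated gathering cutoff is defined to sit above every background
# match; the local aligner's noise ceiling over desk-scale random searches
# is ~40-50 bits (longer profiles, cheap gap extension), while full-length
# member scores are several hundred bits, so 100 separates the two regimes
# with wide margins on both sides.
SYN_GA_BITS <- 100

#' Deterministic family consensus sequence
#'
#' @param family one of YlmH, RqcH, RqcP, Hsp15, SmpB, the Pfam-like
#'   domain tags (PF00163, PF00579, PF00849, PF01728, PF13275) or
#'   `"random"`.
#' @param length protein length in residues; defaults to a family-typical
#'   value (86 for RqcP-like, 130 for Hsp15-like, ...).
#' @param seed base random seed; the consensus is a pure function of
#'   `(family, length, seed)`.
#' @return list with `family`, `sequence`, `motif_positions` (named
#'   character vector, reference position -> required residue) and
#'   `protected` (positions never mutated).
#' @export
make_family_consensus <- function(family, length = NULL, seed = 1) {
  if (!family %in% names(SYN_FAMILY_LENGTHS)) {
    rqc_abort(sprintf("unknown synthetic family '%s'", family),
              "rqc_plan_error")
  }
  if (is.null(length)) length <- SYN_FAMILY_LENGTHS[[family]]
  length <- as.integer(length)

  motif <- character(0)
  if (family == "RqcP") {
    if (length < 16L || length > 112L) {
      rqc_abort("RqcP-like consensus needs 16 <= length <= 112 (distance rule)",
                "rqc_plan_error")
    }
    motif <- c(`2` = "R", `4` = "D", `14` = "K", `15` = "R", `16` = "R")
  } else if (family == "Hsp15") {
    if (length < 16L) {
      rqc_abort("Hsp15-like consensus needs length >= 16", "rqc_plan_error")
    }
    motif <- c(`2` = "R", `4` = "D", `14` = "S", `15` = "T", `16` = "G")
  } else if (family == "RqcH") {
    if (length < max(SYN_RQCH_MOTIF_POS)) {
      rqc_abort("RqcH-like consensus too short for its dyad", "rqc_plan_error")
    }
    motif <- setNames(c("D", "R"), as.character(SYN_RQCH_MOTIF_POS))
  } else if (family == "YlmH") {
    if (length < 167L) {
      rqc_abort("YlmH-like consensus must extend past reference 166",
                "rqc_plan_error")
    }
  }

  chars <- with_seed(derive_seed(seed, paste(family, length)),
                     sample(AA20, length, replace = TRUE))
  pos <- as.integer(names(motif))
  chars[pos] <- motif
  list(family = family,
       sequence = paste(chars, collapse = ""),
       motif_positions = motif,
       protected = pos)
}

#' Mutate a sequence at unprotected positions
#'
#' Each unprotected position is substituted independently with probability
#' `mutation_rate` by a uniformly chosen different residue.
#'
#' @param sequence amino-acid string.
#' @param protected_positions integer positions never mutated.
#' @param mutation_rate per-residue substitution probability in [0, 1).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return mutated sequence string.
#' @export
mutate_sequence <- function(sequence, protected_positions = integer(0),
                            mutation_rate = 0, seed = NULL) {
  if (mutation_rate < 0 || mutation_rate >= 1) {
    rqc_abort("mutation_rate must lie in [0, 1)", "rqc_range_error")
  }
  if (max(c(0L, protected_positions)) > nchar(sequence)) {
    rqc_abort("protected position beyond sequence end", "rqc_range_error")
  }
  do_mutate <- function() {
    chars <- strsplit(sequence, "")[[1]]
    hit <- runif(length(chars)) < mutation_rate
    hit[protected_positions] <- FALSE
    for (p in which(hit)) {
      chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) do_mutate() else with_seed(seed, do_mutate())
}

# seed alignment: consensus as reference row plus mutated members
make_seed_msa <- function(consensus, name, n_rows = 8, seed_rate = 0.03,
                          seed = 1) {
  rows <- c(consensus$sequence,
            vapply(seq_len(n_rows), function(k) {
              mutate_sequence(consensus$sequence, consensus$protected,
                              seed_rate,
                              seed = derive_seed(seed, paste(name, "row", k)))
            }, character(1)))
  new_msa(row_ids = c(paste0(name, "_ref"),
                      sprintf("%s_m%02d", name, seq_len(n_rows))),
          rows = rows,
          reference_row_id = paste0(name, "_ref"))
}

DECOY_KINDS <- c("uS4-like", "TyrS-like", "RluB-like", "YqxC-like",
                 "S4_2-only", "RqcH-motif-broken", "YlmH-CTD-only")

decoy_domain_of <- c("uS4-like" = "PF00163", "TyrS-like" = "PF00579",
                     "RluB-like" = "PF00849", "YqxC-like" = "PF01728",
                     "S4_2-only" = "PF13275")

# Build one decoy sequence from the consensus set. Exclusion decoys carry
# the first 24 residues of the RqcP consensus (anchors + KRR, enough to
# clear the 40-bit gate) followed by their own domain and random filler.
make_decoy <- function(kind, consensus, seed) {
  if (kind %in% names(decoy_domain_of)) {
    window <- substr(consensus$RqcP$sequence, 1, 24)
    domain <- consensus[[decoy_domain_of[[kind]]]]$sequence
    filler <- with_seed(derive_seed(seed, paste("filler", kind)),
                        paste(sample(AA20, 16, replace = TRUE),
                              collapse = ""))
    list(sequence = paste0(window, domain, filler),
         protected = 1:24)
  } else if (kind == "RqcH-motif-broken") {
    chars <- strsplit(consensus$RqcH$sequence, "")[[1]]
    chars[SYN_RQCH_MOTIF_POS] <- "A"
    list(sequence = paste(chars, collapse = ""),
         protected = SYN_RQCH_MOTIF_POS)
  } else if (kind == "YlmH-CTD-only") {
    list(sequence = substr(consensus$YlmH$sequence, SYN_YLMH_CTD_START,
                           nchar(consensus$YlmH$sequence)),
         protected = integer(0))
  } else {
    rqc_abort(sprintf("unknown decoy kind '%s'", kind), "rqc_plan_error")
  }
}

default_phylum_plan <- function() {
  list(Bacillota_sim = c("YlmH", "RqcH", "RqcP", "SmpB"),
       Deinococcota_sim = c("YlmH", "RqcH", "SmpB"),
       Thermotogota_sim = c("RqcH", "RqcP", "SmpB"),
       Armatimonadota_sim = c("RqcH", "SmpB"),
       Cyanobacteriota_sim = c("Hsp15", "SmpB"))
}

#' Generate a complete synthetic dataset with planted truth labels
#'
#' Emits everything the pipeline consumes: per-genome proteomes containing
#' planted family members, the full decoy suite (one decoy per exclusion
#' rule plus motif-failure and domain-only decoys) and random background
#' proteins; seed alignments per family and per Pfam-like domain (the
#' consensus is the reference row); a taxonomy table; and a truth table.
#'
#' @param n_genomes total number of genomes (default 50), divided as
#'   evenly as possible over the phyla of `phylum_plan`.
#' @param phylum_plan named list: phylum -> character vector of planted
#'   families per genome. The default spans five phyla with contrasting
#'   co-distribution patterns (YlmH+RqcH+RqcP, YlmH+RqcH without RqcP,
#'   RqcH+RqcP without YlmH, RqcH alone, Hsp15 alone).
#' @param mutation_rate per-residue substitution probability applied to
#'   planted members and decoys at unprotected positions (default 0).
#' @param seed master seed; the whole dataset is a pure function of the
#'   arguments.
#' @param n_background random background proteins per genome (default 28,
#'   giving ~40 proteins per genome with the planted set).
#' @param n_seed_rows non-reference rows per seed alignment (default 8).
#' @return list with `proteins` (data.frame: protein_id, genome_id,
#'   sequence, description), `truth` (protein_id, genome_id,
#'   expected_label), `taxonomy`, `seed_msas` (named list of `rqc_msa`),
#'   `seed_info` (data.frame: name, family, reference_row_id, sequence_ga,
#'   domain_ga) and `consensus`.
#' @export
make_dataset <- function(n_genomes = 50, phylum_plan = default_phylum_plan(),
                         mutation_rate = 0, seed = 1, n_background = 28,
                         n_seed_rows = 8) {
  if (length(phylum_plan) == 0L || is.null(names(phylum_plan))) {
    rqc_abort("phylum_plan must be a named list", "rqc_plan_error")
  }
  bad <- setdiff(unique(unlist(phylum_plan)), RQC_FAMILIES)
  if (length(bad) > 0L) {
    rqc_abort(sprintf("phylum_plan names unknown families: %s",
                      paste(bad, collapse = ", ")),
              "rqc_plan_error")
  }
  if (n_genomes < length(phylum_plan)) {
    rqc_abort("need at least one genome per planned phylum", "rqc_plan_error")
  }

  fam_names <- setdiff(names(SYN_FAMILY_LENGTHS), "random")
  consensus <- setNames(lapply(fam_names, make_family_consensus, seed = seed),
                        fam_names)

  seed_msas <- setNames(lapply(fam_names, function(nm) {
    make_seed_msa(consensus[[nm]], nm, n_rows = n_seed_rows, seed = seed)
  }), fam_names)
  seed_info <- data.frame(
    name = fam_names,
    family = ifelse(fam_names %in% RQC_FAMILIES,
                    fam_names,
                    ifelse(fam_names == "PF01668", "SmpB", "exclusion")),
    reference_row_id = paste0(fam_names, "_ref"),
    sequence_ga = ifelse(fam_names %in% RQC_FAMILIES, NA_real_, SYN_GA_BITS),
    domain_ga = ifelse(fam_names %in% RQC_FAMILIES, NA_real_, SYN_GA_BITS),
    stringsAsFactors = FALSE)
  # SmpB is gated at its gathering cutoff, like a Pfam domain
  seed_info$sequence_ga[seed_info$name == "SmpB"] <- SYN_GA_BITS
  seed_info$domain_ga[seed_info$name == "SmpB"] <- SYN_GA_BITS
  seed_info$name[seed_info$name == "SmpB"] <- "PF01668"
  names(seed_msas)[names(seed_msas) == "SmpB"] <- "PF01668"

  # genomes -> phyla, contiguous near-even blocks
  n_phyla <- length(phylum_plan)
  sizes <- rep(n_genomes %/% n_phyla, n_phyla) +
    (seq_len(n_phyla) <= n_genomes %% n_phyla)
  phyla_of_genome <- rep(names(phylum_plan), times = sizes)
  genome_ids <- sprintf("g%03d", seq_len(n_genomes))
  taxonomy <- data.frame(genome_id = genome_ids, phylum = phyla_of_genome,
                         stringsAsFactors = FALSE)

  proteins <- vector("list", n_genomes)
  truths <- vector("list", n_genomes)
  for (gi in seq_len(n_genomes)) {
    gid <- genome_ids[gi]
    fams <- phylum_plan[[phyla_of_genome[gi]]]
    seqs <- character(0); labels <- character(0); descs <- character(0)
    for (f in fams) {
      s <- mutate_sequence(consensus[[f]]$sequence,
                           consensus[[f]]$protected, mutation_rate,
                           seed = derive_seed(seed, paste(gid, "member", f)))
      seqs <- c(seqs, s); labels <- c(labels, f)
      descs <- c(descs, sprintf("planted %s member", f))
    }
    for (d in DECOY_KINDS) {
      dec <- make_decoy(d, consensus, seed = derive_seed(seed, paste(gid, d)))
      s <- mutate_sequence(dec$sequence, dec$protected, mutation_rate,
                           seed = derive_seed(seed, paste(gid, "decoy", d)))
      seqs <- c(seqs, s); labels <- c(labels, "unclassified")
      descs <- c(descs, sprintf("decoy %s", d))
    }
    bg <- with_seed(derive_seed(seed, paste(gid, "background")), {
      lens <- sample(80:300, n_background, replace = TRUE)
      vapply(lens, function(L) paste(sample(AA20, L, replace = TRUE),
                                     collapse = ""), character(1))
    })
    seqs <- c(seqs, bg)
    labels <- c(labels, rep("unclassified", n_background))
    descs <- c(descs, rep("random background", n_background))
    pids <- sprintf("%s_p%03d", gid, seq_along(seqs))
    proteins[[gi]] <- data.frame(protein_id = pids, genome_id = gid,
                                 sequence = seqs, description = descs,
                                 stringsAsFactors = FALSE)
    truths[[gi]] <- data.frame(protein_id = pids, genome_id = gid,
                               expected_label = labels,
                               stringsAsFactors = FALSE)
  }

  list(proteins = do.call(rbind, proteins),
       truth = do.call(rbind, truths),
       taxonomy = taxonomy,
       seed_msas = seed_msas,
       seed_info = seed_info,
       consensus = consensus)
}

#' Rule configuration matched to the synthetic dataset
#'
#' The generator plants the RqcH Asp-Arg dyad at reference positions
#' 97-98; this helper returns the default rule configuration with that
#' motif filled in (all thresholds unchanged).
#'
#' @param ... further overrides passed to [validate_config()].
#' @return an `rqc_rule_config`.
#' @export
synthetic_rule_config <- function(...) {
  overrides <- list(...)
  overrides$rqch_motif <- list(
    list(position = SYN_RQCH_MOTIF_POS[1], allowed = "DE"),
    list(position = SYN_RQCH_MOTIF_POS[2], allowed = "RK"))
  validate_config(overrides)
}

#' Write a synthetic dataset to disk in pipeline input layout
#'
#' Creates `proteomes/<genome_id>.fasta`, `seeds/<name>.afa` plus a
#' `seeds/seeds.tsv` manifest (columns: name, family, path,
#' reference_row_id, sequence_ga, domain_ga), `taxonomy.tsv` and
#' `truth.tsv` under `dir`.
#'
#' @param dataset list from [make_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  for (d in file.path(dir, c("proteomes", "seeds"))) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      rqc_abort(sprintf("cannot create %s", d), "rqc_io_error")
    }
  }
  for (gid in unique(dataset$proteins$genome_id)) {
    write_fasta(dataset$proteins[dataset$proteins$genome_id == gid, ],
                file.path(dir, "proteomes", paste0(gid, ".fasta")))
  }
  manifest <- dataset$seed_info
  manifest$path <- paste0(manifest$name, ".afa")  # relative to seeds/
  for (k in seq_len(nrow(manifest))) {
    write_msa(dataset$seed_msas[[manifest$name[k]]],
              file.path(dir, "seeds", manifest$path[k]))
  }
  write.table(manifest, file.path(dir, "seeds", "seeds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
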