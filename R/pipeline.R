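# Pipeline orchestration: profiles -> scoring (internal aligner or external
# domtblout ingestion) -> classification -> census, with a run manifest and
# atomic output staging.

#' Build profiles from a seed-alignment directory
#'
#' The directory must contain a `seeds.tsv` manifest with columns `name`,
#' `family`, `path` (alignment file, relative to the directory),
#' `reference_row_id` and optional `sequence_ga` / `domain_ga` columns
#' (NA when the profile carries no gathering cutoff).
#'
#' @param seeds_dir directory with `seeds.tsv` and the alignment files.
#' @param config an `rqc_rule_config` (supplies `pseudocount_mass`).
#' @return named list of `rqc_profile`.
#' @export
build_profiles_from_seeds <- function(seeds_dir, config = NULL) {
  config <- validate_config(config)
  manifest_path <- file.path(seeds_dir, "seeds.tsv")
  if (!file.exists(manifest_path)) {
    rqc_abort(sprintf("no seeds.tsv manifest in %s", seeds_dir),
              "rqc_config_error")
  }
  manifest <- read.delim(manifest_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "family", "path", "reference_row_id")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0L) {
    rqc_abort(sprintf("seeds.tsv lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "rqc_schema_error")
  }
  profiles <- list()
  for (k in seq_len(nrow(manifest))) {
    msa <- read_msa(file.path(seeds_dir, manifest$path[k]),
                    manifest$reference_row_id[k])
    prof <- build_profile(msa, pseudocount_mass = config$pseudocount_mass,
                          name = manifest$name[k],
                          family = manifest$family[k])
    if ("sequence_ga" %in% names(manifest) &&
        !is.na(manifest$sequence_ga[k])) {
      dga <- if ("domain_ga" %in% names(manifest) &&
                 !is.na(manifest$domain_ga[k])) manifest$domain_ga[k]
             else manifest$sequence_ga[k]
      prof <- set_ga_cutoff(prof, manifest$sequence_ga[k], dga)
    }
    profiles[[manifest$name[k]]] <- prof
  }
  profiles
}

# Load external hmmsearch scores: every *.domtblout under scores_dir plus a
# profiles.tsv manifest (name, family, length, optional sequence_ga /
# domain_ga) describing the profiles the scores were produced with. Stub
# profiles with an identity reference map are constructed so motif rules
# can address reference-numbered positions.
load_external_scores <- function(scores_dir) {
  manifest_path <- file.path(scores_dir, "profiles.tsv")
  if (!file.exists(manifest_path)) {
    rqc_abort(sprintf("no profiles.tsv manifest in %s", scores_dir),
              "rqc_config_error")
  }
  manifest <- read.delim(manifest_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "family", "length")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0L) {
    rqc_abort(sprintf("profiles.tsv lacks column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "rqc_schema_error")
  }
  profiles <- list()
  for (k in seq_len(nrow(manifest))) {
    L <- as.integer(manifest$length[k])
    prof <- structure(list(name = manifest$name[k],
                           family = manifest$family[k],
                           scores = matrix(0, nrow = 20L, ncol = L,
                                           dimnames = list(AA20, NULL)),
                           background = rep(1 / 20, 20),
                           ref_map = seq_len(L),
                           ga_cutoff = NULL),
                      class = "rqc_profile")
    if ("sequence_ga" %in% names(manifest) &&
        !is.na(manifest$sequence_ga[k])) {
      dga <- if ("domain_ga" %in% names(manifest) &&
                 !is.na(manifest$domain_ga[k])) manifest$domain_ga[k]
             else manifest$sequence_ga[k]
      prof <- set_ga_cutoff(prof, manifest$sequence_ga[k], dga)
    }
    profiles[[manifest$name[k]]] <- prof
  }
  files <- list.files(scores_dir, pattern = "\\.domtblout$",
                      full.names = TRUE)
  rows <- do.call(rbind, lapply(sort(files), parse_domtblout))
  hits <- if (is.null(rows)) list() else domtblout_hits(rows)
  for (qid in names(hits)) {
    hits[[qid]] <- lapply(hits[[qid]], function(h) {
      if (h$profile_name %in% names(profiles)) {
        h$family <- profiles[[h$profile_name]]$family
      }
      h
    })
  }
  list(profiles = profiles, hits = hits)
}

read_proteome_dir <- function(proteomes_dir) {
  files <- sort(list.files(proteomes_dir,
                           pattern = "\\.(fasta|faa|fa)$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    rqc_abort(sprintf("no FASTA files in %s", proteomes_dir),
              "rqc_config_error")
  }
  do.call(rbind, lapply(files, function(f) {
    read_fasta(f, genome_id = sub("\\.(fasta|faa|fa)$", "", basename(f)))
  }))
}

#' Run the full census pipeline
#'
#' Reads proteomes and taxonomy, obtains profile scores either from seed
#' alignments via the internal aligner (`seeds_dir`) or from precomputed
#' external hmmsearch results (`scores_dir`, HMMER3 domtblout files plus a
#' `profiles.tsv` manifest) — exactly one of the two — classifies every
#' protein, aggregates the census, and writes all outputs atomically: files
#' are staged in a temporary directory and moved into `out_dir` only after
#' every stage has succeeded, so a failed run leaves no partial outputs.
#'
#' Outputs in `out_dir`: `classifications.tsv`, `presence_matrix.tsv`,
#' `phylum_summary.tsv`, `presence_annotation.txt`, `run.log` and
#' `run_manifest.yaml` (config snapshot, input digests, package version,
#' seed, timestamp).
#'
#' @param proteomes_dir directory of per-genome FASTA files (the file base
#'   name is the genome id).
#' @param taxonomy_file genome-to-phylum TSV ([read_taxonomy()]).
#' @param out_dir output directory (created; must not already contain a
#'   manifest unless `overwrite = TRUE`).
#' @param seeds_dir seed-alignment directory ([build_profiles_from_seeds()]).
#' @param scores_dir external-score directory; mutually exclusive with
#'   `seeds_dir`.
#' @param config rule configuration: `NULL`, YAML path or named list
#'   ([validate_config()]).
#' @param seed integer recorded in the manifest; the pipeline itself is
#'   deterministic.
#' @param strict abort on genomes missing from the taxonomy (default);
#'   otherwise drop them with a warning.
#' @param overwrite allow writing into an existing output directory.
#' @return invisibly, a list with `classifications`, `genome_summaries`,
#'   `phylum_summaries`, `paths` and `manifest`.
#' @export
run_pipeline <- function(proteomes_dir, taxonomy_file, out_dir,
                         seeds_dir = NULL, scores_dir = NULL,
                         config = NULL, seed = 1L, strict = TRUE,
                         overwrite = FALSE) {
  if (is.null(seeds_dir) == is.null(scores_dir)) {
    rqc_abort("supply exactly one of seeds_dir or scores_dir",
              "rqc_config_error")
  }
  for (d in c(proteomes_dir, seeds_dir, scores_dir)) {
    if (!dir.exists(d)) {
      rqc_abort(sprintf("input directory not found: %s", d),
                "rqc_config_error")
    }
  }
  if (!file.exists(taxonomy_file)) {
    rqc_abort(sprintf("taxonomy file not found: %s", taxonomy_file),
              "rqc_config_error")
  }
  cfg <- validate_config(config)

  taxonomy <- read_taxonomy(taxonomy_file)
  records <- read_proteome_dir(proteomes_dir)

  if (strict) {
    unknown <- setdiff(unique(records$genome_id), taxonomy$genome_id)
    if (length(unknown) > 0L) {
      rqc_abort(sprintf("genome(s) missing from taxonomy: %s",
                        paste(unknown, collapse = ", ")),
                "rqc_unknown_genome_error")
    }
  }

  log_lines <- c(sprintf("rqcensus %s", as.character(packageVersion("rqcensus"))),
                 sprintf("proteins: %d in %d genome(s)", nrow(records),
                         length(unique(records$genome_id))))

  if (!is.null(seeds_dir)) {
    profiles <- build_profiles_from_seeds(seeds_dir, cfg)
    hits <- score_proteins(records, profiles,
                           gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend)
    log_lines <- c(log_lines,
                   sprintf("scoring backend: internal aligner, %d profiles",
                           length(profiles)))
  } else {
    ext <- load_external_scores(scores_dir)
    profiles <- ext$profiles
    hits <- ext$hits
    log_lines <- c(log_lines,
                   sprintf("scoring backend: external domtblout, %d profiles",
                           length(profiles)))
  }

  classifications <- classify_proteome(records, hits, cfg, profiles)
  label_counts <- table(factor(classifications$label,
                               levels = c(RQC_FAMILIES, "unclassified")))
  log_lines <- c(log_lines,
                 sprintf("labels: %s",
                         paste(sprintf("%s=%d", names(label_counts),
                                       as.integer(label_counts)),
                               collapse = " ")))

  genome_summaries <- summarize_genomes(classifications, taxonomy,
                                        strict = strict)
  phylum_summaries <- summarize_phyla(genome_summaries)

  # stage everything, then move into place
  stage <- tempfile("rqcensus_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  write_classifications(classifications,
                        file.path(stage, "classifications.tsv"))
  write_census(genome_summaries, phylum_summaries, stage)

  input_files <- c(taxonomy_file,
                   list.files(proteomes_dir, full.names = TRUE),
                   if (!is.null(seeds_dir))
                     list.files(seeds_dir, full.names = TRUE),
                   if (!is.null(scores_dir))
                     list.files(scores_dir, full.names = TRUE))
  digests <- tools::md5sum(input_files)
  names(digests) <- basename(input_files)  # content-keyed, location-free
  manifest <- list(
    tool = "rqcensus",
    version = as.character(packageVersion("rqcensus")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = as.integer(seed),
    score_backend = if (is.null(seeds_dir)) "external_domtblout"
                    else "internal_aligner",
    config = unclass(cfg),
    input_digests = as.list(digests))
  yaml::write_yaml(manifest, file.path(stage, "run_manifest.yaml"))
  writeLines(log_lines, file.path(stage, "run.log"))

  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    rqc_abort(sprintf("cannot create output directory: %s", out_dir),
              "rqc_io_error")
  }
  staged <- list.files(stage)
  if (!overwrite && any(file.exists(file.path(out_dir, staged)))) {
    rqc_abort(sprintf("output files already present in %s (use overwrite = TRUE)",
                      out_dir),
              "rqc_io_error")
  }
  ok <- file.copy(file.path(stage, staged), file.path(out_dir, staged),
                  overwrite = TRUE)
  if (!all(ok)) {
    rqc_abort(sprintf("failed to write outputs into %s", out_dir),
              "rqc_io_error")
  }

  invisible(list(classifications = classifications,
                 genome_summaries = genome_summaries,
                 phylum_summaries = phylum_summaries,
                 paths = setNames(file.path(out_dir, staged), staged),
                 manifest = manifest))
}
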