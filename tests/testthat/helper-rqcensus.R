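# Shared fixtures and the independent alignment oracle.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# wrap a raw score matrix as a profile object
make_raw_profile <- function(scores, name = "p", family = "exclusion",
                             ga = NULL) {
  dimnames(scores) <- list(AA, NULL)
  p <- structure(list(name = name, family = family, scores = scores,
                      background = rep(1 / 20, 20),
                      ref_map = seq_len(ncol(scores)), ga_cutoff = NULL),
                 class = "rqc_profile")
  if (!is.null(ga)) p <- set_ga_cutoff(p, ga)
  p
}

# residue-index vector (1..20, 21 = X) -> sequence string
idx_to_seq <- function(idx) {
  paste(c(AA, "X")[idx], collapse = "")
}

# Exhaustive-enumeration local alignment score: maximize over every
# monotone assignment of profile columns to query positions, charging
# gap_open + (k - 1) * gap_ext per interior run of k skipped columns or
# residues.  Flanks are free; the empty assignment scores 0.  Independent
# of the dynamic program it checks.
oracle_score <- function(scores, idx, gap_open, gap_ext) {
  C <- ncol(scores)
  L <- length(idx)
  best <- 0
  rec <- function(lastc, lastp, acc) {
    if (acc > best) best <<- acc
    if (lastc >= C || lastp >= L) return(invisible())
    for (cc in (lastc + 1):C) {
      for (pp in (lastp + 1):L) {
        s <- if (idx[pp] == 21L) 0 else scores[idx[pp], cc]
        pen <- 0
        if (lastc > 0) {
          gc <- cc - lastc - 1
          gp <- pp - lastp - 1
          if (gc > 0) pen <- pen + gap_open + (gc - 1) * gap_ext
          if (gp > 0) pen <- pen + gap_open + (gp - 1) * gap_ext
        }
        rec(cc, pp, acc + s - pen)
      }
    }
  }
  rec(0L, 0L, 0)
  best
}

# hand-built hit for rule-level unit tests
make_hit <- function(query_id, profile, bit, column_map = NULL,
                     dom = bit) {
  if (is.null(column_map)) {
    column_map <- setNames(seq_len(profile_length(profile)),
                           seq_len(profile_length(profile)))
  }
  structure(list(query_id = query_id, profile_name = profile$name,
                 family = profile$family, bit_score = bit,
                 dom_score = dom,
                 query_span = if (length(column_map))
                   c(min(column_map), max(column_map))
                 else c(NA_integer_, NA_integer_),
                 column_map = column_map,
                 coverage = length(column_map) / profile_length(profile)),
            class = "rqc_hit")
}

# a protein record whose first 20 residues carry the RqcP-style layout
# (R2, D4, K14-R15-R16), padded with alanine to `len`
anchored_record <- function(id = "q1", len = 86, genome = "g1",
                            krr = TRUE) {
  chars <- rep("A", len)
  chars[2] <- "R"; chars[4] <- "D"
  if (krr) { chars[14] <- "K"; chars[15] <- "R"; chars[16] <- "R" }
  data.frame(protein_id = id, genome_id = genome,
             sequence = paste(chars, collapse = ""),
             description = "", stringsAsFactors = FALSE)
}

# controlled profile registry for rule-level tests: flat-scoring profiles
# whose ref_map is the identity
rule_world <- function() {
  flat <- function(C) matrix(0, 20, C)
  list(RqcPx = make_raw_profile(flat(20), "RqcPx", "RqcP"),
       Hsp15x = make_raw_profile(flat(20), "Hsp15x", "Hsp15"),
       YlmHx = make_raw_profile(flat(200), "YlmHx", "YlmH"),
       RqcHx = make_raw_profile(flat(100), "RqcHx", "RqcH"),
       PF00163 = make_raw_profile(flat(30), "PF00163", "exclusion", ga = 22),
       PF13275 = make_raw_profile(flat(30), "PF13275", "exclusion"),
       PF01668 = make_raw_profile(flat(40), "PF01668", "SmpB", ga = 22))
}

# per-family precision/recall of classifications against a truth table
pr_stats <- function(classifications, truth) {
  merged <- merge(classifications, truth, by = c("protein_id", "genome_id"))
  stopifnot(nrow(merged) == nrow(truth))
  fams <- c("YlmH", "RqcH", "RqcP", "Hsp15", "SmpB")
  out <- data.frame(family = fams, precision = NA_real_, recall = NA_real_)
  for (k in seq_along(fams)) {
    f <- fams[k]
    tp <- sum(merged$label == f & merged$expected_label == f)
    np <- sum(merged$label == f)
    nt <- sum(merged$expected_label == f)
    out$precision[k] <- if (np == 0) 1 else tp / np
    out$recall[k] <- if (nt == 0) 1 else tp / nt
  }
  out
}
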