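test_that("build_profile evaluates the log-odds formula", {
  # single row, near-zero pseudocount: consensus residue scores ~log2(20)
  p <- build_profile(new_msa("r1", "AC", "r1"), pseudocount_mass = 1e-9)
  expect_equal(unname(p$scores["A", 1]), log2(20), tolerance = 1e-6)
  expect_equal(unname(p$scores["C", 2]), log2(20), tolerance = 1e-6)

  # counts {A:1, C:1}, uniform background, pseudocount mass 20:
  # score(A) = log2(((1 + 1) / (2 + 20)) / (1/20)) = log2(20/11)
  p <- build_profile(new_msa(c("a", "b"), c("A", "C"), "a"),
                     pseudocount_mass = 20)
  expect_equal(unname(p$scores["A", 1]), log2(20 / 11), tolerance = 1e-12)
  expect_equal(unname(p$scores["C", 1]), log2(20 / 11), tolerance = 1e-12)

  # X contributes background-distributed fractional counts:
  # column {A, X}, m = 1: p(A) = (1.05 + 0.05) / 3, score = log2(22/3)
  p <- build_profile(new_msa(c("a", "b"), c("A", "X"), "a"),
                     pseudocount_mass = 1)
  expect_equal(unname(p$scores["A", 1]), log2(22 / 3), tolerance = 1e-12)
})

test_that("profile columns satisfy the normalization identity", {
  set.seed(42)
  for (trial in 1:20) {
    n_rows <- sample(1:6, 1)
    width <- sample(1:10, 1)
    rows <- vapply(seq_len(n_rows), function(i)
      paste(sample(c(AA, "X", "-"), width, replace = TRUE,
                   prob = c(rep(1, 21), 3)), collapse = ""),
      character(1))
    # ensure reference row has at least one residue
    rows[1] <- paste(sample(AA, width, replace = TRUE), collapse = "")
    msa <- new_msa(sprintf("r%d", seq_len(n_rows)), rows, "r1")
    bg <- runif(20, 0.5, 2); bg <- bg / sum(bg)
    p <- build_profile(msa, pseudocount_mass = runif(1, 0.1, 30),
                       background = bg)
    for (k in seq_len(profile_length(p))) {
      expect_equal(sum(2^p$scores[, k] * p$background), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("build_profile maps match columns to reference numbering", {
  msa <- new_msa(c("ref", "o"), c("M-RS-D", "MKRSTD"), "ref")
  p <- build_profile(msa)
  expect_equal(profile_length(p), 4L)  # M R S D
  expect_equal(p$ref_map, 1:4)
  expect_error(build_profile(new_msa(c("r", "o"), c("----", "ACDE"), "r")),
               class = "rqc_missing_reference_error")
})

test_that("profile TSV serialization round-trips", {
  p <- build_profile(new_msa(c("a", "b"), c("MRSD", "MKSD"), "a"),
                     name = "fam1", family = "RqcP")
  p <- set_ga_cutoff(p, 25, 19.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, f)
  q <- read_profile_tsv(f)
  expect_equal(q$name, p$name)
  expect_equal(q$family, p$family)
  expect_equal(q$scores, p$scores)
  expect_equal(q$ref_map, p$ref_map)
  expect_equal(q$ga_cutoff, p$ga_cutoff)
})

test_that("score_sequence recovers the exact-match closed form", {
  p <- build_profile(new_msa("r", "MRSD", "r"), pseudocount_mass = 1e-9,
                     name = "m", family = "RqcP")
  h <- score_sequence(p, "MRSD")
  expect_equal(h$bit_score, 4 * log2(20), tolerance = 1e-5)
  expect_equal(h$column_map, setNames(1:4, 1:4))
  expect_equal(h$coverage, 1)
  expect_equal(h$query_span, c(1L, 4L))

  # no positive-scoring cell -> empty hit at the 0-bit floor
  h0 <- score_sequence(p, "WWWW")
  expect_equal(h0$bit_score, 0)
  expect_length(h0$column_map, 0L)
})

test_that("DP score equals exhaustive enumeration on 500 random instances", {
  set.seed(7)
  for (trial in 1:500) {
    C <- sample(1:6, 1)
    L <- sample(1:8, 1)
    scores <- matrix(rnorm(20 * C, 0, 3), 20, C)
    idx <- sample(1:21, L, replace = TRUE, prob = c(rep(1, 20), 2))
    go <- sample(c(0, 1, 4), 1)
    ge <- sample(c(0, 0.25, 1), 1)
    p <- make_raw_profile(scores)
    dp <- score_sequence(p, idx_to_seq(idx), gap_open = go, gap_extend = ge)
    expect_equal(dp$bit_score, oracle_score(scores, idx, go, ge),
                 tolerance = 1e-9,
                 label = sprintf("trial %d (C=%d, L=%d)", trial, C, L))
  }
})

test_that("appending residues never decreases the local score", {
  set.seed(11)
  p <- build_profile(new_msa(c("a", "b"), c("MRSDKLMNP", "MRTDKLMNA"), "a"),
                     name = "m", family = "RqcP")
  for (trial in 1:30) {
    base <- paste(sample(AA, sample(3:12, 1), replace = TRUE), collapse = "")
    ext <- paste(sample(AA, 3, replace = TRUE), collapse = "")
    expect_gte(score_sequence(p, paste0(base, ext))$bit_score,
               score_sequence(p, base)$bit_score)
    expect_gte(score_sequence(p, paste0(ext, base))$bit_score,
               score_sequence(p, base)$bit_score)
  }
})

test_that("no query outscores the profile's own sequence", {
  set.seed(13)
  seq0 <- paste(sample(AA, 12, replace = TRUE), collapse = "")
  p <- build_profile(new_msa("r", seq0, "r"), pseudocount_mass = 1e-9)
  self <- score_sequence(p, seq0)$bit_score
  for (trial in 1:50) {
    q <- paste(sample(AA, sample(5:20, 1), replace = TRUE), collapse = "")
    expect_lte(score_sequence(p, q)$bit_score, self + 1e-9)
  }
})

test_that("column maps are strictly increasing and deterministic", {
  set.seed(17)
  p <- build_profile(new_msa(c("a", "b"),
                             c("MRSDKLMNPQRST", "MRTDKLANPQRSA"), "a"),
                     name = "m", family = "RqcP")
  for (trial in 1:30) {
    q <- paste(sample(AA, sample(6:20, 1), replace = TRUE), collapse = "")
    h1 <- score_sequence(p, q)
    h2 <- score_sequence(p, q)
    expect_identical(h1$column_map, h2$column_map)
    if (length(h1$column_map) > 1L) {
      expect_true(all(diff(as.integer(names(h1$column_map))) > 0))
      expect_true(all(diff(h1$column_map) > 0))
    }
  }
})

test_that("max_family_score applies the max-over-subgroups gate", {
  p1 <- make_raw_profile(matrix(0, 20, 5), "YlmH_a", "YlmH")
  p2 <- make_raw_profile(matrix(0, 20, 5), "YlmH_b", "YlmH")
  hits <- list(make_hit("q", p1, 95), make_hit("q", p2, 104))
  res <- max_family_score(hits, "YlmH")
  expect_equal(res$best_bit, 104)
  expect_equal(res$best_hit$profile_name, "YlmH_b")

  expect_equal(max_family_score(hits, "RqcH")$best_bit, 0)
  expect_null(max_family_score(hits, "RqcH")$best_hit)

  # exact tie broken toward the lexicographically smallest profile name
  tied <- list(make_hit("q", p2, 100), make_hit("q", p1, 100))
  expect_equal(max_family_score(tied, "YlmH")$best_hit$profile_name,
               "YlmH_a")

  mixed <- list(make_hit("q1", p1, 50), make_hit("q2", p2, 60))
  expect_error(max_family_score(mixed, "YlmH"),
               class = "rqc_mixed_query_error")
})

test_that("map_reference_positions composes ref_map with the column map", {
  p <- make_raw_profile(matrix(0, 20, 4), "t", "RqcP")
  h <- make_hit("q", p, 50, column_map = setNames(c(3L, 4L), c(1L, 2L)))
  expect_equal(map_reference_positions(h, p, 2L), c(`2` = 4L))
  # gapped-out column -> NA
  expect_equal(map_reference_positions(h, p, c(2L, 4L)),
               c(`2` = 4L, `4` = NA_integer_))
  expect_error(map_reference_positions(h, p, 9L),
               class = "rqc_unknown_position_error")

  # identity alignment of a reference sequence to its own profile
  prof <- build_profile(new_msa("r", "MRSDKL", "r"),
                        pseudocount_mass = 1e-9)
  hit <- score_sequence(prof, "MRSDKL")
  expect_equal(map_reference_positions(hit, prof, c(1L, 3L, 6L)),
               c(`1` = 1L, `3` = 3L, `6` = 6L))
})
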