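# Rule-level tests use hand-built hits against flat profiles whose
# reference map is the identity, so bit scores and aligned positions are
# fully controlled.

test_that("SmpB gate is inclusive at the gathering cutoff", {
  w <- rule_world()
  cfg <- validate_config(list(smpb_profile = "PF01668"))
  rec <- anchored_record()

  expect_true(classify_smpb(list(make_hit("q1", w$PF01668, 25)),
                            cfg, w)$passed)
  expect_true(classify_smpb(list(make_hit("q1", w$PF01668, 22)),
                            cfg, w)$passed)  # == GA counts
  expect_false(classify_smpb(list(make_hit("q1", w$PF01668, 21.99)),
                             cfg, w)$passed)
  expect_false(classify_smpb(list(), cfg, w)$passed)

  # GA missing everywhere -> error; config override rescues
  noga <- w
  noga$PF01668$ga_cutoff <- NULL
  expect_error(classify_smpb(list(make_hit("q1", noga$PF01668, 30)),
                             cfg, noga),
               class = "rqc_missing_cutoff_error")
  cfg2 <- validate_config(list(smpb_ga = 28))
  expect_true(classify_smpb(list(make_hit("q1", noga$PF01668, 30)),
                            cfg2, noga)$passed)
})

test_that("YlmH needs a strict 100-bit gate plus N-terminal coverage", {
  w <- rule_world()
  cfg <- validate_config(NULL)
  rec <- anchored_record(len = 300)
  full_map <- setNames(1:200, 1:200)

  expect_true(classify_ylmh(list(make_hit("q1", w$YlmHx, 104,
                                          column_map = full_map)),
                            rec, cfg, w)$passed)
  # exactly 100 bits fails the strict gate
  expect_false(classify_ylmh(list(make_hit("q1", w$YlmHx, 100,
                                           column_map = full_map)),
                             rec, cfg, w)$passed)
  # S4-domain-only hit: high score but no N-terminal columns aligned
  ctd_map <- setNames(1:30, 170:199)
  expect_false(classify_ylmh(list(make_hit("q1", w$YlmHx, 150,
                                           column_map = ctd_map)),
                             rec, cfg, w)$passed)
})

test_that("RqcH needs a strict 80-bit gate plus the configured dyad", {
  w <- rule_world()
  cfg <- validate_config(list(rqch_motif = list(
    list(position = 2L, allowed = "DE"),
    list(position = 4L, allowed = "RK"))))
  chars <- rep("A", 120); chars[2] <- "D"; chars[4] <- "R"
  rec <- data.frame(protein_id = "q1", genome_id = "g1",
                    sequence = paste(chars, collapse = ""),
                    description = "", stringsAsFactors = FALSE)
  full_map <- setNames(1:100, 1:100)

  expect_true(classify_rqch(list(make_hit("q1", w$RqcHx, 85,
                                          column_map = full_map)),
                            rec, cfg, w)$passed)
  expect_false(classify_rqch(list(make_hit("q1", w$RqcHx, 80,
                                           column_map = full_map)),
                             rec, cfg, w)$passed)
  # motif position gapped out of the alignment fails
  gap_map <- setNames(c(1L, 3L, 4L), c(1L, 3L, 4L))  # column 2 unmatched
  expect_false(classify_rqch(list(make_hit("q1", w$RqcHx, 85,
                                           column_map = gap_map)),
                             rec, cfg, w)$passed)
  # wrong residue fails
  chars[2] <- "G"
  rec$sequence <- paste(chars, collapse = "")
  expect_false(classify_rqch(list(make_hit("q1", w$RqcHx, 85,
                                           column_map = full_map)),
                             rec, cfg, w)$passed)
})

test_that("RqcP/Hsp15 cascade honours every printed boundary", {
  w <- rule_world()
  cfg <- validate_config(NULL)
  hit20 <- function(bit) make_hit("q1", w$RqcPx, bit)

  # clean RqcP: 86 aa, Arg2 at query position 2 -> distance 84
  rec <- anchored_record(len = 86)
  res <- classify_rqcp_hsp15(list(hit20(55)), rec, cfg, w, FALSE)
  expect_equal(res$label, "RqcP")

  # strict 40-bit gate
  expect_equal(classify_rqcp_hsp15(list(hit20(40)), rec, cfg, w,
                                   FALSE)$label, "none")
  expect_equal(classify_rqcp_hsp15(list(hit20(40.01)), rec, cfg, w,
                                   FALSE)$label, "RqcP")

  # distance boundary: 110 inclusive RqcP, 111 Hsp15
  rec112 <- anchored_record(len = 112)   # 112 - 2 = 110
  expect_equal(classify_rqcp_hsp15(list(hit20(55)), rec112, cfg, w,
                                   FALSE)$label, "RqcP")
  rec113 <- anchored_record(len = 113)   # 113 - 2 = 111
  expect_equal(classify_rqcp_hsp15(list(hit20(55)), rec113, cfg, w,
                                   FALSE)$label, "Hsp15")

  # missing KRR -> Hsp15 even when short
  rec_nokrr <- anchored_record(len = 86, krr = FALSE)
  expect_equal(classify_rqcp_hsp15(list(hit20(55)), rec_nokrr, cfg, w,
                                   FALSE)$label, "Hsp15")

  # missing anchors -> none
  rec_noanchor <- rec
  rec_noanchor$sequence <- sub("^AR", "AA", rec_noanchor$sequence)
  expect_equal(classify_rqcp_hsp15(list(hit20(55)), rec_noanchor, cfg, w,
                                   FALSE)$label, "none")
})

test_that("RqcP/Hsp15 exclusions are inclusive and one-directional", {
  w <- rule_world()
  cfg <- validate_config(NULL)
  rec <- anchored_record(len = 86)
  base <- list(make_hit("q1", w$RqcPx, 55))

  # S4_2 at exactly 45 bits excludes; 44.99 does not
  s4 <- make_hit("q1", w$PF13275, 45)
  expect_equal(classify_rqcp_hsp15(c(base, list(s4)), rec, cfg, w,
                                   FALSE)$label, "none")
  s4lo <- make_hit("q1", w$PF13275, 44.99)
  expect_equal(classify_rqcp_hsp15(c(base, list(s4lo)), rec, cfg, w,
                                   FALSE)$label, "RqcP")

  # gathering-cutoff exclusion at exactly GA (22) excludes
  us4 <- make_hit("q1", w$PF00163, 22)
  expect_equal(classify_rqcp_hsp15(c(base, list(us4)), rec, cfg, w,
                                   FALSE)$label, "none")
  us4lo <- make_hit("q1", w$PF00163, 21.9)
  expect_equal(classify_rqcp_hsp15(c(base, list(us4lo)), rec, cfg, w,
                                   FALSE)$label, "RqcP")

  # YlmH call excludes
  expect_equal(classify_rqcp_hsp15(base, rec, cfg, w, TRUE)$label, "none")

  # monotone exclusion: an exclusion hit turns either label into none,
  # never RqcP into Hsp15 (checked on both branch outcomes)
  rec_h <- anchored_record(len = 113)
  expect_equal(classify_rqcp_hsp15(base, rec_h, cfg, w, FALSE)$label,
               "Hsp15")
  expect_equal(classify_rqcp_hsp15(c(base, list(us4)), rec_h, cfg, w,
                                   FALSE)$label, "none")
})

test_that("classify_protein applies precedence and feeds the YlmH exclusion", {
  w <- rule_world()
  cfg <- validate_config(NULL)

  # satisfies only RqcH (no motif configured -> vacuous motif)
  chars <- rep("A", 120)
  rec <- data.frame(protein_id = "q1", genome_id = "g1",
                    sequence = paste(chars, collapse = ""),
                    description = "", stringsAsFactors = FALSE)
  cl <- classify_protein(list(make_hit("q1", w$RqcHx, 90)), rec, cfg, w)
  expect_equal(cl$label, "RqcH")

  # satisfies YlmH and the RqcP gate -> YlmH wins, RqcP branch excluded
  rec2 <- anchored_record(len = 300)
  hits <- list(make_hit("q1", w$YlmHx, 120,
                        column_map = setNames(1:200, 1:200)),
               make_hit("q1", w$RqcPx, 55))
  cl2 <- classify_protein(hits, rec2, cfg, w)
  expect_equal(cl2$label, "YlmH")
  ev <- evidence <- vapply(cl2$evidence, `[[`, character(1), "rule")
  expect_true("exclusion_ylmh" %in% ev)

  # no hits above any gate -> unclassified
  cl3 <- classify_protein(list(), anchored_record(), cfg, w)
  expect_equal(cl3$label, "unclassified")
  # never both RqcP and Hsp15: single label by construction
  expect_length(cl3$label, 1L)
})

test_that("classify_proteome is order-invariant and flags orphans", {
  w <- rule_world()
  cfg <- validate_config(NULL)
  recs <- rbind(anchored_record("p1", len = 86),
                anchored_record("p2", len = 113),
                anchored_record("p3", len = 86))
  hits <- list(p1 = list(make_hit("p1", w$RqcPx, 55)),
               p2 = list(make_hit("p2", w$RqcPx, 55)),
               p3 = list())
  out <- classify_proteome(recs, hits, cfg, w)
  expect_equal(out$label, c("RqcP", "Hsp15", "unclassified"))

  shuffled <- classify_proteome(recs[c(3, 1, 2), ], hits, cfg, w)
  expect_equal(shuffled[order(shuffled$protein_id), "label"],
               out[order(out$protein_id), "label"])

  bad_hits <- c(hits, list(zz = list(make_hit("zz", w$RqcPx, 50))))
  expect_error(classify_proteome(recs, bad_hits, cfg, w),
               class = "rqc_consistency_error")

  empty <- classify_proteome(recs[0, ], list(), cfg, w)
  expect_equal(nrow(empty), 0L)
})
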