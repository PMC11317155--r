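make_cls <- function(genome_id, labels) {
  data.frame(protein_id = sprintf("%s_p%02d", genome_id, seq_along(labels)),
             genome_id = genome_id, label = labels,
             stringsAsFactors = FALSE)
}

two_phylum_summaries <- function() {
  # phylum A: g1 {RqcH, RqcP}, g2 {RqcH}, g3 {};  phylum B: g4 {YlmH, RqcH}
  tax <- data.frame(genome_id = c("g1", "g2", "g3", "g4"),
                    phylum = c("A", "A", "A", "B"),
                    stringsAsFactors = FALSE)
  cls <- rbind(make_cls("g1", c("RqcH", "RqcP", rep("unclassified", 5))),
               make_cls("g2", c("RqcH", "unclassified")),
               make_cls("g3", "unclassified"),
               make_cls("g4", c("YlmH", "RqcH", "YlmH")))
  summarize_genomes(cls, tax)
}

test_that("summarize_genome derives presence from counts", {
  tax <- data.frame(genome_id = "g1", phylum = "A",
                    stringsAsFactors = FALSE)
  g <- summarize_genome(make_cls("g1", c("RqcH", "RqcP",
                                         rep("unclassified", 5))), tax)
  expect_true(g$RqcH && g$RqcP)
  expect_false(g$YlmH || g$Hsp15 || g$SmpB)
  expect_equal(g$count_RqcH, 1L)

  g2 <- summarize_genome(make_cls("g1", c("YlmH", "YlmH")), tax)
  expect_equal(g2$count_YlmH, 2L)
  expect_true(g2$YlmH)

  g3 <- summarize_genome(make_cls("g1", rep("unclassified", 3)), tax)
  expect_false(any(unlist(g3[c("YlmH", "RqcH", "RqcP", "Hsp15", "SmpB")])))

  expect_error(summarize_genome(make_cls("gX", "RqcH"), tax),
               class = "rqc_unknown_genome_error")
})

test_that("phylum incidence percentages and display rounding", {
  gs <- two_phylum_summaries()
  s <- summarize_phylum(gs, "A")
  expect_equal(s$n_genomes, 3L)
  expect_equal(unname(s$incidence_pct[["RqcH"]]), 100 * 2 / 3)
  expect_equal(unname(s$incidence_display[["RqcH"]]), 67)

  # a 4-genome phylum with 3 carriers -> 75%
  tax <- data.frame(genome_id = sprintf("g%d", 1:4), phylum = "P",
                    stringsAsFactors = FALSE)
  cls <- rbind(make_cls("g1", "RqcH"), make_cls("g2", "RqcH"),
               make_cls("g3", "RqcH"), make_cls("g4", "unclassified"))
  s4 <- summarize_phylum(summarize_genomes(cls, tax), "P")
  expect_equal(unname(s4$incidence_pct[["RqcH"]]), 75)

  # single genome -> every incidence is 0 or 100
  s1 <- summarize_phylum(gs, "B")
  expect_true(all(s1$incidence_pct %in% c(0, 100)))

  expect_error(summarize_phylum(gs, "Z"), class = "rqc_empty_group_error")
})

test_that("126 of 133 genomes displays as 95% under half-up rounding", {
  tax <- data.frame(genome_id = sprintf("g%03d", 1:133), phylum = "D",
                    stringsAsFactors = FALSE)
  labels <- function(has_pair) {
    if (has_pair) c("YlmH", "RqcH") else "unclassified"
  }
  cls <- do.call(rbind, lapply(1:133, function(i)
    make_cls(sprintf("g%03d", i), labels(i <= 126))))
  s <- summarize_phylum(summarize_genomes(cls, tax), "D")
  expect_equal(unname(s$named_category_pct[["ylmh_rqch_not_rqcp"]]),
               100 * 126 / 133, tolerance = 1e-12)  # 94.7368...
  expect_equal(round_half_up(s$named_category_pct[["ylmh_rqch_not_rqcp"]]),
               95)
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)   # base round() would give 2
  expect_equal(round_half_up(94.74), 95)
  expect_equal(round_half_up(94.4), 94)
  expect_equal(round_half_up(64.25, 1), 64.3)
})

test_that("co-distribution partitions genomes over the 32 patterns", {
  gs <- two_phylum_summaries()
  cc <- co_distribution(gs)
  expect_length(cc, 32L)
  expect_equal(sum(cc), nrow(gs))
  # g1 {RqcH, RqcP} -> pattern 01100 (YlmH RqcH RqcP Hsp15 SmpB)
  expect_equal(unname(cc[["01100"]]), 1L)
  expect_equal(unname(cc[["01000"]]), 1L)  # g2
  expect_equal(unname(cc[["00000"]]), 1L)  # g3
  expect_equal(unname(cc[["11000"]]), 1L)  # g4

  # identical patterns pool; empty input is all zeros
  expect_equal(unname(co_distribution(gs[c(2, 2), ])[["01000"]]), 2L)
  expect_equal(sum(co_distribution(gs[0, ])), 0L)
})

test_that("incidence of a conjunction never exceeds a conjunct", {
  gs <- two_phylum_summaries()
  for (p in unique(gs$phylum)) {
    s <- summarize_phylum(gs, p)
    expect_lte(s$named_category_pct[["ylmh_rqcp_rqch"]],
               min(s$incidence_pct[c("YlmH", "RqcP", "RqcH")]))
    expect_lte(s$named_category_pct[["rqch_rqcp_not_ylmh"]],
               min(s$incidence_pct[c("RqcH", "RqcP")]))
  }
})

test_that("summaries are invariant to genome input order", {
  gs <- two_phylum_summaries()
  perm <- gs[sample(nrow(gs)), ]
  expect_equal(co_distribution(perm)[sort(names(co_distribution(perm)))],
               co_distribution(gs)[sort(names(co_distribution(gs)))])
  expect_equal(summarize_phyla(perm), summarize_phyla(gs))
})

test_that("census files round-trip and keep the fixed column order", {
  gs <- two_phylum_summaries()
  ps <- summarize_phyla(gs)
  dir <- withr::local_tempdir()
  paths <- write_census(gs, ps, dir)
  expect_true(all(file.exists(paths)))

  back <- read_presence_matrix(paths[["presence_matrix"]])
  for (f in c("YlmH", "RqcH", "RqcP", "Hsp15", "SmpB")) {
    expect_equal(back[[f]], gs[[f]])
  }
  # presence columns in the fixed order
  nm <- names(back)
  expect_equal(nm[match(c("YlmH", "RqcH", "RqcP", "Hsp15", "SmpB"), nm)],
               c("YlmH", "RqcH", "RqcP", "Hsp15", "SmpB"))
  expect_true(which(nm == "YlmH") < which(nm == "RqcH"))

  # annotation export: genome id plus five 0/1 fields, no header
  ann <- read.delim(paths[["annotation"]], header = FALSE, sep = "\t")
  expect_equal(ncol(ann), 6L)
  expect_equal(nrow(ann), nrow(gs))
  expect_true(all(unlist(ann[, 2:6]) %in% 0:1))
})

test_that("strict mode aborts on genomes missing from the taxonomy", {
  tax <- data.frame(genome_id = "g1", phylum = "A",
                    stringsAsFactors = FALSE)
  cls <- rbind(make_cls("g1", "RqcH"), make_cls("g9", "RqcH"))
  expect_error(summarize_genomes(cls, tax, strict = TRUE),
               class = "rqc_unknown_genome_error")
  expect_warning(out <- summarize_genomes(cls, tax, strict = FALSE),
                 "dropping")
  expect_equal(out$genome_id, "g1")
})
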