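r1_family <- data.frame(name = "R1", te_class = "LINE", consensus_len = 5429L,
                        ltr_len = 0L, stringsAsFactors = FALSE)

test_that("a single full-span hit becomes one complete copy", {
  hits <- hit_row("chr", 1000, 6429, "+", "R1", 1, 5429)
  cp <- merge_fragments(hits, r1_family)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$completeness, 1.0)
  expect_equal(cp$category, "full_length")
})

test_that("compatible fragments merge and completeness is the consensus union", {
  fam <- data.frame(name = "F", te_class = "LINE", consensus_len = 5000L,
                    ltr_len = 0L, stringsAsFactors = FALSE)
  hits <- rbind(hit_row("chr", 1000, 3000, "+", "F", 1, 2000),
                hit_row("chr", 3300, 5801, "+", "F", 2500, 5000))
  cp <- merge_fragments(hits, fam)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$completeness, (2000 + 2501) / 5000)
  expect_equal(cp$n_fragments, 2L)
  # same fragments on opposite strands stay separate
  hits2 <- hits; hits2$strand <- c("+", "-")
  expect_equal(nrow(merge_fragments(hits2, fam)), 2L)
  # a genomic gap beyond max_gap splits the copy
  hits3 <- hits; hits3$start[2] <- 20000L; hits3$end[2] <- 22501L
  expect_equal(nrow(merge_fragments(hits3, fam)), 2L)
})

test_that("hits of unknown families are rejected by name", {
  hits <- hit_row("chr", 0, 100, "+", "NOVEL", 1, 100)
  expect_error(merge_fragments(hits, r1_family), "NOVEL")
})

test_that("the 70% completeness boundary is inclusive for full length", {
  fam <- data.frame(name = "L", te_class = "LINE", consensus_len = 1000L,
                    ltr_len = 0L, stringsAsFactors = FALSE)
  at <- merge_fragments(hit_row("chr", 0, 700, "+", "L", 1, 700), fam)
  below <- merge_fragments(hit_row("chr", 0, 699, "+", "L", 1, 699), fam)
  expect_equal(at$completeness, 0.70)
  expect_equal(at$category, "full_length")
  expect_equal(below$completeness, 0.699)
  expect_equal(below$category, "fragment")
})

test_that("LTR copies need both LTRs and internal sequence to be full length", {
  fam <- data.frame(name = "G", te_class = "LTR", consensus_len = 1000L,
                    ltr_len = 100L, stringsAsFactors = FALSE)
  full <- merge_fragments(hit_row("chr", 0, 1000, "+", "G", 1, 1000), fam)
  expect_true(full$has_5ltr && full$has_3ltr && full$has_internal)
  expect_equal(full$category, "full_length")
  # high completeness but the 3' LTR entirely missing -> fragment
  no3 <- merge_fragments(hit_row("chr", 0, 900, "+", "G", 1, 900), fam)
  expect_equal(no3$completeness, 0.9)
  expect_false(no3$has_3ltr)
  expect_equal(no3$category, "fragment")
  # LTR-region-only coverage -> solo LTR
  solo <- merge_fragments(hit_row("chr", 0, 100, "+", "G", 1, 100), fam)
  expect_equal(solo$category, "solo_LTR")
})

test_that("LTR/internal component naming is resolved onto one consensus", {
  fam <- data.frame(name = "G", te_class = "LTR", consensus_len = 1000L,
                    ltr_len = 100L, stringsAsFactors = FALSE)
  hits <- rbind(hit_row("chr", 0, 100, "+", "G_LTR", 1, 100),
                hit_row("chr", 100, 900, "+", "G_I", 1, 800),
                hit_row("chr", 900, 1000, "+", "G_LTR", 1, 100))
  cp <- merge_fragments(hits, fam)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$completeness, 1.0)
  expect_equal(cp$category, "full_length")
  # and in antisense orientation (genomic order reverses element order)
  hits_m <- hits; hits_m$strand <- "-"
  cpm <- merge_fragments(hits_m, fam)
  expect_equal(nrow(cpm), 1L)
  expect_equal(cpm$category, "full_length")
})

test_that("merging partitions hits and is idempotent on simulated loci", {
  sim <- simulate_locus(sim_config(seed = 91, n_insertions = 120L))
  cp <- merge_fragments(sim$hits, sim$families)
  expect_equal(sum(cp$n_fragments), nrow(sim$hits))
  frag_ids <- sort(unlist(lapply(cp$fragments, function(f) f$linkage_id)))
  expect_equal(frag_ids, sort(sim$hits$linkage_id))
  expect_true(all(cp$completeness >= 0 & cp$completeness <= 1))
  expect_true(all(cp$completeness[cp$category == "full_length"] >= 0.70))
  # re-merging emitted fragments reproduces the same copies
  refrag <- do.call(rbind, cp$fragments)
  refrag <- refrag[order(refrag$contig, refrag$start), ]
  cp2 <- merge_fragments(refrag, sim$families)
  expect_equal(cp2[, c("family", "start", "end", "strand", "completeness", "category")],
               cp[, c("family", "start", "end", "strand", "completeness", "category")])
})

test_that("classification matches the generator's planted categories exactly", {
  for (s in c(7, 19)) {
    sim <- simulate_locus(sim_config(seed = s, n_insertions = 150L))
    cp <- merge_fragments(sim$hits, sim$families)
    tr <- sim$truth$insertions
    expect_equal(nrow(cp), nrow(tr))
    m <- merge(tr, cp, by = "start")
    expect_equal(nrow(m), nrow(tr))
    expect_equal(m$category.y, m$category.x)
    expect_equal(m$strand.y, m$strand.x)
  }
})

test_that("composition percentages follow the antisense definition", {
  fams <- data.frame(name = c("A", "B"), te_class = c("LTR", "LINE"),
                     consensus_len = c(1000L, 1000L), ltr_len = c(100L, 0L),
                     stringsAsFactors = FALSE)
  copies <- data.frame(
    family = c(rep("A", 4), rep("B", 6)),
    strand = c(rep("-", 4), "-", rep("+", 5)),
    category = "fragment", stringsAsFactors = FALSE)
  cs <- composition_stats(copies, fams, cluster_strand = "+")
  expect_equal(cs$pct_antisense, 50)
  expect_equal(cs$pct_antisense_that_are_LTR, 80)
  all_sense <- copies; all_sense$strand <- "+"
  cs2 <- composition_stats(all_sense, fams, "+")
  expect_equal(cs2$pct_antisense, 0)
  expect_true(is.na(cs2$pct_antisense_that_are_LTR))
  expect_error(composition_stats(copies[0, ], fams, "+"), "empty")
})

test_that("window enrichment uses half-open start-assigned tiling windows", {
  x <- data.frame(start = sample(300000:399999, 30), family = "mdg4")
  we <- window_enrichment(x, contig_len = 1e6, window = 1e5)
  expect_equal(nrow(we), 10L)
  expect_equal(we$count[4], 30L)          # window [300000, 400000)
  expect_equal(sum(we$count), 30L)
  expect_equal(sum(window_enrichment(x[0, ], 1e6, 1e5)$count), 0L)
  edge <- data.frame(start = 200000L, family = "mdg4")
  we2 <- window_enrichment(edge, 1e6, 1e5)
  expect_equal(we2$count[3], 1L)          # third window = [200000, 300000)
  expect_equal(we2$count[2], 0L)
  expect_error(window_enrichment(x, 1e6, 0), "window")
})

test_that("trap-model report applies the strict divergence bound", {
  copies <- data.frame(
    family = c("M", "M", "N", "N", "P", "P"),
    strand = c("-", "-", "+", "-", "+", "-"),
    category = c("full_length", "full_length", "full_length", "fragment",
                 "full_length", "fragment"),
    mean_divergence_pct = c(2, 3, 1, 8, 1, 12),
    stringsAsFactors = FALSE)
  rep <- trap_model_report(copies, cluster_strand = "+")
  expect_equal(rep$multicopy_antisense_families, "M")
  expect_true("N" %in% rep$trap_fragment_families)   # 8% < 10%
  expect_false("P" %in% rep$trap_fragment_families)  # 12% excluded
  none <- copies; none$category <- "fragment"
  expect_equal(trap_model_report(none, "+")$trap_fragment_families, character())
})
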