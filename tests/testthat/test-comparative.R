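test_that("annotation alignment reproduces hand-computed scores", {
  p <- align_params()
  ident <- random_tokens(5)
  al <- align_annotation_pair(ident, ident, p)
  expect_equal(al$score, 0.2 * 5)
  expect_equal(sum(al$columns$type == "match"), 5L)
  a <- data.frame(family = c("X", "Y", "Z"), strand = "+", start = 1:3)
  b <- data.frame(family = c("X", "Z"), strand = "+", start = 1:2)
  al2 <- align_annotation_pair(a, b, p)
  expect_equal(al2$score, 0.2 * 2 - 0.09)
  expect_equal(al2$columns$type, c("match", "gap_b", "match"))
  expect_error(align_annotation_pair(a[c(2, 1, 3), ], b, p), "ordered")
})

test_that("DP alignment matches the exhaustive pairing oracle", {
  set.seed(71)
  for (trial in 1:60) {
    a <- random_tokens(sample(0:8, 1))
    b <- random_tokens(sample(0:8, 1))
    got <- align_annotation_pair(a, b)$score
    expect_equal(got, bf_align_score(a, b), tolerance = 1e-10)
  }
  # family equivalence groups make near-identical names interchangeable
  pe <- align_params(family_equivalence = c("mdg4-3" = "mdg4", "mdg4-5" = "mdg4"))
  a <- data.frame(family = "mdg4-3", strand = "+", start = 1)
  b <- data.frame(family = "mdg4-5", strand = "+", start = 1)
  expect_equal(align_annotation_pair(a, b, pe)$score, 0.2)
})

test_that("panel columns track presence across genotypes", {
  g <- list(
    G1 = data.frame(family = "F", strand = "+", start = 100L, end = 700L,
                    category = "full_length"),
    G2 = data.frame(family = c("F", "Q"), strand = "+", start = c(100L, 900L),
                    end = c(700L, 1500L), category = c("fragment", "full_length")),
    G3 = data.frame(family = "F", strand = "+", start = 100L, end = 700L,
                    category = "full_length"))
  panel <- build_panel(g)
  expect_equal(nrow(panel), 2L)
  f_col <- panel[panel$family == "F", ]
  expect_equal(f_col$n_present, 3L)
  q_col <- panel[panel$family == "Q", ]
  expect_equal(q_col$n_present, 1L)
  expect_equal(q_col$state_G2, "full_length")
  expect_equal(q_col$state_G1, "absent")
})

test_that("panel construction conserves tokens on simulated panels", {
  pan <- simulate_panel(sim_config(seed = 81, n_columns = 120L))
  panel <- build_panel(pan$genotypes)
  states <- as.matrix(panel[, grep("^state_", names(panel))])
  expect_equal(sum(states != "absent"),
               sum(vapply(pan$genotypes, nrow, integer(1L))))
  spec <- sharing_spectrum(panel, 7)
  expect_equal(sum(spec), 1)
})

test_that("sharing spectrum proportions and the shared-if-degraded rule", {
  st <- matrix("absent", 10, 7, dimnames = list(NULL, paste0("state_G", 1:7)))
  st[1:4, 1] <- "full_length"
  st[5:10, ] <- "fragment"
  cols <- data.frame(column_id = 1:10, family = "F",
                     n_present = c(rep(1L, 4), rep(7L, 6)))
  cols <- cbind(cols, as.data.frame(st, stringsAsFactors = FALSE))
  spec <- sharing_spectrum(cols, 7)
  expect_equal(unname(spec[c("1", "7")]), c(0.4, 0.6))
  expect_equal(sum(spec), 1)
  # full length in one genotype, fragment in three others: shared, n_present 4
  st2 <- matrix("absent", 1, 7, dimnames = list(NULL, paste0("state_G", 1:7)))
  st2[1, 1] <- "full_length"; st2[1, 2:4] <- "fragment"
  col2 <- cbind(data.frame(column_id = 1L, family = "F", n_present = 4L),
                as.data.frame(st2, stringsAsFactors = FALSE))
  spec2 <- sharing_spectrum(col2, 7, full_length_only = TRUE)
  expect_equal(unname(spec2["4"]), 1)
  expect_error(sharing_spectrum(cols[0, ], 7), "empty")
})

test_that("percent identity is exact on constructed cases and symmetric", {
  s1 <- strrep("ACGT", 25)
  expect_equal(percent_identity(s1, s1), 1.0)
  s2 <- s1; substr(s2, 7, 7) <- "A"
  expect_equal(percent_identity(s1, s2), 0.99)
  expect_equal(percent_identity(s2, s1), percent_identity(s1, s2))
  # with an indel, symmetry still holds exactly
  s3 <- paste0(substr(s1, 1, 40), substr(s1, 46, 100))
  expect_equal(percent_identity(s1, s3), percent_identity(s3, s1))
  expect_error(percent_identity("", s1), "empty")
})

test_that("identity tracks the generator's divergence dial", {
  set.seed(91)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  ids <- replicate(10, {
    mut <- pirnakit:::.mutate_seq(base, 0.05)
    percent_identity(base, mut$seq)
  })
  expect_lt(abs(mean(ids) - 0.95), 0.01)
})

test_that("horizontal transfer is called strictly above the threshold", {
  expect_equal(ht_classify(0.99), "horizontal")
  expect_equal(ht_classify(0.95), "vertical")
  expect_equal(ht_classify(0.98), "vertical")
  expect_warning(ht_params(ht_threshold = 0.95, baseline_range = c(0.93, 0.97)),
                 "baseline")
})

test_that("planted cross-species copies separate into horizontal and vertical", {
  set.seed(92)
  calls <- replicate(50, {
    anc <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
    close_pair <- percent_identity(anc, pirnakit:::.mutate_seq(anc, 0.01)$seq)
    far_pair <- percent_identity(anc, pirnakit:::.mutate_seq(anc, 0.05)$seq)
    c(ht_classify(close_pair), ht_classify(far_pair))
  })
  expect_true(all(calls[1, ] == "horizontal"))
  expect_true(all(calls[2, ] == "vertical"))
})

test_that("degenerate-motif digestion yields conserved fragment lengths", {
  set.seed(93)
  bg <- paste(sample(c("A", "C", "G"), 994, TRUE), collapse = "")  # no T: no YACGTR
  amp <- paste0(substr(bg, 1, 747), "TACGTA", substr(bg, 748, 994))
  expect_equal(digest_fragments(amp, "YACGTR", 3), c(750L, 250L))
  expect_equal(digest_fragments(bg, "YACGTR", 3), 994L)
  expect_equal(digest_fragments(tolower(amp), "YACGTR", 3), c(750L, 250L))
  # degeneracy: Y in {C,T}, R in {A,G}
  expect_equal(length(digest_fragments(paste0(strrep("G", 100), "CACGTG",
                                              strrep("G", 94)), "YACGTR", 3)), 2L)
  expect_equal(digest_fragments(paste0(strrep("G", 100), "AACGTA",
                                       strrep("G", 94)), "YACGTR", 3), 200L)
  set.seed(94)
  rnd <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  expect_equal(sum(digest_fragments(rnd, "YACGTR", 3)), 5000L)
  expect_error(digest_fragments(rnd, "YACGTJ", 3), "IUPAC")
})
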