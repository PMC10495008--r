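test_that("a read-dense locus is called and spans the planted interval", {
  cfg <- sim_config(seed = 101, n_reads = 10000L, cluster_reads = 5000L)
  truth <- list(clusters = data.frame(contig = "sim", start = 400000L,
                                      end = 405000L),
                contig_len = c(sim = 1e6))
  sr <- simulate_small_rna(truth, cfg)
  cl <- call_clusters(sr$records, c(sim = 1e6))
  expect_equal(nrow(cl), 1L)
  expect_lte(abs(cl$start - 400000), 1000)
  expect_lte(abs(cl$end - 405000), 1000)
  expect_true(cl$passed)
  expect_equal(cl$classification, "uni")
})

test_that("uniform background yields no clusters and empty input is handled", {
  cfg <- sim_config(seed = 102, n_reads = 10000L, cluster_reads = 0L)
  truth <- list(clusters = data.frame(contig = character(), start = integer(),
                                      end = integer()),
                contig_len = c(sim = 1e6))
  sr <- simulate_small_rna(truth, cfg)
  expect_equal(nrow(call_clusters(sr$records, c(sim = 1e6))), 0L)
  expect_equal(nrow(call_clusters(sr$records[0, ], c(sim = 1e6))), 0L)
  expect_error(call_clusters(sr$records, c(sim = 0)), "zero-length")
})

test_that("read-concentration in one sequence rejects a locus (top-1% rule)", {
  # 2000 reads in one 1-kb window of a 10-kb contig; 101 distinct sequences,
  # one of which holds 95% of the read mass -> top 1% (2 sequences) > 90%
  dom <- make_records(pos = rep(2000:2999, length.out = 1900), strand = "+",
                      seq = rep(paste0("T", strrep("ACG", 8), "A"), 1900))
  code4 <- function(i) {
    d <- (i %/% c(64L, 16L, 4L, 1L)) %% 4L
    paste(c("A", "C", "G", "T")[d + 1L], collapse = "")
  }
  rare_seqs <- vapply(1:100, function(i) {
    paste0("T", code4(i), strrep("A", 21))
  }, character(1L))
  rare <- make_records(pos = rep(2000:2999, length.out = 100), strand = "+",
                       seq = rare_seqs)
  rec <- rbind(dom, rare)
  rec$read_id <- sprintf("u%05d", seq_len(nrow(rec)))
  cl <- call_clusters(rec, c(chr = 10000), all_candidates = TRUE)
  expect_equal(nrow(cl), 1L)
  expect_false(cl$pass_top1)
  expect_gt(cl$top1_share, 0.90)
  expect_false(cl$passed)
  expect_equal(nrow(call_clusters(rec, c(chr = 10000))), 0L)
})

test_that("main-strand fraction drives uni versus dual classification", {
  mk <- function(n_plus, n_minus, seed) {
    set.seed(seed)
    rbind(make_records(pos = sample(2000:2999, n_plus, TRUE), strand = "+"),
          make_records(pos = sample(2000:2999, n_minus, TRUE), strand = "-"))
  }
  uni <- mk(980, 20, 1)
  uni$read_id <- sprintf("a%05d", seq_len(nrow(uni)))
  cl_uni <- call_clusters(uni, c(chr = 10000))
  expect_equal(cl_uni$classification, "uni")
  expect_gt(cl_uni$mainstrand_frac, 0.95)
  dual <- mk(550, 450, 2)
  dual$read_id <- sprintf("b%05d", seq_len(nrow(dual)))
  cl_dual <- call_clusters(dual, c(chr = 10000))
  expect_equal(cl_dual$classification, "dual")
  expect_true(cl_dual$pass_mainstrand)
})

test_that("cluster calls respond monotonically to density_p and u10a_min", {
  cfg <- sim_config(seed = 103, n_reads = 5000L, cluster_reads = 3000L,
                    u1_prob = 0.5)
  truth <- list(clusters = data.frame(contig = "sim",
                                      start = c(100000L, 700000L),
                                      end = c(105000L, 703000L)),
                contig_len = c(sim = 1e6))
  sr <- simulate_small_rna(truth, cfg)
  key <- function(cl) paste(cl$contig, cl$start, cl$end)
  strict <- call_clusters(sr$records, c(sim = 1e6),
                          cluster_params(density_p = 0.01))
  loose <- call_clusters(sr$records, c(sim = 1e6),
                         cluster_params(density_p = 0.07))
  expect_true(all(key(strict) %in% key(loose)))
  hi_u <- call_clusters(sr$records, c(sim = 1e6),
                        cluster_params(u10a_min = 0.9))
  lo_u <- call_clusters(sr$records, c(sim = 1e6),
                        cluster_params(u10a_min = 0.33))
  expect_true(all(key(hi_u) %in% key(lo_u)))
})

test_that("promoter anchors are found with mismatches in both orientations", {
  set.seed(51)
  prom <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  bg <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  genome <- paste0(substr(bg, 1, 12345), prom, substr(bg, 12386, 30000))
  hit <- find_anchor(c(ctg = genome), prom)
  expect_true(any(hit$pos == 12345L & hit$orientation == "+" & hit$mismatches == 0L))
  # two substitutions: found at max_mismatch 2, not at 1
  prom2 <- prom
  substr(prom2, 5, 5) <- if (substr(prom2, 5, 5) == "A") "C" else "A"
  substr(prom2, 30, 30) <- if (substr(prom2, 30, 30) == "G") "T" else "G"
  expect_true(any(find_anchor(c(ctg = genome), prom2, 2)$pos == 12345L))
  expect_false(any(find_anchor(c(ctg = genome), prom2, 1)$pos == 12345L))
  # a reverse-complemented second copy is reported with orientation -
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", prom), "")[[1]]), collapse = "")
  genome2 <- paste0(genome, rc)
  hits2 <- find_anchor(c(ctg = genome2), prom)
  expect_true(any(hits2$orientation == "-" & hits2$pos == 30000L))
  expect_error(find_anchor(c(ctg = genome), "ACGTACGTAC"), ">= 20")
})

test_that("locus delimitation extends through qualifying windows and gaps", {
  enr <- data.frame(window_start = (0:6) * 1000L,
                    window_end = (1:7) * 1000L,
                    count = c(0, 0, 5, 7, 6, 0, 0))
  anchor <- list(pos = 2500L, orientation = "+")
  loc <- delimit_locus(anchor, enr, min_window_count = 3)
  expect_equal(loc$start, 2000L)
  expect_equal(loc$end, 5000L)
  expect_equal(loc$stop_reason, "below_threshold")
  gap <- enr; gap$count <- c(0, 0, 5, 0, 6, 0, 0)
  loc2 <- delimit_locus(anchor, gap, min_window_count = 3, max_gap_windows = 1)
  expect_equal(loc2$start, 2000L)
  expect_equal(loc2$end, 5000L)
  low <- enr; low$count <- rep(0, 7)
  loc3 <- delimit_locus(anchor, low, min_window_count = 3)
  expect_equal(c(loc3$start, loc3$end), c(2000L, 3000L))
  expect_error(delimit_locus(list(pos = 99999L, orientation = "+"), enr, 3),
               "outside")
})

test_that("QC flags windows exceeding benchmark 99% quantiles", {
  set.seed(61)
  qc <- simulate_qc(sim_config(seed = 61, n_anomalies = 1L))
  qs <- qc_benchmark_quantiles(qc$profile, qc$profile$is_benchmark)
  flags <- qc_flag(qc$profile, qs, c("qc", 0, 1e6))
  expect_true(all(qc$truth$anomaly_windows %in% flags$window_start))
  # per metric, at most ~1% of benchmark windows can exceed their own q99
  bench <- qc$profile[qc$profile$is_benchmark, ]
  cap <- max(1, ceiling(0.01 * nrow(bench)))
  expect_lte(sum(bench$mean_cov > qs$cov_q), cap)
  expect_lte(sum(bench$clip_rate > qs$clip_q), cap)
  small <- qc$profile[1:10, ]
  expect_error(qc_benchmark_quantiles(small, rep(TRUE, 10)), "20 benchmark")
})

test_that("constructed coverage and clip excursions are flagged by name", {
  prof <- data.frame(contig = "qc", window_start = (0:59) * 10000L,
                     mean_cov = c(rep(30, 58), 120, 30),
                     clip_rate = c(rep(0.02, 59), 0.40))
  qs <- list(cov_q = 45, clip_q = 0.08)
  flags <- qc_flag(prof, qs, c("qc", 0, 6e5))
  expect_equal(flags$window_start, c(58, 59) * 10000)
  expect_equal(flags$flag, c("coverage", "soft_clip"))
  clean <- prof; clean$mean_cov <- 30; clean$clip_rate <- 0
  expect_equal(nrow(qc_flag(clean, qs, c("qc", 0, 6e5))), 0L)
})
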